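#include <Rcpp.h>
using namespace Rcpp;

// Log likelihood-ratio scores of every w-mer of an encoded sequence.
//
// codes: base codes 1..4 (A,C,G,T), NA at masked positions.
// log_pwm: 4 x w log base probabilities per motif position.
// log_init: length-4 log initial base probabilities of the background.
// log_trans: 4 x 4 log transition matrix (row = previous base).
//
// Returns one value per start position (length L - w + 1); NA where the
// w-mer overlaps a masked base.
// [[Rcpp::export]]
NumericVector scan_logscores_cpp(IntegerVector codes, NumericMatrix log_pwm,
                                 NumericVector log_init,
                                 NumericMatrix log_trans) {
  int L = codes.size();
  int w = log_pwm.ncol();
  int npos = L - w + 1;
  if (npos < 1) return NumericVector(0);
  NumericVector out(npos, NA_REAL);
  for (int i = 0; i < npos; ++i) {
    double num = 0.0, den = 0.0;
    int prev = 0;
    bool ok = true;
    for (int j = 0; j < w; ++j) {
      int c = codes[i + j];
      if (c == NA_INTEGER) { ok = false; break; }
      num += log_pwm(c - 1, j);
      if (j == 0) den += log_init[c - 1];
      else den += log_trans(prev - 1, c - 1);
      prev = c;
    }
    if (ok) out[i] = num - den;
  }
  return out;
}

// First-order transition counts over adjacent unmasked base pairs plus
// unmasked base counts.  Returns list(trans = 4x4, base = 4).
// [[Rcpp::export]]
List transition_counts_cpp(IntegerVector codes) {
  NumericMatrix trans(4, 4);
  NumericVector base(4);
  int L = codes.size();
  for (int i = 0; i < L; ++i) {
    int c = codes[i];
    if (c == NA_INTEGER) continue;
    base[c - 1] += 1.0;
    if (i + 1 < L) {
      int d = codes[i + 1];
      if (d != NA_INTEGER) trans(c - 1, d - 1) += 1.0;
    }
  }
  return List::create(_["trans"] = trans, _["base"] = base);
}
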