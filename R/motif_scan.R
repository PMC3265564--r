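#' Motif scanning inside neighborhoods
#'
#' Cofactor binding sites are detected by scoring every unmasked w-mer of
#' a neighborhood sequence with the probability ratio
#' `r = P(wmer | PWM) / P(wmer | background)`, where the background is a
#' per-sequence first-order Markov model, and calling sites whose score
#' strictly exceeds a threshold calibrated at tail probability `p` on a
#' null distribution of scores from length- and distance-matched control
#' sequences.  Both strands are scanned; w-mers overlapping a masked
#' (lowercase or N) base are skipped.
#'
#' @name motif_scan
NULL

#' Encode a base string as integer codes
#'
#' A,C,G,T map to 1..4; lowercase (repeat-masked), N and anything else map
#' to NA.
#' @param seq a base string.
#' @export
encode_bases <- function(seq) {
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  match(v, BASES)
}

#' Estimate a first-order Markov background model
#'
#' Transition counts are tallied over adjacent unmasked base pairs (one or
#' several sequences may be pooled), `pseudocount` is added to every
#' transition cell, and rows are normalized.  Initial probabilities are
#' the unmasked base frequencies (with the same pseudocount).
#'
#' @param seqs character vector of base strings (pooled), or a list of
#'   integer code vectors from [encode_bases()].
#' @param pseudocount added per transition cell (default 0.5).
#' @return list with `trans` (4 x 4 row-stochastic matrix), `init`
#'   (length-4 probabilities) and `n_informative`, or NULL when fewer than
#'   2 informative bases are available (caller should fall back to a
#'   pooled background).
#' @export
estimate_background <- function(seqs, pseudocount = 0.5) {
  if (is.character(seqs)) seqs <- lapply(seqs, encode_bases)
  trans <- matrix(0, 4, 4)
  base <- numeric(4)
  for (codes in seqs) {
    cnt <- transition_counts_cpp(as.integer(codes))
    trans <- trans + cnt$trans
    base <- base + cnt$base
  }
  if (sum(base) < 2) return(NULL)
  trans <- trans + pseudocount
  trans <- sweep(trans, 1, rowSums(trans), "/")
  init <- (base + pseudocount) / (sum(base) + 4 * pseudocount)
  dimnames(trans) <- list(BASES, BASES)
  names(init) <- BASES
  list(trans = trans, init = init, n_informative = sum(base))
}

#' Score all w-mers of a sequence against a PWM
#'
#' The numerator is the product of PWM column probabilities of the
#' observed bases; the denominator is the background's initial probability
#' of the first base times the product of transition probabilities.  The
#' reverse strand is scored on the reverse complement with the same
#' background, reported at the forward-strand start coordinate of the
#' w-mer.
#'
#' @param seq base string or integer codes from [encode_bases()].
#' @param pwm a PWM record (see [pwm_record()]).
#' @param bg background model from [estimate_background()].
#' @return list with numeric vectors `fwd` and `rev` of length
#'   `L - w + 1` holding ratio scores r (NA where masked), indexed by
#'   0-based... by 1-based forward start position of the w-mer.
#' @export
score_wmers <- function(seq, pwm, bg) {
  codes <- if (is.character(seq)) encode_bases(seq) else seq
  w <- ncol(pwm$matrix)
  if (w > length(codes)) return(list(fwd = numeric(0), rev = numeric(0)))
  lp <- log(pwm$matrix)
  li <- log(bg$init)
  lt <- log(bg$trans)
  fwd <- scan_logscores_cpp(as.integer(codes), lp, li, lt)
  rc <- rev(5L - codes)            # reverse complement in code space
  rvs <- scan_logscores_cpp(as.integer(rc), lp, li, lt)
  list(fwd = exp(fwd), rev = exp(rev(rvs)))
}

#' Sample matched control sequences for a neighborhood
#'
#' Each control has the neighborhood's exact length, and the distance from
#' its center to the nearest TSS matches the neighborhood's
#' center-to-nearest-TSS distance within `tol` (relative).  Controls are
#' drawn uniformly over eligible positions on both flanks of randomly
#' chosen TSSs; if no eligible position is found in 1000 draws the
#' tolerance is relaxed to 25% with a warning; if the distance still
#' cannot be matched (possible when the requested distance exceeds the
#' genome's largest TSS-free gap), length-matched controls at uniform
#' positions are drawn with a warning.
#'
#' @param genome named character vector of chromosome sequences.
#' @param genes gene annotation `data.frame`.
#' @param nbhd a neighborhood (see [build_neighborhoods()]).
#' @param n number of controls (default 20).
#' @param seed RNG seed.
#' @param tol relative distance-match tolerance (default 0.1).
#' @param chrom_len optional named vector of chromosome lengths
#'   (precomputed by batch callers; `nchar` on long strings is O(n)).
#' @return character vector of `n` control sequences.
#' @export
sample_matched_controls <- function(genome, genes, nbhd, n = 20L, seed = 1L,
                                    tol = 0.1, chrom_len = NULL) {
  len <- nbhd$end - nbhd$start
  on_chr <- genes[genes$chrom == nbhd$chrom, , drop = FALSE]
  dist0 <- if (nrow(on_chr)) min(abs(on_chr$tss - nbhd$center)) else 0
  tss_by_chr <- lapply(split(genes$tss, genes$chrom), sort)
  if (is.null(chrom_len)) chrom_len <- vapply(genome, nchar, 0L)
  nearest_tss <- function(chr, center) {
    tss <- tss_by_chr[[chr]]
    i <- findInterval(center, tss)
    cand <- tss[pmax(1L, pmin(length(tss), c(i, i + 1L)))]
    min(abs(cand - center))
  }
  local_seed(seed, {
    draw <- function(tolerance, tries) {
      out <- character(0)
      for (t in seq_len(tries)) {
        gi <- sample.int(nrow(genes), 1L)
        chr <- genes$chrom[gi]
        side <- sample(c(-1L, 1L), 1L)
        d <- round(runif(1, dist0 * (1 - tolerance), dist0 * (1 + tolerance)))
        center <- genes$tss[gi] + side * d
        start <- center - floor(len / 2)
        if (start < 0 || start + len > chrom_len[[chr]]) next
        # the matched distance must hold for the *nearest* TSS, not just
        # the anchor gene
        if (abs(nearest_tss(chr, center) - dist0) > tolerance * max(dist0, 1)) next
        out <- c(out, substr(genome[[chr]], start + 1L, start + len))
        if (length(out) == n) return(out)
      }
      out
    }
    ctrl <- draw(tol, 1000L)
    if (length(ctrl) < n) {
      warnf("relaxing control distance tolerance to 25%% for a neighborhood on %s", nbhd$chrom)
      ctrl <- c(ctrl, draw(0.25, 1000L))
    }
    if (length(ctrl) < n) {
      warnf("distance %d bp unmatchable for a neighborhood on %s; falling back to length-matched controls", dist0, nbhd$chrom)
      while (length(ctrl) < n) {
        chr <- sample(names(genome), 1L)
        start <- sample.int(chrom_len[[chr]] - len, 1L)
        ctrl <- c(ctrl, substr(genome[[chr]], start + 1L, start + len))
      }
    }
    ctrl[seq_len(n)]
  })
}

#' Calibrate a score threshold from a null distribution
#'
#' The threshold is the `ceiling((1 - p) * n)`-th order statistic of the
#' null sample; a site is called iff its score is strictly greater than
#' the threshold.
#' @param null numeric vector of null scores.
#' @param p tail probability (default 9.09e-5).
#' @export
calibrate_threshold <- function(null, p = 9.09e-5) {
  null <- null[is.finite(null)]
  n <- length(null)
  if (n * p < 1) stopf("null sample too small (%d) for tail probability %g; scan more control sequence", n, p)
  k <- ceiling((1 - p) * n)
  sort(null, partial = k)[k]
}

#' Call cofactor motif sites in neighborhoods
#'
#' For each motif, a pooled null of w-mer scores (both strands) over all
#' control sequences of the cluster's neighborhoods calibrates a score
#' threshold at tail probability `p`; the neighborhoods are then scanned
#' and every w-mer whose score strictly exceeds the threshold is recorded
#' as a site with genome-absolute coordinates.  Backgrounds are estimated
#' per sequence; sequences with fewer than `min_informative` unmasked
#' bases fall back to a background pooled over all the cluster's
#' neighborhood sequences.
#'
#' @param nbhds list of neighborhoods.
#' @param pwms list of PWM records.
#' @param genome named character vector of chromosome sequences.
#' @param genes gene annotation (needed for matched controls).
#' @param p tail probability for the score cutoff (default 9.09e-5).
#' @param n_controls matched controls per neighborhood (default 20).
#' @param seed RNG seed.
#' @param pseudocount background transition pseudocount (default 0.5).
#' @param min_informative minimum unmasked bases for a per-sequence
#'   background (default 200).
#' @return list with `nbhds` (input neighborhoods with a `sites`
#'   data.frame each) and `thresholds` (motif, threshold, null_size).
#' @export
call_sites <- function(nbhds, pwms, genome, genes, p = 9.09e-5,
                       n_controls = 20L, seed = 1L, pseudocount = 0.5,
                       min_informative = 200L) {
  if (!length(nbhds) || !length(pwms)) {
    return(list(nbhds = nbhds,
                thresholds = data.frame(motif = character(),
                                        threshold = numeric(),
                                        null_size = integer())))
  }
  chrom_len <- vapply(genome, nchar, 0L)
  seqs <- lapply(nbhds, function(nb) {
    extract_interval(genome, nb$chrom, nb$start, nb$end, chrom_len[[nb$chrom]])
  })
  codes <- lapply(seqs, function(s) as.integer(encode_bases(s$seq)))
  pooled_bg <- estimate_background(codes, pseudocount)
  bg_of <- function(cd) {
    bg <- estimate_background(list(cd), pseudocount)
    if (is.null(bg) || bg$n_informative < min_informative) bg <- pooled_bg
    list(li = log(bg$init), lt = log(bg$trans))
  }
  bgs <- lapply(codes, bg_of)
  rc_codes <- lapply(codes, function(cd) rev(5L - cd))

  ctrl_codes <- vector("list", length(nbhds))
  for (i in seq_along(nbhds)) {
    ctrl <- sample_matched_controls(genome, genes, nbhds[[i]], n = n_controls,
                                    seed = seed + i, chrom_len = chrom_len)
    ctrl_codes[[i]] <- lapply(ctrl, function(s) as.integer(encode_bases(s)))
  }
  all_ctrl <- unlist(ctrl_codes, recursive = FALSE)
  ctrl_bgs <- lapply(all_ctrl, bg_of)
  ctrl_rc <- lapply(all_ctrl, function(cd) rev(5L - cd))

  thresholds <- data.frame(motif = vapply(pwms, `[[`, "", "name"),
                           threshold = NA_real_, null_size = NA_integer_,
                           stringsAsFactors = FALSE)
  site_rows <- list()
  for (m in seq_along(pwms)) {
    pwm <- pwms[[m]]
    lp <- log(pwm$matrix)
    null <- unlist(lapply(seq_along(all_ctrl), function(j) {
      bl <- ctrl_bgs[[j]]
      c(scan_logscores_cpp(all_ctrl[[j]], lp, bl$li, bl$lt),
        scan_logscores_cpp(ctrl_rc[[j]], lp, bl$li, bl$lt))
    }))
    null <- null[!is.na(null)]
    log_thr <- calibrate_threshold(null, p)   # order statistics commute with exp
    thresholds$threshold[m] <- exp(log_thr)
    thresholds$null_size[m] <- length(null)
    w <- ncol(pwm$matrix)
    for (i in seq_along(nbhds)) {
      bl <- bgs[[i]]
      L1 <- length(codes[[i]]) - w + 1L
      for (strand in c("+", "-")) {
        v <- if (strand == "+") {
          scan_logscores_cpp(codes[[i]], lp, bl$li, bl$lt)
        } else {
          rev(scan_logscores_cpp(rc_codes[[i]], lp, bl$li, bl$lt))
        }
        hit <- which(!is.na(v) & v > log_thr)
        if (!length(hit)) next
        site_rows[[length(site_rows) + 1L]] <- data.frame(
          nbhd = i, motif = pwm$name, chrom = nbhds[[i]]$chrom,
          start = seqs[[i]]$offset + hit - 1L, width = w, strand = strand,
          score = exp(v[hit]), stringsAsFactors = FALSE
        )
      }
    }
  }
  sites <- if (length(site_rows)) do.call(rbind, site_rows) else
    data.frame(nbhd = integer(), motif = character(), chrom = character(),
               start = integer(), width = integer(), strand = character(),
               score = numeric())
  for (i in seq_along(nbhds)) {
    nbhds[[i]]$sites <- sites[sites$nbhd == i,
                              setdiff(names(sites), "nbhd"), drop = FALSE]
  }
  list(nbhds = nbhds, thresholds = thresholds)
}

# clip an interval to chromosome bounds and extract its sequence;
# offset is the 0-based genome coordinate of the first extracted base
extract_interval <- function(genome, chrom, start, end, chrom_length = NULL) {
  len <- chrom_length %||% nchar(genome[[chrom]])
  s <- max(0L, start)
  e <- min(len, end)
  list(seq = substr(genome[[chrom]], s + 1L, e), offset = s)
}
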