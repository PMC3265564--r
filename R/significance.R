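#' Feature significance screening
#'
#' Every feature is tested for differential behavior between ES-up and
#' ES-down genes with two one-sided tests: a Wilcoxon rank-sum test on
#' the present feature scores, and a pooled two-sample proportion z-test
#' on the fraction of genes associated with the combination (score
#' present).  P-values are corrected by Benjamini-Hochberg within each
#' family (feature type w x test kind x direction) and significant
#' features are labeled ES-up or ES-down.
#'
#' @name significance
NULL

#' One-sided Wilcoxon rank-sum test
#'
#' Tests whether `scores_up` are stochastically greater than
#' `scores_down` (`direction = "up"`) or the reverse.  Exact enumeration
#' (via the null distribution of the Mann-Whitney U statistic) is used
#' when both samples have at most 10 observations and there are no ties;
#' otherwise a normal approximation with tie correction and a 0.5
#' continuity correction.
#'
#' @param scores_up,scores_down numeric vectors (either may be empty).
#' @param direction "up" or "down".
#' @return list with `p`, `untestable` and `method`.
#' @export
ranksum_test <- function(scores_up, scores_down, direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (!length(scores_up) || !length(scores_down)) {
    return(list(p = 1, untestable = TRUE, method = "none"))
  }
  x <- if (direction == "up") scores_up else scores_down
  y <- if (direction == "up") scores_down else scores_up
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (!ties && n1 <= 10 && n2 <= 10) {
    # exact: P(U >= u) under the permutation null
    p <- pwilcox(u - 1, n1, n2, lower.tail = FALSE)
    method <- "exact"
  } else {
    N <- n1 + n2
    tie_tab <- table(r)
    sigma2 <- (n1 * n2 / 12) * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    if (sigma2 <= 0) return(list(p = 1, untestable = TRUE, method = "degenerate"))
    z <- (u - n1 * n2 / 2 - 0.5) / sqrt(sigma2)
    p <- pnorm(z, lower.tail = FALSE)
    method <- "normal"
  }
  list(p = p, untestable = FALSE, method = method)
}

#' One-sided pooled two-sample proportion test
#'
#' Tests whether the association proportion in the ES-up group exceeds
#' that in the ES-down group (`direction = "up"`), or the reverse, with a
#' pooled-variance z statistic and no continuity correction.
#'
#' @param k_up,n_up associated / total counts in the ES-up group.
#' @param k_down,n_down counts in the ES-down group.
#' @param direction "up" or "down".
#' @return list with `p` and `untestable`.
#' @export
proportion_test <- function(k_up, n_up, k_down, n_down,
                            direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (n_up == 0 || n_down == 0) return(list(p = 1, untestable = TRUE))
  stopifnot(k_up >= 0, k_up <= n_up, k_down >= 0, k_down <= n_down)
  p1 <- k_up / n_up
  p2 <- k_down / n_down
  pp <- (k_up + k_down) / (n_up + n_down)
  se <- sqrt(pp * (1 - pp) * (1 / n_up + 1 / n_down))
  diff <- if (direction == "up") p1 - p2 else p2 - p1
  if (se == 0) return(list(p = 0.5, untestable = FALSE))
  list(p = pnorm(diff / se, lower.tail = FALSE), untestable = FALSE)
}

#' Benjamini-Hochberg step-up FDR control
#'
#' @param pvalues numeric vector.
#' @param q FDR level (default 0.10).
#' @return list with `rejected` (indices) and `adjusted` (monotone BH
#'   q-values).
#' @export
bh_fdr <- function(pvalues, q = 0.10) {
  m <- length(pvalues)
  if (!m) return(list(rejected = integer(), adjusted = numeric()))
  o <- order(pvalues)
  ranked <- pvalues[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adjusted <- numeric(m)
  adjusted[o] <- pmin(adj, 1)
  list(rejected = which(adjusted <= q), adjusted = adjusted)
}

#' Test every feature of a cluster's score matrix
#'
#' @param score_matrix genes x features natural-log score matrix (NA =
#'   absent) from [build_score_matrix()].
#' @param es_class named character vector (per gene) in {ES-up, ES-down}.
#' @return `data.frame` with one row per feature x test kind x direction:
#'   feature, test ("ranksum"/"proportion"), direction, p, untestable.
#' @export
test_features <- function(score_matrix, es_class) {
  up_genes <- names(es_class)[es_class == "ES-up"]
  down_genes <- names(es_class)[es_class == "ES-down"]
  feats <- colnames(score_matrix)
  rows <- vector("list", length(feats) * 4L)
  i <- 0L
  for (f in feats) {
    su <- score_matrix[up_genes, f]
    sd_ <- score_matrix[down_genes, f]
    pu <- su[!is.na(su)]; pd <- sd_[!is.na(sd_)]
    for (dir in c("up", "down")) {
      rs <- ranksum_test(pu, pd, dir)
      pt <- proportion_test(length(pu), length(up_genes),
                            length(pd), length(down_genes), dir)
      i <- i + 1L
      rows[[i]] <- data.frame(feature = f, test = "ranksum", direction = dir,
                              p = rs$p, untestable = rs$untestable,
                              stringsAsFactors = FALSE)
      i <- i + 1L
      rows[[i]] <- data.frame(feature = f, test = "proportion", direction = dir,
                              p = pt$p, untestable = pt$untestable,
                              stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows[seq_len(i)])
}

#' Label features by BH-corrected one-sided tests
#'
#' BH is applied within each family (feature type w x test kind x
#' direction).  A feature is labeled ES-up when it is significant in
#' either test kind in the up direction, ES-down analogously; a feature
#' significant in both directions is labeled "none" with a warning.
#'
#' @param tests output of [test_features()], with a `w` column appended
#'   (feature type of each row).
#' @param q FDR level (default 0.10).
#' @return `data.frame` per feature: feature, w, label, p_label (smallest
#'   significant p in the label direction), test_label (test kind
#'   attaining it), q_min.
#' @export
label_features <- function(tests, q = 0.10) {
  stopifnot("w" %in% names(tests))
  tests$qvalue <- NA_real_
  fam <- interaction(tests$w, tests$test, tests$direction, drop = TRUE)
  for (f in levels(fam)) {
    idx <- which(fam == f)
    tests$qvalue[idx] <- bh_fdr(tests$p[idx], q)$adjusted
  }
  tests$significant <- !tests$untestable & tests$qvalue <= q
  out <- lapply(split(tests, tests$feature), function(tf) {
    sig_up <- tf[tf$direction == "up" & tf$significant, , drop = FALSE]
    sig_down <- tf[tf$direction == "down" & tf$significant, , drop = FALSE]
    label <- "none"
    p_label <- NA_real_
    test_label <- NA_character_
    if (nrow(sig_up) && nrow(sig_down)) {
      warnf("feature %s significant in both directions; labeled none", tf$feature[1])
    } else if (nrow(sig_up)) {
      label <- "ES-up"
      k <- which.min(sig_up$p)
      p_label <- sig_up$p[k]; test_label <- sig_up$test[k]
    } else if (nrow(sig_down)) {
      label <- "ES-down"
      k <- which.min(sig_down$p)
      p_label <- sig_down$p[k]; test_label <- sig_down$test[k]
    }
    data.frame(feature = tf$feature[1], w = tf$w[1], label = label,
               p_label = p_label, test_label = test_label,
               q_min = min(tf$qvalue), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$w, res$feature), , drop = FALSE]
}

#' Reason the regulatory role of a cofactor
#'
#' Combines the direction of the feature it appears in with the
#' cofactor's own expression status: an ES-up feature with a positive
#' fold-change cofactor suggests an ES activator (EA); negative fold
#' change a DF repressor (DR); uniformly high expression leaves EA and/or
#' DR open.  ES-down features give ER, DA and ER/DA symmetrically.
#'
#' @param label "ES-up" or "ES-down".
#' @param status cofactor expression status "P", "N" or "H".
#' @return role string, or NA for status "other".
#' @export
reason_role <- function(label, status) {
  if (!label %in% c("ES-up", "ES-down") || !status %in% c("P", "N", "H")) {
    return(NA_character_)
  }
  roles <- matrix(c("EA", "ER",
                    "DR", "DA",
                    "EA/DR", "ER/DA"),
                  nrow = 3, byrow = TRUE,
                  dimnames = list(c("P", "N", "H"), c("ES-up", "ES-down")))
  roles[status, label]
}
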