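#' Gene-factor association scores
#'
#' The association score between a gene and a main factor sums, over the
#' factor's peaks within `window` bp of the gene's TSS, the peak intensity
#' weighted by exponential decay of the peak-to-TSS distance:
#' `sum_i f_i * exp(-d_i / d0)`.  Genes with no peaks in range score 0.
#'
#' @param peaks peak `data.frame` for all main factors.
#' @param genes gene annotation `data.frame`.
#' @param d0 decay constant in bp (default 5000).
#' @param window distance limit in bp, inclusive (default 1e6).
#' @return list with `scores` (genes x factors nonnegative matrix) and
#'   `normalized = FALSE`.
#' @export
association_scores <- function(peaks, genes, d0 = 5000, window = 1e6) {
  stopifnot(d0 > 0)
  factors <- sort(unique(peaks$factor))
  m <- matrix(0, nrow(genes), length(factors),
              dimnames = list(genes$gene_id, factors))
  by_fac <- split(peaks, peaks$factor)
  for (f in factors) {
    p <- by_fac[[f]]
    by_chr <- split(p, p$chrom)
    for (i in seq_len(nrow(genes))) {
      q <- by_chr[[genes$chrom[i]]]
      if (is.null(q)) next
      d <- abs(q$center - genes$tss[i])
      keep <- d <= window
      if (any(keep)) m[i, f] <- sum(q$intensity[keep] * exp(-d[keep] / d0))
    }
  }
  list(scores = m, normalized = FALSE)
}

#' Log-transform and quantile-normalize an association matrix
#'
#' Applies `log(1 + x)` (so zero scores remain finite), then column-wise
#' quantile normalization: every column receives the mean empirical
#' distribution as its sorted values, assigned through the column's order
#' (ties, e.g. the many exact zeros of unbound genes, are broken by their
#' stable input order).  The order within each column is preserved.
#' @param assoc result of [association_scores()].
#' @export
normalize_association <- function(assoc) {
  m <- log1p(assoc$scores)
  ref <- rowMeans(apply(m, 2, sort))
  out <- apply(m, 2, function(col) {
    v <- numeric(length(col))
    v[order(col)] <- ref
    v
  })
  dimnames(out) <- dimnames(m)
  list(scores = out, normalized = TRUE)
}

#' Cluster genes on normalized association scores
#'
#' k-means with Euclidean distance, k-means++-style seeding and `restarts`
#' random initializations (the run with lowest within-cluster sum of
#' squares is kept), followed by a deterministic naming rule that maps the
#' five clusters onto the labels uniformly-high, Oct4, Myc, Oct4-moderate
#' and uniformly-low from the two main-factor groups:
#' uniformly-high maximizes the minimum over factors of (cluster mean -
#' grand mean); uniformly-low minimizes the maximum; of the remaining
#' three, Myc has the largest (Myc-group mean - Oct4-group mean), Oct4 the
#' larger Oct4-group mean of the remaining two, and Oct4-moderate is last.
#' Main factors of interest per cluster: all factors (uniformly-high),
#' Oct4 group (Oct4 and Oct4-moderate), Myc group (Myc), none
#' (uniformly-low).
#'
#' @param assoc normalized association matrix (see
#'   [normalize_association()]).
#' @param groups named list with `oct4` and `myc` character vectors
#'   partitioning the main factor names.
#' @param k number of clusters (default 5).
#' @param restarts k-means restarts (default 25).
#' @param seed RNG seed.
#' @return list with `table` (`data.frame` gene_id, cluster id, name),
#'   `names` (id -> label), `factors_of_interest` (label -> factor list)
#'   and the fitted `centers`.
#' @export
cluster_genes <- function(assoc, groups, k = 5L, restarts = 25L, seed = 1L) {
  m <- assoc$scores
  if (nrow(m) < k) stopf("fewer genes (%d) than clusters (%d)", nrow(m), k)
  fit <- local_seed(seed, {
    best <- NULL
    for (r in seq_len(restarts)) {
      init <- kmeanspp_init(m, k)
      f <- suppressWarnings(kmeans(m, centers = init, iter.max = 100L))
      if (is.null(best) || f$tot.withinss < best$tot.withinss) best <- f
    }
    best
  })
  labels <- name_clusters(fit$centers, colMeans(m), groups)
  foi <- list(
    "uniformly-high" = colnames(m),
    "Oct4" = intersect(colnames(m), groups$oct4),
    "Myc" = intersect(colnames(m), groups$myc),
    "Oct4-moderate" = intersect(colnames(m), groups$oct4),
    "uniformly-low" = character()
  )
  list(
    table = data.frame(gene_id = rownames(m), cluster = fit$cluster,
                       name = labels[fit$cluster], stringsAsFactors = FALSE),
    names = labels,
    factors_of_interest = foi,
    centers = fit$centers
  )
}

# k-means++ seeding: centers drawn with probability proportional to the
# squared distance to the nearest already-chosen center
kmeanspp_init <- function(m, k) {
  n <- nrow(m)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1L)
  d2 <- rowSums((m - matrix(m[idx[1], ], n, ncol(m), byrow = TRUE))^2)
  for (j in seq_len(k - 1L) + 1L) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    idx[j] <- sample.int(n, 1L, prob = p)
    nd <- rowSums((m - matrix(m[idx[j], ], n, ncol(m), byrow = TRUE))^2)
    d2 <- pmin(d2, nd)
  }
  m[idx, , drop = FALSE]
}

name_clusters <- function(centers, grand, groups) {
  k <- nrow(centers)
  if (k != 5L) stopf("cluster naming rule requires k = 5, got %d", k)
  dev <- sweep(centers, 2, grand)   # cluster mean - grand mean per factor
  labels <- rep(NA_character_, k)
  uh <- which.max(apply(dev, 1, min))
  labels[uh] <- "uniformly-high"
  rest <- setdiff(seq_len(k), uh)
  ul <- rest[which.min(apply(dev[rest, , drop = FALSE], 1, max))]
  labels[ul] <- "uniformly-low"
  rest <- setdiff(rest, ul)
  oct4_cols <- intersect(colnames(centers), groups$oct4)
  myc_cols <- intersect(colnames(centers), groups$myc)
  myc_vs_oct4 <- rowMeans(centers[rest, myc_cols, drop = FALSE]) -
    rowMeans(centers[rest, oct4_cols, drop = FALSE])
  myc <- rest[which.max(myc_vs_oct4)]
  labels[myc] <- "Myc"
  rest <- setdiff(rest, myc)
  oct4_mean <- rowMeans(centers[rest, oct4_cols, drop = FALSE])
  oct4 <- rest[which.max(oct4_mean)]
  labels[oct4] <- "Oct4"
  labels[setdiff(rest, oct4)] <- "Oct4-moderate"
  labels
}

#' Call ES-up/ES-down genes and cofactor expression statuses
#'
#' A gene is ES-up when its mean expression at ES stage exceeds
#' `fc_threshold` times its DF mean and a Welch two-sample t-test on
#' `log2(1 + expression)` gives p < `alpha`; ES-down symmetrically;
#' otherwise neutral.  Expression status (used for cofactor genes) is P
#' when the raw ES/DF mean ratio > `fc_threshold`, N when it is <
#' 1/`fc_threshold`, H when neither holds but both stage means exceed
#' `h_floor`, and "other" otherwise.
#'
#' @param expr an `expr_matrix` (see [expression_matrix()]).
#' @param fc_threshold fold-change threshold (default 2).
#' @param alpha test level (default 0.05).
#' @param h_floor uniformly-high expression floor (default 500).
#' @return `data.frame` with gene_id, mean_es, mean_df, fc, p_value,
#'   es_class in {ES-up, ES-down, neutral}, status in {P, N, H, other}.
#' @export
call_es_genes <- function(expr, fc_threshold = 2, alpha = 0.05, h_floor = 500) {
  es <- expr$values[, expr$stage == "ES", drop = FALSE]
  df <- expr$values[, expr$stage == "DF", drop = FALSE]
  mean_es <- rowMeans(es)
  mean_df <- rowMeans(df)
  if (any(mean_df == 0)) warnf("zero DF mean expression: fold change treated as Inf")
  fc <- ifelse(mean_df == 0, Inf, mean_es / mean_df)
  les <- log2(1 + es)
  ldf <- log2(1 + df)
  pv <- vapply(seq_len(nrow(les)), function(i) {
    if (var(les[i, ]) + var(ldf[i, ]) == 0) return(1)
    t.test(les[i, ], ldf[i, ])$p.value
  }, 0)
  es_class <- rep("neutral", length(fc))
  es_class[fc > fc_threshold & pv < alpha] <- "ES-up"
  es_class[fc < 1 / fc_threshold & pv < alpha] <- "ES-down"
  status <- rep("other", length(fc))
  status[fc > fc_threshold] <- "P"
  status[fc < 1 / fc_threshold] <- "N"
  status[status == "other" & mean_es > h_floor & mean_df > h_floor] <- "H"
  data.frame(gene_id = rownames(expr$values), mean_es = mean_es,
             mean_df = mean_df, fc = fc, p_value = pv,
             es_class = es_class, status = status,
             stringsAsFactors = FALSE, row.names = NULL)
}
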