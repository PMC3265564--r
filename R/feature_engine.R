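#' TF combinations and feature scores
#'
#' A feature is the association pattern between genes and a TF
#' combination: `w` main factors of interest (w in 0, 1, 2) plus one
#' cofactor motif.  The feature score of a gene sums, over its associated
#' neighborhoods that support the combination, a combined binding strength
#' (geometric mean of the relevant peak intensities times geometric mean
#' of the cofactor site scores) down-weighted exponentially by the average
#' site-to-TSS distance.  Scores are used in natural-log scale; a gene
#' with no supporting neighborhood has no score ("absent").
#'
#' @name feature_engine
NULL

#' Enumerate TF combinations
#'
#' All `choose(length(main_factors), w) * length(cofactors)` combinations,
#' in deterministic lexicographic order (factors and motifs sorted
#' case-insensitively).
#' @param main_factors character vector of the cluster's main factors of
#'   interest.
#' @param cofactors character vector of cofactor motif names.
#' @param w number of main factors per combination (0, 1 or 2).
#' @return list of combinations, each a list with `main` (sorted factor
#'   names), `motif`, `w` and `name` (dot-concatenated).
#' @export
enumerate_combinations <- function(main_factors, cofactors, w) {
  if (!w %in% 0:2) stopf("w must be 0, 1 or 2")
  main_factors <- unique(sort_factors(main_factors))
  cofactors <- unique(sort(cofactors))
  if (w > length(main_factors)) stopf("w = %d exceeds the %d main factors", w, length(main_factors))
  mains <- if (w == 0) list(character()) else
    apply(combn(main_factors, w), 2, identity, simplify = FALSE)
  out <- vector("list", length(mains) * length(cofactors))
  i <- 0L
  for (mf in mains) {
    # main_factors are pre-sorted, so combn emits each subset in name order
    prefix <- paste(mf, collapse = ".")
    for (cf in cofactors) {
      i <- i + 1L
      out[[i]] <- list(main = mf, motif = cf, w = w,
                       name = if (w == 0) cf else paste(prefix, cf, sep = "."))
    }
  }
  out
}

#' Does a neighborhood support a TF combination?
#'
#' True iff the neighborhood contains at least one peak of every main
#' factor in the combination and at least one motif site of its cofactor
#' (for w = 0 only the cofactor condition applies).
#' @param nbhd a neighborhood with called `sites`.
#' @param combo a combination from [enumerate_combinations()].
#' @export
supports <- function(nbhd, combo) {
  all(combo$main %in% nbhd$peaks$factor) &&
    combo$motif %in% nbhd$sites$motif
}

#' Feature score of one gene for one combination
#'
#' For each supporting associated neighborhood k with `n_k` peaks of the
#' combination's main factors (intensities `f_ki`) and `m_k` sites of its
#' cofactor (scores `g_kj`), the contribution is
#' `(prod f_ki)^(1/n_k) * (prod g_kj)^(1/m_k) *
#'  exp(-(sum d_ki + sum d_kj) / ((n_k + m_k) * d0))`,
#' with distances measured from peak center / site start to the gene TSS.
#' For w = 0 the main-factor term is the empty product 1 and `n_k = 0`.
#' The score is the natural log of the summed contributions, or NA
#' ("absent") when no associated neighborhood supports the combination.
#'
#' @param gene one row of the gene annotation.
#' @param nbhds list of the gene's associated neighborhoods.
#' @param combo a combination.
#' @param d0 decay constant in bp (default 5000).
#' @export
feature_score <- function(gene, nbhds, combo, d0 = 5000) {
  total <- 0
  any_support <- FALSE
  for (nb in nbhds) {
    if (!supports(nb, combo)) next
    any_support <- TRUE
    pk <- nb$peaks[nb$peaks$factor %in% combo$main, , drop = FALSE]
    st <- nb$sites[nb$sites$motif == combo$motif, , drop = FALSE]
    if (any(pk$intensity <= 0) || any(st$score <= 0)) {
      stopf("nonpositive peak intensity or site score in a supporting neighborhood")
    }
    n_k <- nrow(pk)
    m_k <- nrow(st)
    log_gm <- (if (n_k > 0) sum(log(pk$intensity)) / n_k else 0) +
      sum(log(st$score)) / m_k
    dsum <- sum(abs(pk$center - gene$tss)) + sum(abs(st$start - gene$tss))
    total <- total + exp(log_gm - dsum / ((n_k + m_k) * d0))
  }
  if (!any_support) NA_real_ else log(total)
}

#' Build the gene x feature score matrix for a cluster
#'
#' Rows are the supplied (ES) genes, columns the enumerated combinations;
#' entries are natural-log feature scores or NA when absent.
#'
#' @param genes gene annotation rows for the cluster's ES genes.
#' @param nbhds the cluster's neighborhoods (with called sites).
#' @param assoc_map gene -> neighborhood indices from
#'   [associate_neighborhoods()] (must cover `genes`).
#' @param combos list of combinations.
#' @param d0 decay constant (default 5000).
#' @return numeric matrix with feature names as columns.
#' @export
build_score_matrix <- function(genes, nbhds, assoc_map, combos, d0 = 5000) {
  cnames <- vapply(combos, `[[`, "", "name")
  m <- matrix(NA_real_, nrow(genes), length(combos),
              dimnames = list(genes$gene_id, cnames))
  if (!nrow(genes) || !length(combos)) return(m)
  # per-neighborhood index structures reused across genes
  pk_by_fac <- lapply(nbhds, function(nb) split(nb$peaks, nb$peaks$factor))
  st_by_mot <- lapply(nbhds, function(nb) split(nb$sites, nb$sites$motif))
  for (gi in seq_len(nrow(genes))) {
    tss <- genes$tss[gi]
    idx <- assoc_map[[genes$gene_id[gi]]]
    if (!length(idx)) next
    for (ci in seq_along(combos)) {
      combo <- combos[[ci]]
      total <- 0
      found <- FALSE
      for (k in idx) {
        st <- st_by_mot[[k]][[combo$motif]]
        if (is.null(st)) next
        n_k <- 0L
        log_f <- 0
        dsum_f <- 0
        ok <- TRUE
        for (f in combo$main) {
          pk <- pk_by_fac[[k]][[f]]
          if (is.null(pk)) { ok <- FALSE; break }
          n_k <- n_k + nrow(pk)
          log_f <- log_f + sum(log(pk$intensity))
          dsum_f <- dsum_f + sum(abs(pk$center - tss))
        }
        if (!ok) next
        found <- TRUE
        m_k <- nrow(st)
        log_gm <- (if (n_k > 0) log_f / n_k else 0) + sum(log(st$score)) / m_k
        dsum <- dsum_f + sum(abs(st$start - tss))
        total <- total + exp(log_gm - dsum / ((n_k + m_k) * d0))
      }
      if (found) m[gi, ci] <- log(total)
    }
  }
  m
}
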