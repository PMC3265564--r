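#' Neighborhood construction
#'
#' A neighborhood is a merged genomic island built from ChIP-seq peaks of a
#' cluster's main factors of interest: each peak contributes a window of
#' +/- `extend` bp around its center, and two islands merge whenever a peak
#' center in one lies within `merge_dist` bp of a peak center in the other
#' (applied recursively, i.e. single linkage on peak centers).  Only
#' islands holding at least `min_peaks` peaks are retained.  Peaks of the
#' same factor may both count toward the minimum.
#'
#' @param peaks peak `data.frame` (factor, chrom, center, intensity).
#' @param extend window half-width in bp (default 500).
#' @param merge_dist merge threshold on peak-center distance in bp,
#'   inclusive (default 500).
#' @param min_peaks minimum member peaks for a retained island (default 2).
#' @return list of neighborhoods; each is a list with `chrom`, `start`,
#'   `end` (0-based half-open), `center` (floor of the mean member peak
#'   center) and `peaks` (the member rows of `peaks`).
#' @export
build_neighborhoods <- function(peaks, extend = 500L, merge_dist = 500L,
                                min_peaks = 2L) {
  if (!nrow(peaks)) return(list())
  out <- list()
  for (chr in unique(peaks$chrom)) {
    p <- peaks[peaks$chrom == chr, , drop = FALSE]
    p <- p[order(p$center), , drop = FALSE]
    # single-linkage clusters on sorted centers: break where gap > merge_dist
    gap_new <- c(TRUE, diff(p$center) > merge_dist)
    grp <- cumsum(gap_new)
    for (g in unique(grp)) {
      memb <- p[grp == g, , drop = FALSE]
      if (nrow(memb) < min_peaks) next
      out[[length(out) + 1L]] <- list(
        chrom = chr,
        start = min(memb$center) - as.integer(extend),
        end = max(memb$center) + as.integer(extend),
        center = as.integer(floor(mean(memb$center))),
        peaks = memb
      )
    }
  }
  out
}

#' Associate neighborhoods with genes
#'
#' A neighborhood is associated with every gene whose TSS lies within `d`
#' bp of the neighborhood center (inclusive boundary); a neighborhood may
#' serve several genes.
#'
#' @param nbhds list of neighborhoods from [build_neighborhoods()].
#' @param genes gene annotation `data.frame`.
#' @param d distance limit in bp (default 1e6).
#' @return named list mapping gene id to an integer vector of neighborhood
#'   indices (possibly empty).
#' @export
associate_neighborhoods <- function(nbhds, genes, d = 1e6) {
  centers <- vapply(nbhds, `[[`, 0L, "center")
  chroms <- vapply(nbhds, `[[`, "", "chrom")
  out <- vector("list", nrow(genes))
  names(out) <- genes$gene_id
  for (i in seq_len(nrow(genes))) {
    hit <- which(chroms == genes$chrom[i] & abs(centers - genes$tss[i]) <= d)
    out[[i]] <- hit
  }
  out
}
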