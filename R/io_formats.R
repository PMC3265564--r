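#' File formats
#'
#' Readers and writers for every external file the pipeline touches.  All
#' genomic coordinates are 0-based; intervals are half-open ("BED
#' convention").  Distances to a TSS are absolute base-pair differences,
#' strand-independent.
#'
#' @name io_formats
NULL

# ---- peaks -------------------------------------------------------------

#' Read a ChIP-seq peak table
#'
#' Accepts two tab-separated layouts (with header): `chrom, start, end,
#' intensity` (BED-like, 0-based half-open; the peak center is the floor of
#' the interval midpoint) or `chrom, center, intensity`.
#'
#' @param path path to a tab-separated peak file.
#' @param factor name of the ChIP-seq'd transcription factor.
#' @return a `data.frame` with columns `factor`, `chrom`, `center`,
#'   `intensity`, sorted by (chrom, center).
#' @export
read_peaks <- function(path, factor) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  cols <- names(df)
  if (all(c("chrom", "start", "end", "intensity") %in% cols)) {
    bad <- which(!is.finite(df$start) | !is.finite(df$end) | df$end <= df$start)
    if (length(bad)) {
      stopf("malformed peak interval at line %d of %s", bad[1] + 1L, path)
    }
    center <- floor((df$start + df$end) / 2)
  } else if (all(c("chrom", "center", "intensity") %in% cols)) {
    bad <- which(!is.finite(df$center))
    if (length(bad)) stopf("malformed peak center at line %d of %s", bad[1] + 1L, path)
    center <- df$center
  } else {
    stopf("unrecognized peak header in %s: need chrom/start/end/intensity or chrom/center/intensity", path)
  }
  if (nrow(df) && (any(!is.finite(df$intensity)) || any(df$intensity <= 0))) {
    bad <- which(!is.finite(df$intensity) | df$intensity <= 0)[1]
    stopf("nonpositive or missing intensity at line %d of %s", bad + 1L, path)
  }
  peaks <- data.frame(
    factor = rep(as.character(factor), nrow(df)),
    chrom = as.character(df$chrom),
    center = as.integer(center),
    intensity = as.numeric(df$intensity),
    stringsAsFactors = FALSE
  )
  peaks[order(peaks$chrom, peaks$center), , drop = FALSE]
}

#' @rdname read_peaks
#' @param peaks peak `data.frame` as returned by [read_peaks()].
#' @export
write_peaks <- function(peaks, path) {
  write_tsv(peaks[, c("chrom", "center", "intensity")], path)
}

# ---- gene annotation ---------------------------------------------------

#' Read/write a TSS annotation (one TSS per gene)
#'
#' Tab-separated with header `gene_id, chrom, tss, strand`.
#' @param path file path.
#' @return `data.frame` with those four columns.
#' @export
read_genes <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "tss", "strand")
  if (!all(need %in% names(df))) stopf("gene table %s must have columns %s", path, paste(need, collapse = ", "))
  if (anyDuplicated(df$gene_id)) stopf("duplicate gene ids in %s", path)
  df$tss <- as.integer(df$tss)
  df[, need]
}

#' @rdname read_genes
#' @param genes gene annotation `data.frame`.
#' @export
write_genes <- function(genes, path) write_tsv(genes, path)

# ---- genome ------------------------------------------------------------

#' Read/write a (repeat-masked) genome FASTA
#'
#' Lowercase bases and `N` mark masked positions; case is preserved, so the
#' genome is held as a named character vector of base strings.
#' @param path FASTA path.
#' @return named character vector, one element per chromosome.
#' @export
read_genome <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  g <- as.character(ss)
  names(g) <- sub("\\s.*$", "", names(g))
  if (anyDuplicated(names(g))) stopf("duplicate chromosome names in %s", path)
  if (any(nchar(g) == 0)) stopf("empty chromosome sequence in %s", path)
  g
}

#' @rdname read_genome
#' @param genome named character vector of chromosome sequences.
#' @export
write_genome <- function(genome, path) {
  ss <- Biostrings::BStringSet(genome)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

# ---- PWMs --------------------------------------------------------------

#' Read a PWM collection
#'
#' TRANSFAC-style text blocks: a header line `>NAME gene1,gene2` (the gene
#' ids the motif maps to), followed by the matrix, one row per motif
#' position with 4 whitespace-separated numbers in A, C, G, T order.  A
#' block whose rows are the 4 bases (4 rows, width != 4 columns) is
#' transposed automatically.  Counts are converted to per-position
#' probabilities; whenever any cell of a matrix is 0 a pseudocount of 0.01
#' is added to every cell before normalization.
#'
#' @param path PWM text file.
#' @return list of PWM records, each a list with `name`, `matrix`
#'   (4 x width, rows A/C/G/T, columns summing to 1) and `cofactor_genes`.
#' @export
read_pwm <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  heads <- grep("^>", lines)
  if (!length(heads)) return(list())
  bounds <- c(heads, length(lines) + 1L)
  pwms <- vector("list", length(heads))
  for (k in seq_along(heads)) {
    hdr <- sub("^>", "", lines[heads[k]])
    parts <- strsplit(hdr, "[ \t]+")[[1]]
    name <- parts[1]
    cof <- if (length(parts) > 1) strsplit(parts[2], ",")[[1]] else character()
    body <- lines[seq(heads[k] + 1L, bounds[k + 1L] - 1L)]
    body <- body[nzchar(body)]
    if (!length(body)) stopf("PWM block %s in %s has no matrix", name, path)
    rows <- lapply(body, function(l) as.numeric(strsplit(l, "[ \t]+")[[1]]))
    ncols <- unique(lengths(rows))
    if (length(ncols) != 1) stopf("ragged matrix rows in PWM block %s of %s", name, path)
    m <- do.call(rbind, rows)
    if (ncols == 4) {
      m <- t(m)            # rows were positions, make 4 x w
    } else if (nrow(m) == 4) {
      # already 4 x w (rows are bases)
    } else {
      stopf("PWM block %s in %s: matrix must have 4 columns or 4 rows", name, path)
    }
    if (any(!is.finite(m)) || any(m < 0)) stopf("invalid PWM values in block %s of %s", name, path)
    pwms[[k]] <- pwm_record(name, m, cof)
  }
  pwms
}

#' Construct and validate a PWM record
#' @param name motif name.
#' @param matrix 4 x width numeric matrix (counts or probabilities), rows
#'   in A, C, G, T order.
#' @param cofactor_genes character vector of gene ids the motif maps to.
#' @export
pwm_record <- function(name, matrix, cofactor_genes = character()) {
  if (nrow(matrix) != 4 || ncol(matrix) < 1) stopf("PWM %s must be 4 x w with w >= 1", name)
  if (any(matrix == 0)) matrix <- matrix + 0.01
  matrix <- sweep(matrix, 2, colSums(matrix), "/")
  if (any(abs(colSums(matrix) - 1) > 1e-9)) stopf("PWM %s columns do not normalize", name)
  rownames(matrix) <- BASES
  list(name = as.character(name), matrix = matrix,
       cofactor_genes = as.character(cofactor_genes))
}

#' @rdname read_pwm
#' @param pwms list of PWM records.
#' @export
write_pwm <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(sprintf(">%s %s", p$name, paste(p$cofactor_genes, collapse = ",")), con)
    for (j in seq_len(ncol(p$matrix))) {
      writeLines(paste(format(p$matrix[, j], digits = 12, trim = TRUE), collapse = "\t"), con)
    }
  }
  invisible(path)
}

# ---- expression --------------------------------------------------------

#' Read/write an expression matrix with stage labels
#'
#' Tab-separated: first line `gene_id` plus sample ids, second line `stage`
#' plus a per-sample label in {ES, DF}, then one row per gene of
#' nonnegative expression indices.
#' @param path file path.
#' @return list with `values` (genes x samples numeric matrix) and `stage`
#'   (named character vector of per-sample labels).
#' @export
read_expression <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (df[[1]][1] != "stage") stopf("expression file %s must carry a 'stage' label line", path)
  stage <- as.character(df[1, -1])
  names(stage) <- names(df)[-1]
  vals <- as.matrix(df[-1, -1, drop = FALSE])
  mode(vals) <- "numeric"
  rownames(vals) <- df[[1]][-1]
  expression_matrix(vals, stage)
}

#' @rdname read_expression
#' @param values genes x samples nonnegative matrix.
#' @param stage per-sample labels in {ES, DF} (recycled names from columns).
#' @export
expression_matrix <- function(values, stage) {
  stage <- as.character(stage)
  if (length(stage) != ncol(values)) stopf("one stage label per sample required")
  if (!all(stage %in% c("ES", "DF"))) stopf("stage labels must be ES or DF")
  if (min(table(factor(stage, c("ES", "DF")))) < 2) stopf("need >= 2 samples per stage")
  if (any(values < 0)) stopf("expression values must be nonnegative")
  names(stage) <- colnames(values)
  structure(list(values = values, stage = stage), class = "expr_matrix")
}

#' @rdname read_expression
#' @param expr an `expr_matrix`.
#' @export
write_expression <- function(expr, path) {
  hdr <- c("gene_id", colnames(expr$values))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(hdr, collapse = "\t"), con)
  writeLines(paste(c("stage", expr$stage), collapse = "\t"), con)
  body <- cbind(rownames(expr$values),
                format(expr$values, digits = 12, trim = TRUE, scientific = FALSE))
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

# ---- naming and generic writers ---------------------------------------

#' Feature name in dot-concatenated convention
#'
#' Main factor names (case-insensitively sorted) and the cofactor motif
#' name joined with dots, e.g. `Smad1.STAT3.M00052_NFKB`; a cofactor-only
#' feature is named by the motif alone.
#' @param main_factors character vector of 0-2 main factor names.
#' @param motif cofactor motif name.
#' @export
feature_name <- function(main_factors, motif) {
  mf <- sort_factors(main_factors)
  paste(c(mf, motif), collapse = ".")
}

sort_factors <- function(x) {
  if (!length(x)) return(character())
  x[order(tolower(x), x)]
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write neighborhoods or motif sites as BED
#' @param nbhds list of neighborhoods (see [build_neighborhoods()]).
#' @param path output path.
#' @export
write_neighborhoods_bed <- function(nbhds, path) {
  df <- data.frame(
    chrom = vapply(nbhds, `[[`, "", "chrom"),
    start = vapply(nbhds, `[[`, 0L, "start"),
    end = vapply(nbhds, `[[`, 0L, "end"),
    name = sprintf("nbhd_%d", seq_along(nbhds)),
    n_peaks = vapply(nbhds, function(n) nrow(n$peaks), 0L),
    center = vapply(nbhds, `[[`, 0L, "center"),
    stringsAsFactors = FALSE
  )
  write_tsv(df, path)
}

#' @rdname write_neighborhoods_bed
#' @param sites motif site `data.frame` (chrom, start, strand, motif, score).
#' @export
write_sites_bed <- function(sites, path) {
  df <- data.frame(
    chrom = sites$chrom, start = sites$start, end = sites$start + sites$width,
    name = sites$motif, score = sites$score, strand = sites$strand,
    stringsAsFactors = FALSE
  )
  write_tsv(df, path)
}

#' Write a gene x feature score matrix ("NA" marks absent scores)
#' @param mat numeric matrix (natural-log feature scores, NA = absent).
#' @param path output path.
#' @export
write_score_matrix <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat),
                   format(mat, digits = 12, trim = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read back a score matrix written by [write_score_matrix()]
#' @param path file path.
#' @export
read_score_matrix <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df[[1]]
  m
}

#' Write all pipeline result tables to a directory
#'
#' Emits tab-separated files for association scores, cluster assignments,
#' ES gene calls, neighborhoods (BED), motif sites (BED with score),
#' per-cluster feature score matrices, the significant-feature table, the
#' selected features, predicted targets, and the validation summary --
#' whichever of these the supplied result object carries.
#'
#' @param results a pipeline result list (see [run_pipeline()]).
#' @param outdir output directory (created if missing).
#' @export
write_results <- function(results, outdir) {
  ok <- dir.exists(outdir) || dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(outdir, 2) != 0) stopf("cannot write to %s", outdir)
  if (!is.null(results$association)) {
    m <- results$association$scores
    write_tsv(data.frame(gene_id = rownames(m), format(m, digits = 12, trim = TRUE),
                         check.names = FALSE), file.path(outdir, "association_scores.tsv"))
  }
  if (!is.null(results$clusters)) {
    write_tsv(results$clusters$table, file.path(outdir, "clusters.tsv"))
  }
  if (!is.null(results$es_status)) {
    write_tsv(results$es_status, file.path(outdir, "es_genes.tsv"))
  }
  for (cl in names(results$per_cluster %||% list())) {
    pc <- results$per_cluster[[cl]]
    tag <- gsub("[^A-Za-z0-9]+", "_", cl)
    if (length(pc$neighborhoods)) {
      write_neighborhoods_bed(pc$neighborhoods, file.path(outdir, sprintf("neighborhoods_%s.bed", tag)))
    }
    sites <- collect_sites(pc$neighborhoods)
    if (nrow(sites)) write_sites_bed(sites, file.path(outdir, sprintf("motif_sites_%s.bed", tag)))
    if (!is.null(pc$thresholds)) {
      write_tsv(pc$thresholds, file.path(outdir, sprintf("motif_thresholds_%s.tsv", tag)))
    }
    if (!is.null(pc$score_matrix)) {
      write_score_matrix(pc$score_matrix, file.path(outdir, sprintf("feature_scores_%s.tsv", tag)))
    }
  }
  if (!is.null(results$significant)) {
    write_tsv(results$significant, file.path(outdir, "significant_features.tsv"))
  }
  if (!is.null(results$selection)) {
    write_tsv(results$selection, file.path(outdir, "selected_features.tsv"))
  }
  if (!is.null(results$targets)) {
    write_tsv(results$targets, file.path(outdir, "predicted_targets.tsv"))
  }
  if (!is.null(results$validation)) {
    write_tsv(results$validation, file.path(outdir, "validation_summary.tsv"))
  }
  invisible(outdir)
}

collect_sites <- function(nbhds) {
  out <- lapply(nbhds, function(n) n$sites)
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) {
    return(data.frame(chrom = character(), start = integer(), width = integer(),
                      strand = character(), motif = character(), score = numeric()))
  }
  do.call(rbind, out)
}
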