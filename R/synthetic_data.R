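#' Synthetic input bundles with ground truth
#'
#' Generates every input the pipeline consumes -- repeat-masked genome,
#' TSS annotation, per-factor ChIP-seq peaks with planted cluster
#' structure, cofactor PWMs, planted motif instances near designated gene
#' sets, two-stage expression, and an independent validation expression
#' set -- together with a ground-truth manifest, so every downstream
#' stage is testable without downloads.  Generation with a fixed seed is
#' byte-reproducible.
#'
#' @name synthetic_data
NULL

CLUSTER_LABELS <- c("uniformly-high", "Oct4", "Myc", "Oct4-moderate",
                    "uniformly-low")

#' Synthetic bundle configuration
#'
#' Defaults describe the stated world the package is exercised on: a
#' 2 x 6 Mb genome at mouse-like 42% GC with 30% repeat masking, 200
#' genes at ~56 kb TSS spacing, 6 main factors (3 per group), 12 cofactor
#' PWMs, 4 planted co-binding features, and 8 ES + 8 DF expression
#' samples with a log2 effect size of 2 and noise sd 0.25.  The spacing
#' keeps crosstalk between neighboring genes' peaks negligible under the
#' 1 Mb association window (decay exp(-60000/5000) ~ 6e-6), emulating
#' the per-gene sparsity of a mammalian genome at desk scale.
#'
#' @param seed master seed.
#' @param n_chromosomes,chrom_length genome shape.
#' @param gc GC fraction in (0, 1).
#' @param repeat_fraction masked (lowercase) fraction in `[0, 1)`.
#' @param n_genes number of regular genes (cofactor genes are appended).
#' @param factors named list `oct4` / `myc` partitioning the main factor
#'   names into the two groups.
#' @param cluster_probs per-cluster gene proportions (named, sums to 1).
#' @param es_up_frac,es_down_frac per-cluster fractions of ES-up/-down
#'   genes among the four non-low clusters.
#' @param n_cofactors,pwm_width,pwm_dominant cofactor PWM shape: dominant
#'   base probability per column.
#' @param planted list of planted features, each a list with `main`
#'   (0-2 factor names), `cofactor` (index into the PWM list), `cluster`
#'   and `direction` ("ES-up"/"ES-down"); NULL for the default four,
#'   `list()` for none.
#' @param n_anchors_range peaks per "on" factor per gene (each factor
#'   draws this many anchors from the gene's pool).
#' @param anchor_pool_range size of the per-gene pool of shared anchor
#'   positions; factors draw their peaks from this pool so co-binding
#'   islands form while factor-level distance noise stays partially
#'   independent.
#' @param peak_dist_mean mean TSS distance of anchors (exponential), bp.
#' @param co_jitter max per-factor jitter around a shared anchor, bp.
#' @param off_peak_prob probability an "off" factor still has one peak.
#' @param intensity_meanlog,intensity_sdlog log-normal peak intensities.
#' @param moderate_scale,moderate_n_factors the Oct4-moderate cluster
#'   binds only `moderate_n_factors` of the Oct4-group factors (drawn per
#'   gene) at `moderate_scale` times the usual intensity: partial-group
#'   occupancy gives the moderate group-average association while keeping
#'   the cluster identifiable.
#' @param effect log2 expression effect size between stages.
#' @param noise per-sample log2 noise sd.
#' @param n_es,n_df samples per stage in the primary expression data.
#' @param n_es_val,n_df_val samples per stage in the validation data
#'   (day-0-like vs day-4-6-like).
#' @param effect_val,noise_val validation effect and noise.
#' @export
synthetic_config <- function(seed = 1L,
                             n_chromosomes = 2L, chrom_length = 6e6,
                             gc = 0.42, repeat_fraction = 0.30,
                             n_genes = 200L,
                             factors = list(oct4 = c("Oct4", "Sox2", "Nanog"),
                                            myc = c("Myc", "Mycn", "E2f1")),
                             cluster_probs = c("uniformly-high" = 0.15,
                                               "Oct4" = 0.25, "Myc" = 0.25,
                                               "Oct4-moderate" = 0.15,
                                               "uniformly-low" = 0.20),
                             es_up_frac = 0.30, es_down_frac = 0.30,
                             n_cofactors = 12L, pwm_width = 10L,
                             pwm_dominant = 0.95,
                             planted = NULL,
                             n_anchors_range = c(2L, 4L),
                             anchor_pool_range = c(4L, 6L),
                             peak_dist_mean = 2e4, co_jitter = 150L,
                             off_peak_prob = 0.05,
                             intensity_meanlog = 4, intensity_sdlog = 0.4,
                             moderate_scale = 0.6, moderate_n_factors = 2L,
                             effect = 2, noise = 0.25,
                             n_es = 8L, n_df = 8L,
                             n_es_val = 2L, n_df_val = 3L,
                             effect_val = 1.5, noise_val = 0.3) {
  stopifnot(gc > 0, gc < 1, repeat_fraction >= 0, repeat_fraction < 1,
            effect >= 0, abs(sum(cluster_probs) - 1) < 1e-9,
            es_up_frac + es_down_frac <= 1)
  if (is.null(planted)) {
    planted <- list(
      list(main = factors$oct4[1:2], cofactor = 1L, cluster = "Oct4",
           direction = "ES-up"),
      list(main = factors$oct4[1], cofactor = 2L, cluster = "Oct4",
           direction = "ES-down"),
      list(main = factors$myc[1], cofactor = 3L, cluster = "Myc",
           direction = "ES-down"),
      list(main = character(), cofactor = 4L, cluster = "uniformly-high",
           direction = "ES-up")
    )
  }
  cfg <- as.list(environment())
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate genome sequence and gene annotation
#'
#' Bases are i.i.d. at the configured GC; contiguous lowercase repeat
#' tracts (exponential lengths, mean 1 kb) cover the repeat fraction
#' within 2 percentage points; TSSs are evenly spaced with +/-10% jitter,
#' at least 10 kb apart.  Cofactor genes (`cofNN`) are appended after the
#' regular genes (`gNNNN`).
#'
#' @param config a [synthetic_config()].
#' @param seed RNG seed (defaults to `config$seed + 1`).
#' @return list with `genome` and `genes`.
#' @export
generate_genome <- function(config, seed = config$seed + 1L) {
  n_tot <- config$n_genes + config$n_cofactors
  per_chrom <- ceiling(n_tot / config$n_chromosomes)
  spacing <- config$chrom_length / (per_chrom + 1)
  if (0.8 * spacing < 1e4) {
    stopf("infeasible TSS spacing: %d genes on %g bp chromosomes", n_tot, config$chrom_length)
  }
  local_seed(seed, {
    genome <- character(config$n_chromosomes)
    names(genome) <- sprintf("chr%d", seq_len(config$n_chromosomes))
    tss <- integer(0); chrom <- character(0)
    base_codes <- utf8ToInt("ACGT")
    for (c in seq_len(config$n_chromosomes)) {
      len <- as.integer(config$chrom_length)
      p <- c(A = (1 - config$gc) / 2, C = config$gc / 2,
             G = config$gc / 2, T = (1 - config$gc) / 2)
      codes <- sample(base_codes, len, replace = TRUE, prob = p)
      if (config$repeat_fraction > 0) {
        masked <- logical(len)
        target <- config$repeat_fraction * len
        covered <- 0L
        while (covered < target) {
          tract <- max(50L, as.integer(rexp(1, 1 / 1000)))
          s <- sample.int(len - tract, 1L)
          span <- s:(s + tract - 1L)
          covered <- covered + sum(!masked[span])
          masked[span] <- TRUE
        }
        codes[masked] <- codes[masked] + 32L   # to lowercase
      }
      seq_str <- intToUtf8(codes)
      Encoding(seq_str) <- "unknown"   # pure ASCII; avoid UTF-8 O(n) substr
      genome[c] <- seq_str
      k <- min(per_chrom, n_tot - length(tss))
      if (k > 0) {
        pos <- round(spacing * seq_len(k) +
                       runif(k, -0.1 * spacing, 0.1 * spacing))
        tss <- c(tss, as.integer(pos))
        chrom <- c(chrom, rep(names(genome)[c], k))
      }
    }
    ids <- c(sprintf("g%04d", seq_len(config$n_genes)),
             sprintf("cof%02d", seq_len(config$n_cofactors)))
    genes <- data.frame(gene_id = ids, chrom = chrom, tss = tss,
                        strand = sample(c("+", "-"), n_tot, replace = TRUE),
                        stringsAsFactors = FALSE)
    list(genome = genome, genes = genes)
  })
}

#' Assign ground-truth cluster and expression labels
#'
#' @param config a [synthetic_config()].
#' @param genes annotation from [generate_genome()].
#' @param seed RNG seed.
#' @return `data.frame`: gene_id, cluster, es_label; cofactor genes are
#'   uniformly-low and neutral.
#' @export
assign_truth_labels <- function(config, genes, seed = config$seed + 2L) {
  local_seed(seed, {
    n <- config$n_genes
    counts <- diff(c(0, round(cumsum(config$cluster_probs) * n)))
    cluster <- sample(rep(names(config$cluster_probs), counts))
    es <- rep("neutral", n)
    for (cl in setdiff(CLUSTER_LABELS, "uniformly-low")) {
      idx <- which(cluster == cl)
      n_up <- round(config$es_up_frac * length(idx))
      n_down <- round(config$es_down_frac * length(idx))
      pick <- sample(idx)
      es[pick[seq_len(n_up)]] <- "ES-up"
      es[pick[n_up + seq_len(n_down)]] <- "ES-down"
    }
    data.frame(gene_id = genes$gene_id,
               cluster = c(cluster, rep("uniformly-low", config$n_cofactors)),
               es_label = c(es, rep("neutral", config$n_cofactors)),
               stringsAsFactors = FALSE)
  })
}

cluster_on_groups <- function(cluster, factors) {
  switch(cluster,
         "uniformly-high" = c(factors$oct4, factors$myc),
         "Oct4" = factors$oct4,
         "Oct4-moderate" = factors$oct4,
         "Myc" = factors$myc,
         "uniformly-low" = character())
}

#' Generate per-factor ChIP-seq peaks
#'
#' Each gene receives a pool of 4-6 shared "anchor" positions at
#' exponential (mean `peak_dist_mean`) distances from its TSS; every main
#' factor whose group is "on" in the gene's designed cluster places 2-4
#' peaks on a random subset of the pool with a small jitter
#' (<= `co_jitter` bp), so peaks of co-binding factors are co-located and
#' the neighborhood merge rule joins them, while each factor's distance
#' noise stays partially independent.  Oct4-moderate genes bind only 2 of
#' the Oct4-group factors at reduced intensity.  "Off" factors receive a
#' single peak near the gene with probability `off_peak_prob`.
#' Intensities are log-normal.
#'
#' @param config a [synthetic_config()].
#' @param genes gene annotation.
#' @param truth label table from [assign_truth_labels()].
#' @param seed RNG seed.
#' @return list with `peaks` and `anchors` (per-gene anchor table, kept
#'   in the ground truth for site planting).
#' @export
generate_peaks <- function(config, genes, truth, seed = config$seed + 3L) {
  all_factors <- c(config$factors$oct4, config$factors$myc)
  chrom_len <- config$chrom_length
  local_seed(seed, {
    rows <- list(); anchor_rows <- list()
    # planted combinations whose targets must carry co-located peaks of
    # every combination factor on >= 2 shared anchors
    forced <- lapply(config$planted, function(pl) {
      list(main = pl$main,
           targets = truth$gene_id[truth$cluster == pl$cluster &
                                     truth$es_label == pl$direction])
    })
    for (i in seq_len(nrow(genes))) {
      cl <- truth$cluster[i]
      on <- cluster_on_groups(cl, config$factors)
      scale <- 1
      if (cl == "Oct4-moderate") {
        on <- sample(config$factors$oct4, config$moderate_n_factors)
        scale <- config$moderate_scale
      }
      must <- character()
      for (fc in forced) {
        if (genes$gene_id[i] %in% fc$targets) must <- union(must, fc$main)
      }
      on <- union(on, must)
      if (length(on)) {
        npool <- sample(seq(config$anchor_pool_range[1],
                            config$anchor_pool_range[2]), 1L)
        d <- pmin(rexp(npool, 1 / config$peak_dist_mean), 9e5)
        side <- sample(c(-1, 1), npool, replace = TRUE)
        anchors <- pmin(pmax(round(genes$tss[i] + side * d), 500), chrom_len - 500)
        # nearest anchors first, so forced planted co-binding (anchors 1-2)
        # stays closer to this gene's TSS than to any neighbor's
        anchors <- anchors[order(abs(anchors - genes$tss[i]))]
        anchor_rows[[length(anchor_rows) + 1L]] <- data.frame(
          gene_id = genes$gene_id[i], chrom = genes$chrom[i],
          anchor = as.integer(anchors), stringsAsFactors = FALSE)
        for (f in on) {
          k <- min(sample(seq(config$n_anchors_range[1],
                              config$n_anchors_range[2]), 1L), npool)
          sel <- sample(npool, k)
          # factors of a planted combination share the first two anchors
          if (f %in% must) sel <- union(1:2, sel)[seq_len(max(k, 2L))]
          jit <- round(runif(length(sel), -config$co_jitter, config$co_jitter))
          rows[[length(rows) + 1L]] <- data.frame(
            factor = f, chrom = genes$chrom[i],
            center = as.integer(anchors[sel] + jit),
            intensity = scale * rlnorm(length(sel), config$intensity_meanlog,
                                       config$intensity_sdlog),
            stringsAsFactors = FALSE)
        }
      }
      off <- setdiff(all_factors, on)
      for (f in off) {
        if (runif(1) < config$off_peak_prob) {
          d <- min(rexp(1, 1 / config$peak_dist_mean), 9e5)
          pos <- min(max(round(genes$tss[i] + sample(c(-1, 1), 1) * d), 500),
                     chrom_len - 500)
          rows[[length(rows) + 1L]] <- data.frame(
            factor = f, chrom = genes$chrom[i], center = as.integer(pos),
            intensity = rlnorm(1, config$intensity_meanlog,
                               config$intensity_sdlog),
            stringsAsFactors = FALSE)
        }
      }
    }
    peaks <- do.call(rbind, rows)
    peaks <- peaks[order(peaks$factor, peaks$chrom, peaks$center), , drop = FALSE]
    rownames(peaks) <- NULL
    list(peaks = peaks, anchors = do.call(rbind, anchor_rows))
  })
}

#' Generate cofactor PWMs
#'
#' Informative PWMs: each column puts `pwm_dominant` probability on one
#' random base.  Motif k maps to cofactor gene `cofNN`.
#' @param config a [synthetic_config()].
#' @param seed RNG seed.
#' @export
generate_pwms <- function(config, seed = config$seed + 4L) {
  local_seed(seed, {
    lapply(seq_len(config$n_cofactors), function(k) {
      m <- matrix((1 - config$pwm_dominant) / 3, 4, config$pwm_width)
      dom <- sample.int(4, config$pwm_width, replace = TRUE)
      for (j in seq_len(config$pwm_width)) m[dom[j], j] <- config$pwm_dominant
      pwm_record(sprintf("M%03d_COF%02d", k, k), m, sprintf("cof%02d", k))
    })
  })
}

#' Assign cofactor expression statuses
#'
#' Planted cofactors get the status their planted direction implies
#' (P for ES-up features, N for ES-down); the rest draw from
#' P/N/H/other.
#' @param config a [synthetic_config()].
#' @param seed RNG seed.
#' @export
assign_cofactor_status <- function(config, seed = config$seed + 5L) {
  local_seed(seed, {
    status <- sample(c("P", "N", "H", "other"), config$n_cofactors,
                     replace = TRUE)
    for (pl in config$planted) {
      status[pl$cofactor] <- if (pl$direction == "ES-up") "P" else "N"
    }
    data.frame(gene_id = sprintf("cof%02d", seq_len(config$n_cofactors)),
               status = status, stringsAsFactors = FALSE)
  })
}

#' Plant cofactor motif instances near target genes
#'
#' For each planted (combination, gene set), consensus-sampled motif
#' instances (bases drawn per PWM column) are written in uppercase into
#' the genome within 250 bp of every co-located peak pair of the
#' combination's main factors (any co-located pair for w = 0) within
#' 1 Mb of each target gene's TSS, so a target typically carries one
#' instance per co-binding island (2-4).  Targets with no eligible peak
#' pair are skipped with a warning and recorded.
#'
#' @param genome named character vector (modified copy returned).
#' @param peaks peak table.
#' @param pwms PWM list.
#' @param planted planted feature list (see [synthetic_config()]).
#' @param genes,truth annotation and label table defining target sets.
#' @param seed RNG seed.
#' @return list with `genome`, `planted_sites` (gene, feature, position)
#'   and `skipped`.
#' @export
plant_cofactor_sites <- function(genome, peaks, pwms, planted, genes, truth,
                                 seed = 1L) {
  if (!length(planted)) {
    return(list(genome = genome, planted_sites = NULL, skipped = character()))
  }
  local_seed(seed, {
    site_rows <- list(); skipped <- character()
    for (pl in planted) {
      pwm <- pwms[[pl$cofactor]]
      w <- ncol(pwm$matrix)
      fname <- feature_name(pl$main, pwm$name)
      targets <- truth$gene_id[truth$cluster == pl$cluster &
                                 truth$es_label == pl$direction]
      for (g in targets) {
        gi <- match(g, genes$gene_id)
        near <- peaks[peaks$chrom == genes$chrom[gi] &
                        abs(peaks$center - genes$tss[gi]) <= 1e6, , drop = FALSE]
        islands <- build_neighborhoods(near, extend = 500L, merge_dist = 500L,
                                       min_peaks = 2L)
        # an island is eligible only if it carries the combination's factors
        # AND the target is its nearest TSS -- instances belong to the
        # target's own co-binding islands, not a neighbor's
        tss_chr <- genes$tss[genes$chrom == genes$chrom[gi]]
        ok <- vapply(islands, function(nb) {
          all(pl$main %in% nb$peaks$factor) &&
            abs(nb$center - genes$tss[gi]) <= min(abs(nb$center - tss_chr))
        }, TRUE)
        islands <- islands[ok]
        if (!length(islands)) {
          warnf("no eligible peak pair near target gene %s for %s; skipped", g, fname)
          skipped <- c(skipped, sprintf("%s:%s", fname, g))
          next
        }
        for (nb in islands) {
          pos <- nb$center + sample(seq(-250L, 250L - w), 1L)
          pos <- min(max(pos, 0L), nchar(genome[[nb$chrom]]) - w)
          inst <- paste(vapply(seq_len(w), function(j) {
            sample(BASES, 1L, prob = pwm$matrix[, j])
          }, ""), collapse = "")
          site_rows[[length(site_rows) + 1L]] <- data.frame(
            feature = fname, gene_id = g, chrom = nb$chrom, position = pos,
            instance = inst, stringsAsFactors = FALSE)
        }
      }
    }
    planted_sites <- if (length(site_rows)) do.call(rbind, site_rows) else NULL
    # apply all edits per chromosome in one pass (substr<- copies the
    # whole chromosome string on every call)
    if (!is.null(planted_sites)) {
      for (chr in unique(planted_sites$chrom)) {
        codes <- utf8ToInt(genome[[chr]])
        ps <- planted_sites[planted_sites$chrom == chr, , drop = FALSE]
        for (r in seq_len(nrow(ps))) {
          codes[ps$position[r] + seq_len(nchar(ps$instance[r]))] <-
            utf8ToInt(ps$instance[r])
        }
        seq_str <- intToUtf8(codes)
        Encoding(seq_str) <- "unknown"
        genome[[chr]] <- seq_str
      }
      planted_sites$instance <- NULL
    }
    list(genome = genome, planted_sites = planted_sites, skipped = skipped)
  })
}

#' Generate two-stage expression (and the validation set)
#'
#' log2 expression is Normal(baseline +/- effect/2 by stage and label,
#' noise sd), exponentiated to the raw index scale.  Cofactor genes
#' follow their assigned status: P/N are +/- 2 log2 units between stages,
#' H sits at a high baseline (both stage means > 500), "other" at a low
#' one.  The validation matrix mimics a day-0 versus day-4-6 design; with
#' `concordant = FALSE` each gene's direction is drawn at random,
#' independent of the truth.
#'
#' @param config a [synthetic_config()].
#' @param truth label table.
#' @param cof_status cofactor status table.
#' @param seed RNG seed.
#' @param validation generate the validation-shaped matrix?
#' @param concordant validation directions follow the truth?
#' @return an `expr_matrix`.
#' @export
generate_expression <- function(config, truth, cof_status,
                                seed = config$seed + 6L,
                                validation = FALSE, concordant = TRUE) {
  n_es <- if (validation) config$n_es_val else config$n_es
  n_df <- if (validation) config$n_df_val else config$n_df
  effect <- if (validation) config$effect_val else config$effect
  noise <- if (validation) config$noise_val else config$noise
  local_seed(seed, {
    n <- nrow(truth)
    baseline <- rnorm(n, 7, 1)
    delta <- numeric(n)               # log2(ES) - log2(DF)
    delta[truth$es_label == "ES-up"] <- effect
    delta[truth$es_label == "ES-down"] <- -effect
    ci <- match(cof_status$gene_id, truth$gene_id)
    baseline[ci] <- ifelse(cof_status$status == "H", 10.5,
                           ifelse(cof_status$status == "other", 5, 9))
    delta[ci] <- ifelse(cof_status$status == "P", 2,
                        ifelse(cof_status$status == "N", -2, 0))
    if (!concordant) delta <- abs(delta) * sample(c(-1, 1), n, replace = TRUE)
    mu_es <- baseline + delta / 2
    mu_df <- baseline - delta / 2
    vals <- cbind(
      matrix(rnorm(n * n_es, mu_es, noise), n, n_es),
      matrix(rnorm(n * n_df, mu_df, noise), n, n_df)
    )
    vals <- 2^vals
    rownames(vals) <- truth$gene_id
    colnames(vals) <- c(sprintf("ES%d", seq_len(n_es)),
                        sprintf("DF%d", seq_len(n_df)))
    expression_matrix(vals, rep(c("ES", "DF"), c(n_es, n_df)))
  })
}

#' Generate a complete synthetic bundle
#'
#' Runs the generators in order with child seeds fanned out from the
#' master seed, planting motif instances after peaks exist.
#' @param config a [synthetic_config()].
#' @return list with `genome`, `genes`, `peaks`, `pwms`, `expr`,
#'   `validation`, `truth` (labels, cofactor statuses, planted sites,
#'   anchors, skips) and `config`.
#' @export
generate_bundle <- function(config = synthetic_config()) {
  gg <- generate_genome(config)
  truth <- assign_truth_labels(config, gg$genes)
  pk <- generate_peaks(config, gg$genes, truth)
  pwms <- generate_pwms(config)
  cof_status <- assign_cofactor_status(config)
  pl <- plant_cofactor_sites(gg$genome, pk$peaks, pwms, config$planted,
                             gg$genes, truth, seed = config$seed + 7L)
  expr <- generate_expression(config, truth, cof_status)
  val <- generate_expression(config, truth, cof_status,
                             seed = config$seed + 8L, validation = TRUE)
  planted_features <- lapply(config$planted, function(p) {
    list(main = p$main, motif = pwms[[p$cofactor]]$name,
         cofactor_gene = sprintf("cof%02d", p$cofactor),
         w = length(p$main), cluster = p$cluster, direction = p$direction,
         name = feature_name(p$main, pwms[[p$cofactor]]$name))
  })
  list(genome = pl$genome, genes = gg$genes, peaks = pk$peaks, pwms = pwms,
       expr = expr, validation = val,
       truth = list(labels = truth, cofactor_status = cof_status,
                    planted = planted_features, planted_sites = pl$planted_sites,
                    anchors = pk$anchors, skipped = pl$skipped),
       config = config)
}

#' Write a bundle to disk in the formats the readers consume
#'
#' Emits genome.fa, genes.tsv, peaks_FACTOR.tsv, pwms.txt,
#' expression.tsv, validation.tsv, the ground-truth tables and a
#' machine-readable config echo (config.json).
#' @param bundle from [generate_bundle()].
#' @param dir output directory.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_genome(bundle$genome, file.path(dir, "genome.fa"))
  write_genes(bundle$genes, file.path(dir, "genes.tsv"))
  for (f in unique(bundle$peaks$factor)) {
    write_peaks(bundle$peaks[bundle$peaks$factor == f, ],
                file.path(dir, sprintf("peaks_%s.tsv", f)))
  }
  write_pwm(bundle$pwms, file.path(dir, "pwms.txt"))
  write_expression(bundle$expr, file.path(dir, "expression.tsv"))
  write_expression(bundle$validation, file.path(dir, "validation.tsv"))
  write_tsv(bundle$truth$labels, file.path(dir, "truth_labels.tsv"))
  write_tsv(bundle$truth$cofactor_status, file.path(dir, "truth_cofactor_status.tsv"))
  if (!is.null(bundle$truth$planted_sites)) {
    write_tsv(bundle$truth$planted_sites, file.path(dir, "truth_planted_sites.tsv"))
  }
  cfg <- bundle$config
  class(cfg) <- NULL
  cfg$factors <- as.list(cfg$factors)
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
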