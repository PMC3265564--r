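#' Pipeline configuration
#'
#' Houses every tunable constant of the analysis, each defaulting to its
#' published value: decay constant d0 = 5000 bp, association window
#' d = 1e6 bp, neighborhood extend/merge = 500 bp with a 2-peak minimum,
#' 20 matched controls per neighborhood, motif cutoff tail probability
#' 9.09e-5, fold-change threshold 2 at test level 0.05, uniformly-high
#' expression floor 500, FDR 10%, top-feature cap 20, 10 CV folds, and
#' k-means with k = 5.
#'
#' @param seed master seed; per-stage child seeds are fixed offsets.
#' @param d0,window,extend,merge_dist,min_peaks,n_controls,motif_p
#'   genomic-stage constants (see above).
#' @param fc_threshold,alpha,h_floor,fdr_q expression/test constants.
#' @param kmax,folds,k,kmeans_restarts selection and clustering constants.
#' @param bg_pseudocount,min_informative background-model constants.
#' @export
pipeline_config <- function(seed = 1L, d0 = 5000, window = 1e6,
                            extend = 500L, merge_dist = 500L, min_peaks = 2L,
                            n_controls = 20L, motif_p = 9.09e-5,
                            fc_threshold = 2, alpha = 0.05, h_floor = 500,
                            fdr_q = 0.10, kmax = 20L, folds = 10L, k = 5L,
                            kmeans_restarts = 25L, bg_pseudocount = 0.5,
                            min_informative = 200L) {
  cfg <- as.list(environment())
  stopifnot(all(vapply(cfg[setdiff(names(cfg), "seed")], function(v) v > 0, TRUE)))
  class(cfg) <- "pipeline_config"
  cfg
}

PIPELINE_STAGES <- c("associate", "es", "neighborhoods", "scan", "features",
                     "tests", "classify", "targets", "validate")

#' Run the full analysis pipeline
#'
#' Executes the stages in order -- association scoring and gene
#' clustering, ES gene calling, neighborhood construction, motif
#' scanning, feature scoring, significance testing, classification-based
#' feature selection, target prediction and expression validation -- on
#' an input bundle (synthetic or read from disk).  A subset of stages can
#' be re-run against a previous result (`resume`), reusing its cached
#' upstream artifacts.
#'
#' @param bundle input bundle (see [generate_bundle()] / [read_bundle()]).
#' @param config a [pipeline_config()].
#' @param stages character vector of stages to (re)compute, or "all".
#' @param resume previous result to reuse for stages not recomputed.
#' @param outdir optional directory: result tables and a run manifest are
#'   written there.
#' @return list with `association`, `clusters`, `es_status`,
#'   `per_cluster` (neighborhoods, thresholds, score matrices, tests,
#'   selection, model), `significant`, `selection`, `targets`,
#'   `validation` and `manifest`.
#' @export
run_pipeline <- function(bundle, config = pipeline_config(), stages = "all",
                         resume = NULL, outdir = NULL) {
  if (identical(stages, "all")) stages <- PIPELINE_STAGES
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad)) stopf("unknown stage(s): %s", paste(bad, collapse = ", "))
  res <- resume %||% list(per_cluster = list())
  groups <- bundle$config$factors %||%
    list(oct4 = grep("Oct4|Sox|Nanog|STAT|Smad|Tcf|Esrrb", unique(bundle$peaks$factor), value = TRUE),
         myc = grep("Myc|Zfx|E2f", unique(bundle$peaks$factor), value = TRUE))
  need <- function(what, stage) {
    if (is.null(res[[what]])) stopf("stage '%s' needs artifact '%s'; run its stage first", stage, what)
    res[[what]]
  }

  if ("associate" %in% stages) {
    raw <- association_scores(bundle$peaks, bundle$genes,
                              d0 = config$d0, window = config$window)
    norm <- normalize_association(raw)
    res$association <- norm
    res$association_raw <- raw
    res$clusters <- cluster_genes(norm, groups, k = config$k,
                                  restarts = config$kmeans_restarts,
                                  seed = config$seed + 10L)
  }
  if ("es" %in% stages) {
    res$es_status <- call_es_genes(bundle$expr, fc_threshold = config$fc_threshold,
                                   alpha = config$alpha, h_floor = config$h_floor)
  }

  clusters <- need("clusters", "neighborhoods")
  es_status <- need("es_status", "neighborhoods")
  active <- setdiff(unique(clusters$table$name), "uniformly-low")
  pc <- res$per_cluster

  if ("neighborhoods" %in% stages) {
    for (cl in active) {
      foi <- clusters$factors_of_interest[[cl]]
      sub <- bundle$peaks[bundle$peaks$factor %in% foi, , drop = FALSE]
      nb <- build_neighborhoods(sub, extend = config$extend,
                                merge_dist = config$merge_dist,
                                min_peaks = config$min_peaks)
      pc[[cl]] <- list(factors_of_interest = foi, neighborhoods = nb,
                       assoc_map = associate_neighborhoods(nb, bundle$genes,
                                                           d = config$window))
    }
  }
  if ("scan" %in% stages) {
    keep <- motif_preselect(bundle$pwms, es_status)
    for (ci in seq_along(active)) {
      cl <- active[ci]
      cs <- call_sites(pc[[cl]]$neighborhoods, keep, bundle$genome,
                       bundle$genes, p = config$motif_p,
                       n_controls = config$n_controls,
                       seed = config$seed + 1000L * ci,
                       pseudocount = config$bg_pseudocount,
                       min_informative = config$min_informative)
      pc[[cl]]$neighborhoods <- cs$nbhds
      pc[[cl]]$thresholds <- cs$thresholds
      pc[[cl]]$pwms <- keep
    }
  }
  if ("features" %in% stages) {
    for (cl in active) {
      motifs <- pc[[cl]]$thresholds$motif
      foi <- pc[[cl]]$factors_of_interest
      combos <- list()
      for (w in 0:min(2, length(foi))) {
        combos <- c(combos, enumerate_combinations(foi, motifs, w))
      }
      es_genes <- cluster_es_genes(clusters, es_status, cl)
      gsub_ <- bundle$genes[bundle$genes$gene_id %in% es_genes, , drop = FALSE]
      pc[[cl]]$combos <- combos
      pc[[cl]]$score_matrix <- build_score_matrix(gsub_, pc[[cl]]$neighborhoods,
                                                  pc[[cl]]$assoc_map, combos,
                                                  d0 = config$d0)
    }
  }
  if ("tests" %in% stages) {
    sig_rows <- list()
    for (cl in active) {
      sm <- pc[[cl]]$score_matrix
      es_class <- setNames(es_status$es_class, es_status$gene_id)[rownames(sm)]
      if (!nrow(sm) || !ncol(sm)) {
        pc[[cl]]$labeled <- NULL
        next
      }
      tests <- test_features(sm, es_class)
      wmap <- setNames(vapply(pc[[cl]]$combos, `[[`, 0L, "w"),
                       vapply(pc[[cl]]$combos, `[[`, "", "name"))
      tests$w <- wmap[tests$feature]
      labeled <- label_features(tests, q = config$fdr_q)
      pc[[cl]]$tests <- tests
      pc[[cl]]$labeled <- labeled
      sig <- labeled[labeled$label != "none", , drop = FALSE]
      if (nrow(sig)) {
        sig_rows[[cl]] <- significant_table(sig, cl, pc[[cl]]$combos,
                                            bundle$pwms, es_status)
      }
    }
    res$significant <- if (length(sig_rows)) do.call(rbind, c(sig_rows, make.row.names = FALSE)) else NULL
  }
  if ("classify" %in% stages) {
    sel_rows <- list()
    for (cl in active) {
      pc[[cl]]$selection <- NULL
      sm <- pc[[cl]]$score_matrix
      if (is.null(sm) || !nrow(sm)) next
      es_class <- setNames(es_status$es_class, es_status$gene_id)[rownames(sm)]
      y <- as.integer(es_class == "ES-up")
      if (min(table(factor(y, 0:1))) < 2) next
      labeled <- pc[[cl]]$labeled %||%
        data.frame(feature = character(), w = integer(), label = character(),
                   p_label = numeric(), test_label = character())
      main_scores <- res$association$scores[rownames(sm),
                                            pc[[cl]]$factors_of_interest,
                                            drop = FALSE]
      sel <- select_features(labeled, sm, main_scores, y, kmax = config$kmax,
                             folds = config$folds, seed = config$seed + 20L)
      pc[[cl]]$selection <- sel
      sel_rows[[cl]] <- data.frame(
        cluster = cl, w_up = sel$best$w_up, w_down = sel$best$w_down,
        k1 = sel$best$k1, k2 = sel$best$k2,
        cv_error = sel$best$cv_error, cv_se = sel$best$cv_se,
        baseline_error = sel$baseline$error, baseline_se = sel$baseline$se,
        features = paste(c(sel$best$features_up$feature,
                           sel$best$features_down$feature), collapse = ","),
        stringsAsFactors = FALSE)
    }
    res$selection <- if (length(sel_rows)) do.call(rbind, c(sel_rows, make.row.names = FALSE)) else NULL
  }
  if ("targets" %in% stages) {
    tgt_rows <- list()
    for (cl in active) {
      sel <- pc[[cl]]$selection
      if (is.null(sel)) next
      chosen <- rbind(sel$best$features_up, sel$best$features_down)
      if (!nrow(chosen)) next
      sm <- pc[[cl]]$score_matrix
      es_class <- setNames(es_status$es_class, es_status$gene_id)[rownames(sm)]
      y <- as.integer(es_class == "ES-up")
      main_scores <- res$association$scores[rownames(sm),
                                            pc[[cl]]$factors_of_interest,
                                            drop = FALSE]
      x <- cbind(sm[, chosen$feature, drop = FALSE], main_scores)
      modes <- c(ifelse(chosen$test_label == "proportion", "ind", "cont_ind"),
                 rep("cont", ncol(main_scores)))
      model <- fit_nb(x, y, modes)
      pc[[cl]]$model <- model
      pc[[cl]]$model_x <- x
      motif_of <- setNames(vapply(pc[[cl]]$combos, `[[`, "", "motif"),
                           vapply(pc[[cl]]$combos, `[[`, "", "name"))
      for (r in seq_len(nrow(chosen))) {
        tg <- predict_targets(model, x, es_class, chosen$feature[r],
                              chosen$label[r])
        if (nrow(tg)) {
          tg$cluster <- cl
          tg$direction <- chosen$label[r]
          tg$motif <- motif_of[[chosen$feature[r]]]
          tgt_rows[[length(tgt_rows) + 1L]] <- tg
        }
      }
    }
    res$targets <- if (length(tgt_rows)) do.call(rbind, c(tgt_rows, make.row.names = FALSE)) else NULL
  }
  if ("validate" %in% stages) {
    res$validation <- validate_all(res$targets, bundle, es_status,
                                   config$fc_threshold, config$h_floor)
  }

  res$per_cluster <- pc
  res$manifest <- list(
    package_version = as.character(utils::packageVersion("cobindcode")),
    seed = config$seed,
    config = unclass(config),
    stages_run = stages,
    counts = list(
      genes = nrow(bundle$genes),
      clusters = length(active),
      neighborhoods = sum(vapply(pc, function(p) length(p$neighborhoods), 0L)),
      significant_features = if (is.null(res$significant)) 0L else nrow(res$significant)
    )
  )
  if (!is.null(outdir)) {
    write_results(res, outdir)
    jsonlite::write_json(res$manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}

# motifs whose mapped cofactor gene shows P, N or H expression status
motif_preselect <- function(pwms, es_status) {
  status <- setNames(es_status$status, es_status$gene_id)
  keep <- vapply(pwms, function(p) {
    any(status[p$cofactor_genes] %in% c("P", "N", "H"), na.rm = TRUE)
  }, TRUE)
  pwms[keep]
}

cluster_es_genes <- function(clusters, es_status, cl) {
  in_cl <- clusters$table$gene_id[clusters$table$name == cl]
  es <- es_status$gene_id[es_status$es_class %in% c("ES-up", "ES-down")]
  intersect(in_cl, es)
}

significant_table <- function(sig, cl, combos, pwms, es_status) {
  motif_of <- setNames(vapply(combos, `[[`, "", "motif"),
                       vapply(combos, `[[`, "", "name"))
  genes_of <- setNames(lapply(pwms, `[[`, "cofactor_genes"),
                       vapply(pwms, `[[`, "", "name"))
  status <- setNames(es_status$status, es_status$gene_id)
  rows <- list()
  for (r in seq_len(nrow(sig))) {
    motif <- motif_of[[sig$feature[r]]]
    cgs <- genes_of[[motif]] %||% NA_character_
    if (!length(cgs)) cgs <- NA_character_
    for (cg in cgs) {
      st <- lookup(status, cg, "other")
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl, direction = ifelse(sig$label[r] == "ES-up", "U", "D"),
        feature = sig$feature[r], w = sig$w[r], cofactor_gene = cg,
        status = st, role = reason_role(sig$label[r], st),
        p_value = sig$p_label[r], test = sig$test_label[r],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

validate_all <- function(targets, bundle, es_status, fc_threshold, h_floor) {
  if (is.null(targets) || !nrow(targets)) return(NULL)
  val_status_df <- call_es_genes(bundle$validation, fc_threshold = fc_threshold,
                                 h_floor = h_floor)
  val_status <- setNames(val_status_df$status, val_status_df$gene_id)
  prim_status <- setNames(es_status$status, es_status$gene_id)
  motif_genes <- setNames(lapply(bundle$pwms, `[[`, "cofactor_genes"),
                          vapply(bundle$pwms, `[[`, "", "name"))
  rows <- list()
  for (key in unique(paste(targets$cluster, targets$feature))) {
    tg <- targets[paste(targets$cluster, targets$feature) == key, , drop = FALSE]
    motif <- tg$motif[1]
    for (cg in (motif_genes[[motif]] %||% character())) {
      sp <- lookup(prim_status, cg, "other")
      sv <- lookup(val_status, cg, "other")
      matched <- sp %in% c("P", "N", "H") && sv %in% c("P", "N", "H") &&
        match_status(sp, sv)
      role <- reason_role(tg$direction[1], sp)
      if (is.na(role)) matched <- FALSE
      vs <- validate_targets(tg, role, bundle$validation, matched = matched)
      vs$cluster <- tg$cluster[1]
      vs$cofactor_gene <- cg
      vs$status_validation <- sv
      rows[[length(rows) + 1L]] <- vs
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Read an input bundle from a directory written by [write_bundle()]
#' @param dir bundle directory.
#' @export
read_bundle <- function(dir) {
  peak_files <- list.files(dir, pattern = "^peaks_.*\\.tsv$", full.names = TRUE)
  peaks <- do.call(rbind, lapply(peak_files, function(f) {
    read_peaks(f, sub("^peaks_(.*)\\.tsv$", "\\1", basename(f)))
  }))
  cfg <- NULL
  cfg_path <- file.path(dir, "config.json")
  if (file.exists(cfg_path)) {
    cfg <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
  }
  list(genome = read_genome(file.path(dir, "genome.fa")),
       genes = read_genes(file.path(dir, "genes.tsv")),
       peaks = peaks,
       pwms = read_pwm(file.path(dir, "pwms.txt")),
       expr = read_expression(file.path(dir, "expression.tsv")),
       validation = read_expression(file.path(dir, "validation.tsv")),
       config = cfg)
}
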