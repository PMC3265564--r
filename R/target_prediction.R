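#' Target prediction and expression validation
#'
#' A gene is predicted to be a target of the TF combination behind a
#' selected feature when (1) its class matches the feature's direction
#' (ES-up gene for an ES-up feature, ES-down for ES-down) and (2)
#' removing the feature's term from the naive Bayes probability ratio
#' moves the ratio in the expected direction (a decrease for ES-up
#' features, an increase for ES-down).  Predicted targets are then
#' checked in an independent two-stage expression set: targets of an ES
#' activator and/or DF repressor should drop after differentiation
#' (fold change ES/DF > 1), targets of an ES repressor and/or DF
#' activator should rise.
#'
#' @name target_prediction
NULL

#' Predict target genes of a selected feature
#'
#' @param model `nb_model` trained on all the cluster's ES genes with the
#'   selected predictors.
#' @param x genes x predictors matrix used for the fit.
#' @param es_class named per-gene class in {ES-up, ES-down}, aligned with
#'   `x` rows.
#' @param feature name of the predictor to perturb (must be a model
#'   predictor).
#' @param direction the feature's label, "ES-up" or "ES-down".
#' @return `data.frame` of targets ranked by |log ratio fold change|
#'   descending: feature, gene_id, ratio_with, ratio_without, ratio_fc,
#'   rank.
#' @export
predict_targets <- function(model, x, es_class, feature, direction) {
  j <- match(feature, names(model$fits))
  if (is.na(j)) stopf("feature %s is not among the model predictors", feature)
  rows <- list()
  for (i in seq_len(nrow(x))) {
    if (es_class[i] != direction) next
    term <- exp(predictor_log_term(model$fits[[j]], x[i, j]))
    hit <- if (direction == "ES-up") term > 1 else term < 1
    if (!hit) next
    rw <- nb_ratio(model, x[i, ])
    rows[[length(rows) + 1L]] <- data.frame(
      feature = feature, gene_id = rownames(x)[i],
      ratio_with = rw, ratio_without = rw / term, ratio_fc = term,
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) {
    return(data.frame(feature = character(), gene_id = character(),
                      ratio_with = numeric(), ratio_without = numeric(),
                      ratio_fc = numeric(), rank = integer()))
  }
  out <- do.call(rbind, rows)
  out <- out[order(-abs(log(out$ratio_fc))), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Do cofactor expression statuses match across data sets?
#'
#' Equal statuses match; uniformly high (H) in either data set matches
#' any status, since it indicates potential functioning at both stages.
#' @param status_primary,status_validation statuses in {P, N, H}.
#' @export
match_status <- function(status_primary, status_validation) {
  status_primary == status_validation ||
    status_primary == "H" || status_validation == "H"
}

#' Validate predicted targets against an independent expression set
#'
#' @param targets target table from [predict_targets()].
#' @param role cofactor role (EA, ER, DA, DR, EA/DR, ER/DA).
#' @param validation_expr `expr_matrix` of the validation data set (ES =
#'   day-0-like stage, DF = late stage).
#' @param matched was the cofactor status matched across data sets (see
#'   [match_status()])?  Unmatched features are flagged and skipped.
#' @param floor detectability floor on mean validation expression
#'   (default 0, exclusive).
#' @return one-row `data.frame`: feature, matched, n_b (targets present
#'   in the validation set), n_e (with usable expression), pc (proportion
#'   with role-consistent fold change; fold change exactly 1 counts as
#'   inconsistent), fc quartiles.
#' @export
validate_targets <- function(targets, role, validation_expr, matched = TRUE,
                             floor = 0) {
  feature <- if (nrow(targets)) targets$feature[1] else NA_character_
  empty <- data.frame(feature = feature, role = role, matched = matched,
                      n_b = 0L, n_e = 0L, pc = NA_real_,
                      fc_q1 = NA_real_, fc_median = NA_real_, fc_q3 = NA_real_,
                      stringsAsFactors = FALSE)
  if (!matched || !nrow(targets)) return(empty)
  v <- validation_expr$values
  present <- targets$gene_id[targets$gene_id %in% rownames(v)]
  n_b <- length(present)
  if (!n_b) return(transform(empty, n_b = 0L))
  usable <- present[rowMeans(v[present, , drop = FALSE]) > floor]
  n_e <- length(usable)
  if (!n_e) return(transform(empty, n_b = n_b))
  mes <- rowMeans(v[usable, validation_expr$stage == "ES", drop = FALSE])
  mdf <- rowMeans(v[usable, validation_expr$stage == "DF", drop = FALSE])
  fc <- ifelse(mdf == 0, Inf, mes / mdf)
  expect_up <- role %in% c("EA", "DR", "EA/DR")
  consistent <- if (expect_up) fc > 1 else fc < 1
  q <- quantile(fc, c(0.25, 0.5, 0.75), names = FALSE)
  data.frame(feature = feature, role = role, matched = TRUE,
             n_b = n_b, n_e = n_e, pc = mean(consistent),
             fc_q1 = q[1], fc_median = q[2], fc_q3 = q[3],
             stringsAsFactors = FALSE)
}
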