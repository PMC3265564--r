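#' Naive Bayes gene classification
#'
#' Genes are classified as ES-up (Y = 1) versus ES-down (Y = 0) from
#' feature-score predictors.  Each predictor contributes
#' `P(Xj | Y) = (1 - lambda_jY)^(1 - Ij) * (lambda_jY f_jY(Xj))^Ij`,
#' where `Ij` indicates score existence, `lambda_jY` is the
#' (add-one-smoothed) probability that a class-Y gene carries a score and
#' `f_jY` a Gaussian kernel density estimate with Silverman's rule-of-
#' thumb bandwidth.  Predictors derived from the proportion test carry
#' only binary information, so their density term is dropped
#' (mode "ind"); main-factor association scores are always-present
#' continuous predictors (mode "cont"); rank-sum-derived feature scores
#' use both parts (mode "cont_ind").
#'
#' @name classification
NULL

#' Silverman's rule-of-thumb kernel bandwidth
#'
#' `h = 0.9 * min(sd, IQR / 1.34) * n^(-1/5)`, with a fallback of 0.1
#' when fewer than 2 points are available or the formula degenerates to
#' 0.
#' @param x numeric sample.
#' @export
silverman_bandwidth <- function(x) {
  n <- length(x)
  if (n < 2) return(0.1)
  s <- min(sd(x), (quantile(x, 0.75, names = FALSE) - quantile(x, 0.25, names = FALSE)) / 1.34)
  h <- 0.9 * s * n^(-1 / 5)
  if (!is.finite(h) || h <= 0) 0.1 else h
}

kde_eval <- function(x, train, h) {
  if (!length(train)) return(rep(1, length(x)))  # no in-class scores: neutral
  f <- vapply(x, function(v) mean(dnorm(v, mean = train, sd = h)), 0)
  pmax(f, 1e-300)
}

fit_predictor <- function(xj, y, mode) {
  present <- !is.na(xj)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  fit <- list(mode = mode,
              lambda1 = (sum(present & y == 1) + 1) / (n1 + 2),
              lambda0 = (sum(present & y == 0) + 1) / (n0 + 2))
  if (mode %in% c("cont_ind", "cont")) {
    fit$train1 <- xj[present & y == 1]
    fit$train0 <- xj[present & y == 0]
    fit$h1 <- silverman_bandwidth(fit$train1)
    fit$h0 <- silverman_bandwidth(fit$train0)
  }
  fit
}

# log P(Xj | Y=1) - log P(Xj | Y=0) for a vector of new values
predictor_log_term <- function(fit, xj_new) {
  present <- !is.na(xj_new)
  out <- numeric(length(xj_new))
  if (fit$mode == "cont") {
    out <- log(kde_eval(xj_new, fit$train1, fit$h1)) -
      log(kde_eval(xj_new, fit$train0, fit$h0))
    return(out)
  }
  out[!present] <- log(1 - fit$lambda1) - log(1 - fit$lambda0)
  if (any(present)) {
    lr <- log(fit$lambda1) - log(fit$lambda0)
    if (fit$mode == "cont_ind") {
      v <- xj_new[present]
      lr <- lr + log(kde_eval(v, fit$train1, fit$h1)) -
        log(kde_eval(v, fit$train0, fit$h0))
    }
    out[present] <- lr
  }
  out
}

#' Fit a naive Bayes model
#'
#' @param x genes x predictors numeric matrix; NA marks an absent feature
#'   score.
#' @param y 0/1 class labels (1 = ES-up); both classes must be present.
#' @param modes character vector per predictor: "cont_ind", "ind" or
#'   "cont".
#' @return an `nb_model` list with the class prior `p1` and per-predictor
#'   fits.
#' @export
fit_nb <- function(x, y, modes) {
  y <- as.integer(y)
  if (length(unique(y)) < 2) stopf("both classes must be present in training data")
  stopifnot(ncol(x) == length(modes))
  fits <- lapply(seq_len(ncol(x)), function(j) fit_predictor(x[, j], y, modes[j]))
  names(fits) <- colnames(x)
  structure(list(p1 = mean(y == 1), fits = fits), class = "nb_model")
}

#' Posterior probability ratio of a naive Bayes model
#'
#' `P(Y=1 | X) / P(Y=0 | X)`, computed in log space.  The predicted label
#' is ES-up iff the ratio is >= 1 (ties go to ES-up).
#' @param model an `nb_model`.
#' @param xrow named numeric vector of predictor values (NA = absent).
#' @param log return the log ratio?
#' @export
nb_ratio <- function(model, xrow, log = FALSE) {
  lr <- log(model$p1) - log(1 - model$p1)
  for (j in seq_along(model$fits)) {
    lr <- lr + unname(predictor_log_term(model$fits[[j]], xrow[j]))
  }
  if (log) lr else exp(lr)
}

#' Per-predictor multiplicative terms of the probability ratio
#'
#' Returns the factor each predictor contributes to [nb_ratio()]; removing
#' predictor j divides the ratio by exactly this factor.
#' @param model an `nb_model`.
#' @param xrow predictor values for one gene.
#' @export
nb_terms <- function(model, xrow) {
  vapply(seq_along(model$fits),
         function(j) exp(unname(predictor_log_term(model$fits[[j]], xrow[j]))), 0)
}

stratified_folds <- function(y, folds, seed) {
  min_class <- min(table(y))
  if (min_class < 2) stopf("a class has fewer than 2 genes; cannot cross-validate")
  if (folds > min_class) {
    warnf("reducing folds from %d to %d (smallest class size)", folds, min_class)
    folds <- min_class
  }
  local_seed(seed, {
    assign <- integer(length(y))
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
    assign
  })
}

#' Stratified k-fold cross-validation of a naive Bayes model
#'
#' @param x,y,modes as in [fit_nb()].
#' @param folds number of folds (default 10); reduced with a warning if a
#'   class is smaller.
#' @param seed RNG seed for the fold assignment.
#' @return list with `error` (mean per-fold misclassification rate), `se`
#'   (sd across folds / sqrt(folds)) and `per_fold`.
#' @export
cross_validate <- function(x, y, modes, folds = 10L, seed = 1L) {
  y <- as.integer(y)
  fold <- stratified_folds(y, folds, seed)
  nf <- max(fold)
  errs <- vapply(seq_len(nf), function(f) {
    tr <- fold != f
    model <- fit_nb(x[tr, , drop = FALSE], y[tr], modes)
    lr <- vapply(which(!tr), function(i) nb_ratio(model, x[i, ], log = TRUE), 0)
    mean((lr >= 0) != (y[!tr] == 1))
  }, 0)
  list(error = mean(errs), se = sd(errs) / sqrt(nf), per_fold = errs)
}

#' Select top-(k1, k2) feature pairs over the 9 feature-type combinations
#'
#' For each of the 9 pairs of one ES-up feature type and one ES-down
#' feature type (w in 0, 1, 2 each), every (k1, k2) grid point with
#' 0 <= k1, k2 <= `kmax` is evaluated by stratified CV of a naive Bayes
#' model using the top k1 ES-up and top k2 ES-down features of those
#' types (ranked by p-value) plus the always-included main-factor
#' association-score predictors.  The global minimum CV error wins; ties
#' break toward smaller k1 + k2, then smaller k1, then the
#' lexicographically earlier type pair.  k1 = k2 = 0 reproduces the
#' main-factor-only baseline.
#'
#' @param labeled labeled feature table from [label_features()] (columns
#'   feature, w, label, p_label, test_label).
#' @param score_matrix genes x features log-score matrix (NA = absent).
#' @param main_scores genes x main-factors matrix of normalized
#'   association scores (always-present continuous predictors).
#' @param y 0/1 labels (1 = ES-up), aligned with the matrix rows.
#' @param kmax top-feature cap per direction (default 20).
#' @param folds CV folds (default 10).
#' @param seed RNG seed.
#' @param cv_eval optional stub `function(w_up, w_down, k1, k2) -> error`
#'   replacing the internal CV evaluation (used to audit the search
#'   structure).
#' @return list with `best` (w_up, w_down, k1, k2, features_up,
#'   features_down, cv_error, cv_se), `baseline` (error, se),
#'   `n_evaluations`, `n_type_pairs` and `ranked` candidate lists.
#' @export
select_features <- function(labeled, score_matrix, main_scores, y,
                            kmax = 20L, folds = 10L, seed = 1L,
                            cv_eval = NULL) {
  y <- as.integer(y)
  ranked <- list(up = vector("list", 3), down = vector("list", 3))
  for (w in 0:2) {
    for (dir in c("up", "down")) {
      lab <- if (dir == "up") "ES-up" else "ES-down"
      cand <- labeled[labeled$label == lab & labeled$w == w, , drop = FALSE]
      cand <- cand[order(cand$p_label, cand$feature), , drop = FALSE]
      ranked[[dir]][[w + 1]] <- head(cand, kmax)
    }
  }

  if (is.null(cv_eval)) {
    ctx <- precompute_cv(ranked, score_matrix, main_scores, y, folds, seed)
    eval_fun <- function(wu, wd, k1, k2) cv_grid_error(ctx, wu, wd, k1, k2)
  } else {
    eval_fun <- cv_eval
    ctx <- NULL
  }

  best <- NULL
  n_eval <- 0L
  baseline_err <- NA_real_
  for (wu in 0:2) {
    for (wd in 0:2) {
      for (k1 in 0:kmax) {
        for (k2 in 0:kmax) {
          err <- eval_fun(wu, wd, k1, k2)
          n_eval <- n_eval + 1L
          if (k1 == 0 && k2 == 0 && is.na(baseline_err)) baseline_err <- err
          cand <- list(wu = wu, wd = wd, k1 = k1, k2 = k2, error = err)
          if (is.null(best) || err < best$error ||
              (err == best$error && (k1 + k2 < best$k1 + best$k2 ||
                                     (k1 + k2 == best$k1 + best$k2 && k1 < best$k1)))) {
            best <- cand
          }
        }
      }
    }
  }

  feats_up <- head(ranked$up[[best$wu + 1]], best$k1)
  feats_down <- head(ranked$down[[best$wd + 1]], best$k2)
  if (!is.null(ctx)) {
    best_pf <- cv_grid_error(ctx, best$wu, best$wd, best$k1, best$k2, per_fold = TRUE)
    base_pf <- cv_grid_error(ctx, 0, 0, 0, 0, per_fold = TRUE)
    cv_se <- sd(best_pf) / sqrt(length(best_pf))
    base_se <- sd(base_pf) / sqrt(length(base_pf))
  } else {
    cv_se <- base_se <- NA_real_
  }
  list(
    best = list(w_up = best$wu, w_down = best$wd, k1 = best$k1, k2 = best$k2,
                features_up = feats_up, features_down = feats_down,
                cv_error = best$error, cv_se = cv_se),
    baseline = list(error = baseline_err, se = base_se),
    n_evaluations = n_eval, n_type_pairs = 9L,
    ranked = ranked
  )
}

# Precompute fold-held-out per-predictor log-ratio contributions so each
# (k1, k2) grid point reduces to summing cached columns.
precompute_cv <- function(ranked, score_matrix, main_scores, y, folds, seed) {
  fold <- stratified_folds(y, folds, seed)
  nf <- max(fold)
  n <- length(y)
  cand_feats <- unique(unlist(lapply(c(ranked$up, ranked$down), function(df) df$feature)))
  modes <- setNames(character(0), character(0))
  for (df in c(ranked$up, ranked$down)) {
    if (nrow(df)) modes[df$feature] <- ifelse(df$test_label == "proportion", "ind", "cont_ind")
  }
  contrib <- matrix(0, n, length(cand_feats) + ncol(main_scores),
                    dimnames = list(NULL, c(cand_feats, colnames(main_scores))))
  prior <- numeric(n)
  for (f in seq_len(nf)) {
    tr <- fold != f
    te <- which(!tr)
    p1 <- mean(y[tr] == 1)
    prior[te] <- log(p1) - log(1 - p1)
    for (feat in cand_feats) {
      fit <- fit_predictor(score_matrix[tr, feat], y[tr], modes[[feat]])
      contrib[te, feat] <- predictor_log_term(fit, score_matrix[te, feat])
    }
    for (mf in colnames(main_scores)) {
      fit <- fit_predictor(main_scores[tr, mf], y[tr], "cont")
      contrib[te, mf] <- predictor_log_term(fit, main_scores[te, mf])
    }
  }
  base <- prior + if (ncol(main_scores)) rowSums(contrib[, colnames(main_scores), drop = FALSE]) else 0
  # cumulative contributions of the ranked lists, per direction and type
  cum <- list(up = vector("list", 3), down = vector("list", 3))
  for (dir in c("up", "down")) {
    for (w in 0:2) {
      feats <- ranked[[dir]][[w + 1]]$feature
      cm <- matrix(0, n, length(feats) + 1L)
      if (length(feats)) {
        cm[, -1] <- t(apply(contrib[, feats, drop = FALSE], 1, cumsum))
      }
      cum[[dir]][[w + 1]] <- cm
    }
  }
  list(base = base, cum = cum, fold = fold, nf = nf, y = y)
}

cv_grid_error <- function(ctx, wu, wd, k1, k2, per_fold = FALSE) {
  cu <- ctx$cum$up[[wu + 1]]
  cd <- ctx$cum$down[[wd + 1]]
  s <- ctx$base + cu[, min(k1, ncol(cu) - 1L) + 1L] + cd[, min(k2, ncol(cd) - 1L) + 1L]
  wrong <- (s >= 0) != (ctx$y == 1)
  pf <- vapply(seq_len(ctx$nf), function(f) mean(wrong[ctx$fold == f]), 0)
  if (per_fold) pf else mean(pf)
}
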