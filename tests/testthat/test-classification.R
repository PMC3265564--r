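test_that("Silverman bandwidth: formula, fallback, scale equivariance", {
  expect_equal(silverman_bandwidth(rep(3, 10)), 0.1)   # sd 0 -> fallback
  expect_equal(silverman_bandwidth(5), 0.1)            # n < 2
  set.seed(51)
  x <- rnorm(100)
  h <- silverman_bandwidth(x)
  expect_equal(h, 0.9 * min(sd(x), IQR(x) / 1.34) * 100^(-1 / 5),
               tolerance = 1e-12)
  expect_equal(silverman_bandwidth(3 * x), 3 * h, tolerance = 1e-12)
})

test_that("fit_nb estimates priors, smoothed lambdas and survives degeneracy", {
  y <- rep(c(1, 0), c(60, 40))
  x <- matrix(rnorm(100), 100, 1, dimnames = list(NULL, "f"))
  m <- fit_nb(x, y, "cont_ind")
  expect_equal(m$p1, 0.6)
  # predictor absent for every class-1 gene: lambda1 = (0+1)/(60+2)
  x2 <- x; x2[y == 1, 1] <- NA
  m2 <- fit_nb(x2, y, "cont_ind")
  expect_equal(m2$fits$f$lambda1, 1 / 62)
  expect_equal(m2$fits$f$lambda0, 41 / 42)
  # identical training scores: bandwidth falls back, density finite
  x3 <- x; x3[, 1] <- 2.5
  m3 <- fit_nb(x3, y, "cont_ind")
  expect_equal(m3$fits$f$h1, 0.1)
  expect_true(is.finite(nb_ratio(m3, c(f = 2.5), log = TRUE)))
  expect_error(fit_nb(x, rep(1, 100), "cont_ind"), "both classes")
})

test_that("nb_ratio: prior-only, indicator ratio, monotone in prior", {
  y <- rep(c(1, 0), c(60, 40))
  x0 <- matrix(numeric(0), 100, 0)
  m <- fit_nb(x0, y, character())
  expect_equal(nb_ratio(m, numeric()), 0.6 / 0.4, tolerance = 1e-12)

  # indicator predictor with lambda1 = 0.8, lambda0 = 0.2 -> ratio 4 at I=1
  m$fits <- list(f = list(mode = "ind", lambda1 = 0.8, lambda0 = 0.2))
  m$p1 <- 0.5
  expect_equal(nb_ratio(m, c(f = 1.0)), 4, tolerance = 1e-12)
  expect_equal(nb_ratio(m, c(f = NA)), 0.2 / 0.8, tolerance = 1e-12)

  # increasing the prior never flips a label from ES-up to ES-down
  set.seed(52)
  for (i in 1:20) {
    m$p1 <- runif(1, 0.05, 0.5)
    r1 <- nb_ratio(m, c(f = 1))
    m2 <- m; m2$p1 <- m$p1 + runif(1, 0, 0.45)
    expect_gte(nb_ratio(m2, c(f = 1)), r1)
  }
})

test_that("nb_ratio equals a brute-force term-by-term evaluation", {
  set.seed(53)
  for (rep in 1:50) {
    n <- 40
    y <- rbinom(n, 1, 0.5); if (length(unique(y)) < 2) next
    k <- sample(1:4, 1)
    modes <- sample(c("cont_ind", "ind", "cont"), k, replace = TRUE)
    x <- matrix(rnorm(n * k), n, k, dimnames = list(NULL, paste0("p", 1:k)))
    for (j in which(modes != "cont")) x[rbinom(n, 1, 0.3) == 1, j] <- NA
    m <- fit_nb(x, y, modes)
    xnew <- x[sample(n, 1), ]
    got <- nb_ratio(m, xnew)
    # independent evaluation of the published ratio formula
    dens <- function(v, train, h) max(mean(dnorm(v, train, h)), 1e-300)
    lik <- function(cls) {
      out <- if (cls == 1) m$p1 else 1 - m$p1
      for (j in seq_len(k)) {
        f <- m$fits[[j]]
        lam <- if (cls == 1) f$lambda1 else f$lambda0
        tr <- if (cls == 1) f$train1 else f$train0
        h <- if (cls == 1) f$h1 else f$h0
        out <- out * switch(f$mode,
          cont = dens(xnew[j], tr, h),
          ind = if (is.na(xnew[j])) 1 - lam else lam,
          cont_ind = if (is.na(xnew[j])) 1 - lam else lam * dens(xnew[j], tr, h))
      }
      out
    }
    expect_equal(got, lik(1) / lik(0), tolerance = 1e-12)
    # per-predictor terms multiply back to the full ratio
    expect_equal(prod(nb_terms(m, xnew)) * m$p1 / (1 - m$p1), got,
                 tolerance = 1e-10)
  }
})

test_that("cross-validation: determinism, separability, permutation null", {
  set.seed(54)
  n <- 80
  y <- rep(c(1, 0), each = n / 2)
  x <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "f"))
  x[y == 1, 1] <- x[y == 1, 1] + 8            # far separated classes
  cv1 <- cross_validate(x, y, "cont", folds = 10, seed = 7)
  expect_lt(cv1$error, 0.05)
  expect_identical(cv1, cross_validate(x, y, "cont", folds = 10, seed = 7))
  yperm <- sample(y)
  cvp <- cross_validate(x, yperm, "cont", folds = 10, seed = 7)
  expect_gt(cvp$error, 0.3)                   # near the majority-class rate
  expect_warning(cross_validate(x[1:12, , drop = FALSE], rep(c(1, 0), c(3, 9)),
                                "cont", folds = 10, seed = 1),
                 "reducing folds")
})

test_that("selection enumerates 9 type pairs x 441 grid points", {
  calls <- new.env(); calls$n <- 0; calls$pairs <- character()
  stub <- function(wu, wd, k1, k2) {
    calls$n <- calls$n + 1
    calls$pairs <- union(calls$pairs, paste(wu, wd))
    0.5
  }
  labeled <- data.frame(feature = character(), w = integer(),
                        label = character(), p_label = numeric(),
                        test_label = character())
  sel <- select_features(labeled, matrix(0, 4, 0, dimnames = list(letters[1:4], NULL)),
                         matrix(rnorm(8), 4, 2, dimnames = list(letters[1:4], c("F1", "F2"))),
                         y = c(1, 1, 0, 0), cv_eval = stub)
  expect_equal(calls$n, 9 * 441)
  expect_length(calls$pairs, 9)
  expect_equal(sel$n_type_pairs, 9)
  # ties across the constant stub resolve to the baseline k1 = k2 = 0
  expect_equal(sel$best$k1, 0)
  expect_equal(sel$best$k2, 0)
  expect_equal(sel$baseline$error, 0.5)
})

test_that("selection finds planted signal and matches baseline on noise", {
  set.seed(55)
  n <- 60
  y <- rep(c(1, 0), each = n / 2)
  genes <- paste0("g", 1:n)
  # 6 candidate features: f1 informative (higher scores in class 1), rest noise
  sm <- matrix(rnorm(n * 6), n, 6, dimnames = list(genes, paste0("f", 1:6)))
  sm[y == 1, 1] <- sm[y == 1, 1] + 5
  sm[sample(length(sm), 40)] <- NA
  mains <- matrix(rnorm(n * 2), n, 2, dimnames = list(genes, c("F1", "F2")))
  labeled <- data.frame(feature = paste0("f", 1:6), w = c(1, 1, 1, 0, 0, 2),
                        label = c("ES-up", "ES-up", "ES-down", "ES-down", "ES-up", "ES-down"),
                        p_label = c(1e-6, 0.01, 0.02, 0.03, 0.05, 0.01),
                        test_label = "ranksum", stringsAsFactors = FALSE)
  sel <- select_features(labeled, sm, mains, y, folds = 5, seed = 8)
  expect_equal(sel$n_evaluations, 9 * 441)
  expect_true("f1" %in% sel$best$features_up$feature)
  expect_lt(sel$best$cv_error, sel$baseline$error)

  # pure-noise candidates: selected error within 1 SE of baseline
  sm2 <- matrix(rnorm(n * 6), n, 6, dimnames = list(genes, paste0("f", 1:6)))
  sel2 <- select_features(labeled, sm2, mains, y, folds = 5, seed = 8)
  expect_lte(sel2$best$cv_error,
             sel2$baseline$error + max(sel2$baseline$se, 0.1))
})
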