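mk_nbhd <- function(chrom = "chr1", peaks, sites) {
  list(chrom = chrom, start = min(peaks$center) - 500L,
       end = max(peaks$center) + 500L,
       center = as.integer(floor(mean(peaks$center))),
       peaks = peaks, sites = sites)
}
mk_pk <- function(factors, centers, intens) {
  data.frame(factor = factors, chrom = "chr1", center = as.integer(centers),
             intensity = intens, stringsAsFactors = FALSE)
}
mk_st <- function(motifs, starts, scores) {
  n <- length(motifs)
  data.frame(motif = motifs, chrom = rep("chr1", n),
             start = as.integer(starts), width = rep(10L, n),
             strand = rep("+", n), score = scores, stringsAsFactors = FALSE)
}

test_that("combination counts reproduce the published combinatorics", {
  cof <- sprintf("M%03d", 1:202)
  f12 <- sprintf("F%02d", 1:12)
  expect_length(enumerate_combinations(f12, cof, 2), 13332)
  expect_length(enumerate_combinations(f12, cof, 1), 2424)
  expect_length(enumerate_combinations(f12[1:7], cof, 2), 4242)
  expect_length(enumerate_combinations(f12[1:7], cof, 1), 1414)
  expect_length(enumerate_combinations(f12[1:4], cof, 2), 1212)
  expect_length(enumerate_combinations(f12[1:4], cof, 1), 808)
  expect_length(enumerate_combinations(f12, cof, 0), 202)
  expect_error(enumerate_combinations(f12[1], cof, 2), "exceeds")
  # deterministic lexicographic order, no duplicates
  e <- enumerate_combinations(c("B", "A", "C"), c("m2", "m1"), 2)
  expect_equal(vapply(e, `[[`, "", "name"),
               c("A.B.m1", "A.B.m2", "A.C.m1", "A.C.m2", "B.C.m1", "B.C.m2"))
})

test_that("supports requires every main factor plus the cofactor", {
  nb <- mk_nbhd(peaks = mk_pk(c("A", "A"), c(1000, 1100), c(1, 2)),
                sites = mk_st("C", 1050, 50))
  combo_ab <- list(main = c("A", "B"), motif = "C", w = 2, name = "A.B.C")
  combo_a <- list(main = "A", motif = "C", w = 1, name = "A.C")
  combo_0 <- list(main = character(), motif = "C", w = 0, name = "C")
  combo_d <- list(main = "A", motif = "D", w = 1, name = "A.D")
  expect_false(supports(nb, combo_ab))
  expect_true(supports(nb, combo_a))
  expect_true(supports(nb, combo_0))
  expect_false(supports(nb, combo_d))
})

test_that("feature score: hand-evaluated examples", {
  gene <- data.frame(gene_id = "g", chrom = "chr1", tss = 1000L, strand = "+")
  # one peak f = e^2 and one site g = e^3 both at distance 0 -> log score 5
  nb1 <- mk_nbhd(peaks = mk_pk("A", 1000, exp(2)), sites = mk_st("C", 1000, exp(3)))
  combo <- list(main = "A", motif = "C", w = 1, name = "A.C")
  expect_equal(feature_score(gene, list(nb1), combo, d0 = 5000), 5,
               tolerance = 1e-12)

  # two peaks e^2, e^4 and one site e^3, all at distance 5000:
  # geometric means e^3 and e^3, decay exp(-15000/(3*5000)) = e^-1
  nb2 <- mk_nbhd(peaks = mk_pk(c("A", "A"), c(6000, 6000), c(exp(2), exp(4))),
                 sites = mk_st("C", 6000, exp(3)))
  expect_equal(feature_score(gene, list(nb2), combo, d0 = 5000), 5,
               tolerance = 1e-12)

  # no supporting neighborhood -> absent
  expect_true(is.na(feature_score(gene, list(nb1),
                                  list(main = "B", motif = "C", w = 1, name = "B.C"))))
  # w = 0: main-factor term is the empty product
  combo0 <- list(main = character(), motif = "C", w = 0, name = "C")
  expect_equal(feature_score(gene, list(nb1), combo0, d0 = 5000), 3,
               tolerance = 1e-12)
})

# naive direct implementation of the score formula, no shared code
oracle_score <- function(gene, nbhds, combo, d0 = 5000) {
  terms <- c()
  for (nb in nbhds) {
    pk <- nb$peaks[nb$peaks$factor %in% combo$main, , drop = FALSE]
    st <- nb$sites[nb$sites$motif == combo$motif, , drop = FALSE]
    if (length(combo$main) && !all(combo$main %in% pk$factor)) next
    if (!nrow(st)) next
    n <- nrow(pk); m <- nrow(st)
    gm_f <- if (n) prod(pk$intensity)^(1 / n) else 1
    gm_g <- prod(st$score)^(1 / m)
    dsum <- sum(abs(pk$center - gene$tss)) + sum(abs(st$start - gene$tss))
    terms <- c(terms, gm_f * gm_g * exp(-dsum / ((n + m) * d0)))
  }
  if (!length(terms)) NA_real_ else log(sum(terms))
}

test_that("feature_score and build_score_matrix agree with the naive oracle", {
  set.seed(31)
  for (rep in 1:50) {
    gene <- data.frame(gene_id = "g", chrom = "chr1",
                       tss = sample.int(50000, 1), strand = "+")
    nbhds <- lapply(1:3, function(i) {
      np <- sample(1:4, 1); ns <- sample(0:3, 1)
      mk_nbhd(
        peaks = mk_pk(sample(c("A", "B", "X"), np, replace = TRUE),
                      sample.int(60000, np), runif(np, 0.5, 30)),
        sites = if (ns) mk_st(sample(c("C", "D"), ns, replace = TRUE),
                              sample.int(60000, ns), runif(ns, 2, 5000))
                else mk_st(character(), integer(), numeric())
      )
    })
    w <- sample(0:2, 1)
    combo <- list(main = sort(sample(c("A", "B"), w)), motif = "C", w = w)
    combo$name <- feature_name(combo$main, combo$motif)
    got <- feature_score(gene, nbhds, combo)
    want <- oracle_score(gene, nbhds, combo)
    expect_equal(got, want, tolerance = 1e-10)
    # build_score_matrix computes the same value through its indexed path
    amap <- list(g = seq_along(nbhds))
    m <- build_score_matrix(gene, nbhds, amap, list(combo))
    expect_equal(unname(m[1, 1]), want, tolerance = 1e-10)
  }
})

test_that("feature score monotonicity in strengths and distances", {
  gene <- data.frame(gene_id = "g", chrom = "chr1", tss = 1000L, strand = "+")
  combo <- list(main = "A", motif = "C", w = 1, name = "A.C")
  nb <- mk_nbhd(peaks = mk_pk("A", 6000, 3), sites = mk_st("C", 7000, 40))
  s0 <- feature_score(gene, list(nb), combo)
  nb_f <- nb; nb_f$peaks$intensity <- 4
  expect_gt(feature_score(gene, list(nb_f), combo), s0)
  nb_g <- nb; nb_g$sites$score <- 50
  expect_gt(feature_score(gene, list(nb_g), combo), s0)
  nb_d <- nb; nb_d$peaks$center <- 9000L; nb_d$sites$start <- 10000L
  expect_lt(feature_score(gene, list(nb_d), combo), s0)
  # nonpositive strengths are rejected
  nb_bad <- nb; nb_bad$sites$score <- -1
  expect_error(feature_score(gene, list(nb_bad), combo), "onpositive")
})

test_that("score matrix rows/columns follow the contracts", {
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                      tss = c(1000L, 900000L), strand = "+")
  nb <- mk_nbhd(peaks = mk_pk(c("A", "B"), c(1000, 1100), c(2, 3)),
                sites = mk_st("C", 1050, 100))
  combos <- enumerate_combinations(c("A", "B"), "C", 1)
  amap <- list(g1 = 1L, g2 = integer())   # g2 has no associated neighborhood
  m <- build_score_matrix(genes, list(nb), amap, combos)
  expect_equal(dim(m), c(2L, 2L))
  expect_true(all(is.na(m["g2", ])))
  expect_true(all(!is.na(m["g1", ])))
})
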