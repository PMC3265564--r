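uniform_bg <- list(init = setNames(rep(0.25, 4), c("A", "C", "G", "T")),
                   trans = matrix(0.25, 4, 4, dimnames = list(c("A","C","G","T"), c("A","C","G","T"))))

revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]), collapse = "")
}

test_that("background estimation: homopolymer, alternating, concentration", {
  bg <- estimate_background("AAAA", pseudocount = 0)
  expect_equal(bg$trans["A", "A"], 1)
  bg2 <- estimate_background("ACACAC", pseudocount = 0)
  expect_equal(bg2$trans["A", "C"], 1)
  expect_equal(bg2$trans["C", "A"], 1)
  set.seed(41)
  s <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE), collapse = "")
  bg3 <- estimate_background(s, pseudocount = 0.5)
  expect_true(all(bg3$trans >= 0.22 & bg3$trans <= 0.28))
  expect_true(all(bg3$init >= 0.22 & bg3$init <= 0.28))
  # all-masked sequence signals fallback
  expect_null(estimate_background("acgtnacgt"))
  # masked positions break transition pairs
  bg4 <- estimate_background("AAaAA", pseudocount = 0)
  expect_equal(unname(bg4$n_informative), 4)
})

test_that("w-mer scoring: identity, single column, masking", {
  pwm_u <- pwm_record("U", matrix(1, 4, 3))       # uniform columns
  sc <- score_wmers("ACGTACGT", pwm_u, uniform_bg)
  expect_equal(sc$fwd, rep(1, 6), tolerance = 1e-12)
  expect_equal(sc$rev, rep(1, 6), tolerance = 1e-12)

  pwm_a <- pwm_record("A1", matrix(c(10, 0, 0, 0), 4, 1))  # ~0.997 A
  sc2 <- score_wmers("AC", pwm_a, uniform_bg)
  expect_equal(sc2$fwd[1], (10.01 / 10.04) / 0.25, tolerance = 1e-9)
  expect_equal(sc2$fwd[1], 3.99, tolerance = 1e-2)

  sc3 <- score_wmers("ACgTACGT", pwm_u, uniform_bg)
  expect_true(all(is.na(sc3$fwd[1:3])))      # w-mers overlapping the mask
  expect_true(all(!is.na(sc3$fwd[4:6])))
  expect_length(score_wmers("AC", pwm_u, uniform_bg)$fwd, 0)  # w > L
})

test_that("scores match a direct probability-ratio oracle on both strands", {
  oracle_r <- function(wmer, pwm, bg) {
    b <- strsplit(wmer, "")[[1]]
    num <- prod(pwm$matrix[cbind(match(b, rownames(pwm$matrix)), seq_along(b))])
    den <- bg$init[b[1]] *
      prod(bg$trans[cbind(b[-length(b)], b[-1])])
    unname(num / den)
  }
  set.seed(42)
  for (rep in 1:5) {
    L <- 300
    s <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE,
                      prob = c(0.3, 0.2, 0.2, 0.3)), collapse = "")
    w <- sample(4:8, 1)
    pwm <- pwm_record("M", matrix(runif(4 * w, 0.05, 1), 4, w))
    bg <- estimate_background(s, pseudocount = 0.5)
    sc <- score_wmers(s, pwm, bg)
    rc <- revcomp(s)
    for (i in sample(L - w + 1, 10)) {
      expect_equal(sc$fwd[i], oracle_r(substr(s, i, i + w - 1), pwm, bg),
                   tolerance = 1e-12)
      # reverse strand: the w-mer read off the reverse complement
      j <- L - (i + w - 1) + 1
      expect_equal(sc$rev[i], oracle_r(substr(rc, j, j + w - 1), pwm, bg),
                   tolerance = 1e-12)
    }
    # strand symmetry: scanning the reverse complement swaps the vectors
    sc2 <- score_wmers(rc, pwm, bg)
    expect_equal(sc2$fwd, rev(sc$rev), tolerance = 1e-12)
    expect_equal(sc2$rev, rev(sc$fwd), tolerance = 1e-12)
  }
})

test_that("threshold calibration order statistics", {
  expect_equal(calibrate_threshold(sample(1:100), p = 0.05), 95)
  expect_equal(sum(1:100 > 95), 5)
  n <- 50
  null <- sample(seq_len(n))
  thr <- calibrate_threshold(null, p = 1 / n)
  expect_equal(thr, n - 1)                 # second-largest value
  expect_equal(sum(null > thr), 1)
  expect_equal(calibrate_threshold(rep(7, 100), p = 0.05), 7)
  expect_equal(sum(rep(7, 100) > 7), 0)    # strict inequality: nothing passes
  expect_error(calibrate_threshold(1:5, p = 0.05), "null sample too small")
})

test_that("matched controls: length, distance, determinism", {
  set.seed(43)
  genome <- c(chr1 = paste(sample(c("A", "C", "G", "T"), 2e5, replace = TRUE),
                           collapse = ""))
  genes <- data.frame(gene_id = paste0("g", 1:8), chrom = "chr1",
                      tss = as.integer(seq(2e4, 1.8e5, length.out = 8)),
                      strand = "+", stringsAsFactors = FALSE)
  nbhd <- list(chrom = "chr1", start = 44000L, end = 45200L, center = 44600L,
               peaks = NULL)
  ctrl <- sample_matched_controls(genome, genes, nbhd, n = 10, seed = 5)
  expect_length(ctrl, 10)
  expect_true(all(nchar(ctrl) == 1200))
  expect_identical(ctrl, sample_matched_controls(genome, genes, nbhd, n = 10, seed = 5))
  expect_false(identical(ctrl, sample_matched_controls(genome, genes, nbhd, n = 10, seed = 6)))
})

test_that("planted consensus sites are recovered and all sites beat thresholds", {
  set.seed(44)
  bases <- sample(c("A", "C", "G", "T"), 3e5, replace = TRUE)
  w <- 10
  m <- matrix(0.02, 4, w); for (j in 1:w) m[sample(4, 1), j] <- 0.94
  pwm <- pwm_record("M1", m, "cofX")
  consensus <- c("A", "C", "G", "T")[apply(pwm$matrix, 2, which.max)]
  bases[150000:150009] <- consensus
  genome <- c(chr1 = paste(bases, collapse = ""))
  genes <- data.frame(gene_id = paste0("g", 1:6), chrom = "chr1",
                      tss = as.integer(seq(3e4, 2.7e5, length.out = 6)),
                      strand = "+", stringsAsFactors = FALSE)
  peaks <- data.frame(factor = c("A1", "B1"), chrom = "chr1",
                      center = c(149900L, 150100L), intensity = c(5, 5),
                      stringsAsFactors = FALSE)
  nb <- build_neighborhoods(peaks)
  cs <- suppressWarnings(call_sites(nb, list(pwm), genome, genes,
                                    p = 1e-3, n_controls = 5, seed = 9))
  sites <- cs$nbhds[[1]]$sites
  expect_true(any(sites$start == 149999 & sites$strand == "+"))
  expect_true(all(sites$score > cs$thresholds$threshold[1]))
  # site coordinates are genome-absolute and inside the island
  expect_true(all(sites$start >= nb[[1]]$start & sites$start + 10 <= nb[[1]]$end))
})
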