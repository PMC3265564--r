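small_cfg <- function(seed = 1, ...) {
  synthetic_config(seed = seed, chrom_length = 2e6, n_genes = 40,
                   n_cofactors = 6, ...)
}

test_that("bundle generation is byte-reproducible under a fixed seed", {
  b1 <- generate_bundle(small_cfg(3))
  b2 <- generate_bundle(small_cfg(3))
  expect_identical(b1$genome, b2$genome)
  expect_identical(b1$peaks, b2$peaks)
  expect_identical(b1$expr$values, b2$expr$values)
  expect_identical(b1$truth$labels, b2$truth$labels)
  b3 <- generate_bundle(small_cfg(4))
  expect_false(identical(b1$genome, b3$genome))
})

test_that("genome: GC, repeat masking, TSS spacing and feasibility", {
  cfg <- synthetic_config(seed = 2, n_chromosomes = 1, chrom_length = 1e6,
                          n_genes = 20, n_cofactors = 4, gc = 0.5,
                          repeat_fraction = 0.25)
  gg <- generate_genome(cfg)
  s <- strsplit(gg$genome[[1]], "")[[1]]
  gc_obs <- mean(toupper(s) %in% c("C", "G"))
  expect_gt(gc_obs, 0.48); expect_lt(gc_obs, 0.52)
  frac_masked <- mean(s %in% c("a", "c", "g", "t"))
  expect_gt(frac_masked, 0.23); expect_lt(frac_masked, 0.27)
  for (chr in unique(gg$genes$chrom)) {
    expect_true(all(diff(sort(gg$genes$tss[gg$genes$chrom == chr])) >= 1e4))
  }

  cfg0 <- synthetic_config(seed = 2, n_chromosomes = 1, chrom_length = 1e6,
                           n_genes = 20, n_cofactors = 4, repeat_fraction = 0)
  g0 <- generate_genome(cfg0)
  expect_false(grepl("[acgt]", g0$genome[[1]]))

  expect_error(generate_genome(synthetic_config(seed = 1, n_chromosomes = 1,
                                                chrom_length = 1e5,
                                                n_genes = 50)),
               "infeasible")
})

test_that("peaks follow the cluster design", {
  cfg <- small_cfg(5)
  gg <- generate_genome(cfg)
  truth <- assign_truth_labels(cfg, gg$genes)
  pk <- generate_peaks(cfg, gg$genes, truth)$peaks
  oct4 <- cfg$factors$oct4; myc <- cfg$factors$myc
  near_counts <- function(gene_row, factors) {
    sub <- pk[pk$factor %in% factors & pk$chrom == gene_row$chrom &
                abs(pk$center - gene_row$tss) <= 1e6, , drop = FALSE]
    table(factor(sub$factor, factors))
  }
  for (i in seq_len(nrow(gg$genes))) {
    cl <- truth$cluster[i]
    if (cl == "Myc") {
      # every Myc-group factor has >= 2 peaks within 1 Mb
      expect_true(all(near_counts(gg$genes[i, ], myc) >= 2))
    }
  }
  # uniformly-low genes: "off" factors rarely peak; check the genome-wide rate
  low <- truth$gene_id[truth$cluster == "uniformly-low"]
  low_genes <- gg$genes[gg$genes$gene_id %in% low, ]
  has_near <- vapply(seq_len(nrow(low_genes)), function(i) {
    any(pk$chrom == low_genes$chrom[i] & abs(pk$center - low_genes$tss[i]) <= 2e4)
  }, TRUE)
  expect_lt(mean(has_near), 0.5)
  expect_true(all(pk$intensity > 0))
})

test_that("planted instances land near targets; empty planting is a no-op", {
  b <- generate_bundle(small_cfg(6))
  ps <- b$truth$planted_sites
  expect_gt(nrow(ps), 0)
  # placement accounting: targets minus recorded skips all carry instances
  for (p in b$truth$planted) {
    targets <- b$truth$labels$gene_id[b$truth$labels$cluster == p$cluster &
                                        b$truth$labels$es_label == p$direction]
    skipped <- sum(grepl(paste0("^", p$name, ":"), b$truth$skipped))
    covered <- unique(ps$gene_id[ps$feature == p$name])
    expect_equal(length(covered), length(targets) - skipped)
    expect_gte(length(covered) / max(length(targets), 1), 0.5)
  }
  # instances sit within 1 Mb of their target's TSS
  g <- b$genes[match(ps$gene_id, b$genes$gene_id), ]
  expect_true(all(abs(ps$position - g$tss) <= 1e6))

  cfg0 <- small_cfg(6, planted = list())
  gg <- generate_genome(cfg0)
  truth <- assign_truth_labels(cfg0, gg$genes)
  pk <- generate_peaks(cfg0, gg$genes, truth)
  pw <- generate_pwms(cfg0)
  pl <- plant_cofactor_sites(gg$genome, pk$peaks, pw, list(), gg$genes, truth,
                             seed = 1)
  expect_identical(pl$genome, gg$genome)
})

test_that("expression honors labels, statuses and effect sizes", {
  cfg <- small_cfg(7)
  gg <- generate_genome(cfg)
  truth <- assign_truth_labels(cfg, gg$genes)
  cs <- assign_cofactor_status(cfg)
  e <- generate_expression(cfg, truth, cs)
  st <- call_es_genes(e)
  lab <- truth$es_label
  # power: effect 2 (log2), noise 0.25 -> nearly every designed gene called
  expect_gt(mean(st$es_class[lab == "ES-up"] == "ES-up"), 0.95)
  expect_gt(mean(st$es_class[lab == "ES-down"] == "ES-down"), 0.95)
  # H-status cofactor genes: raw means above 500 at both stages
  hgenes <- cs$gene_id[cs$status == "H"]
  if (length(hgenes)) {
    i <- match(hgenes, st$gene_id)
    expect_true(all(st$mean_es[i] > 500 & st$mean_df[i] > 500))
    expect_true(all(st$status[i] == "H"))
  }
  # null: effect 0 -> ES call rate stays near the test level
  cfg0 <- small_cfg(7, effect = 0, planted = list())
  e0 <- generate_expression(cfg0, truth, cs)
  st0 <- call_es_genes(e0)
  reg <- !truth$gene_id %in% cs$gene_id
  expect_lt(mean(st0$es_class[reg] != "neutral"), 0.075)
  # concordant validation moves with the truth labels
  v <- generate_expression(cfg, truth, cs, validation = TRUE)
  sv <- call_es_genes(v)
  expect_gt(mean(sv$fc[lab == "ES-up"] > 1), 0.95)
  expect_gt(mean(sv$fc[lab == "ES-down"] < 1), 0.95)
})
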