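# Shared fixtures: a reduced synthetic bundle (small genome, fewer genes,
# fewer controls) keeps full-pipeline tests inside the suite's time budget;
# the generator itself defaults to the full stated world.  Pipeline runs
# are cached per seed so acceptance tests can share them.

test_synth_config <- function(seed) {
  synthetic_config(seed = seed, chrom_length = 4.5e6, n_genes = 80,
                   n_cofactors = 8)
}

test_pipe_config <- function(seed) {
  pipeline_config(seed = seed, n_controls = 3)
}

.run_cache <- new.env(parent = emptyenv())

cached_run <- function(seed) {
  key <- as.character(seed)
  if (is.null(.run_cache[[key]])) {
    bundle <- suppressWarnings(generate_bundle(test_synth_config(seed)))
    res <- suppressWarnings(run_pipeline(bundle, test_pipe_config(seed)))
    .run_cache[[key]] <- list(bundle = bundle, res = res)
  }
  .run_cache[[key]]
}

# unadjusted Rand index between two partitions
rand_index <- function(a, b) {
  n <- length(a)
  same <- outer(a, a, "==") == outer(b, b, "==")
  (sum(same) - n) / (n^2 - n)
}
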