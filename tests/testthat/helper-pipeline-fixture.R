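# Reference-scale pipeline run shared by the acceptance tests. Built lazily
# once per session and cached: a synthetic corpus at the scale of the
# motivating extract (887/113/47 drugs, 751 ADR terms, strongly
# class-typical reporting), the three experiment designs, and the
# enhancement artifacts. GAN training uses 800 epochs, enough for the
# generator to reach the sparsity regime of the real submatrix while
# keeping the suite fast.

.pipeline_cache <- new.env(parent = emptyenv())

reference_scale_run <- function() {
  if (!is.null(.pipeline_cache$run)) {
    return(.pipeline_cache$run)
  }
  cfg <- generator_config(seed = 1L)  # generator defaults
  catalog <- generate_catalog(cfg)
  reports <- generate_reports(cfg, catalog)
  cleaned <- clean_reports(reports)
  tab <- attach_labels(aggregate_counts(cleaned$reports), catalog$drugs)
  sm <- build_signal_matrix(tab)
  results <- lapply(1:3, function(m) {
    run_experiment(sm, config = experiment_config(
      model = m, seed = 1L, gan = gan_config(epochs = 800L)))
  })
  .pipeline_cache$run <- list(config = cfg, catalog = catalog,
                              cleaned = cleaned, table = tab, sm = sm,
                              results = results)
  .pipeline_cache$run
}
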