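# Fitted models are expensive; cache them across test files.
.fit_cache <- new.env(parent = emptyenv())

# Small-but-faithful training run used by unit tests (reduced MCMC budget;
# the acceptance tests use the full defaults).
cached_default_fit <- function() {
  if (is.null(.fit_cache$default)) {
    spec <- default_network_spec()
    trials <- generate_paradigm(paradigm_config(seed = 401), spec)
    .fit_cache$default <- fit_posterior(
      trials, spec,
      mcmc = mcmc_config(n_iterations = 6000, n_burn_in = 2000,
                         thinning = 4, seed = 402))
  }
  .fit_cache$default
}

# Replicated end-to-end runs shared by the sign-recovery and PIT-battery
# acceptance checks (full default settings, seeds 1..n).
cached_replicates <- function(n = 20) {
  key <- paste0("rep", n)
  if (is.null(.fit_cache[[key]])) {
    spec <- default_network_spec()
    .fit_cache[[key]] <- lapply(seq_len(n), function(seed) {
      trials <- generate_paradigm(paradigm_config(seed = seed), spec)
      fit <- fit_posterior(trials, spec,
                           mcmc = mcmc_config(seed = 1000 + seed))
      list(means = colMeans(fit$draws),
           battery = run_pit_battery(fit, spec),
           fit = if (seed == 1) fit else NULL)
    })
  }
  .fit_cache[[key]]
}
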