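#' MCMC sampler configuration
#'
#' Settings for the blocked random-walk Metropolis sampler: each free
#' parameter (edge weight or node bias) is updated in turn with a Gaussian
#' proposal whose scale is adapted during burn-in toward a target
#' acceptance rate and frozen afterward.
#'
#' @param n_iterations total sweeps per chain.
#' @param n_burn_in sweeps discarded (and used for adaptation).
#' @param thinning keep every `thinning`-th post-burn-in sweep.
#' @param proposal_scale initial Gaussian proposal standard deviation.
#' @param n_chains number of independent chains.
#' @param adapt_interval sweeps between scale adaptations during burn-in.
#' @param target_accept acceptance rate the adaptation aims for.
#' @param seed integer seed; chain i runs under `seed + i`.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iterations = 15000, n_burn_in = 5000,
                        thinning = 5, proposal_scale = 0.5,
                        n_chains = 2, adapt_interval = 50,
                        target_accept = 0.3, seed = NULL) {
  if (n_iterations <= 0) stop("n_iterations must be positive")
  if (n_burn_in < 0 || n_iterations <= n_burn_in) {
    stop("need n_iterations > n_burn_in >= 0")
  }
  if (thinning < 1) stop("thinning must be >= 1")
  if (proposal_scale <= 0) stop("proposal_scale must be positive")
  if (n_chains < 1) stop("n_chains must be >= 1")
  structure(list(n_iterations = as.integer(n_iterations),
                 n_burn_in = as.integer(n_burn_in),
                 thinning = as.integer(thinning),
                 proposal_scale = proposal_scale,
                 n_chains = as.integer(n_chains),
                 adapt_interval = as.integer(adapt_interval),
                 target_accept = target_accept,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "mcmc_config")
}

#' Sample the posterior over weights and biases
#'
#' Targets `log_prior + sum of trial log-likelihoods` with the exact
#' marginal likelihood (latent causes enumerated, never sampled).
#' Identical trials are aggregated by multiplicity before evaluation,
#' which leaves the target bit-identical while making each evaluation
#' cheap. Chains are initialized at the prior mean (all zeros) and updated
#' in the canonical parameter order (biases by node order, then edge
#' weights sorted by name); draws from all chains are pooled for
#' reporting, with per-chain identity retained for diagnostics.
#'
#' @param trials an `sbn_trials` training set (may be empty, in which case
#'   the posterior equals the prior).
#' @param spec an `sbn_spec`.
#' @param prior an [prior_spec()].
#' @param mcmc an [mcmc_config()].
#' @param fixed named numeric vector of parameters (theta names, e.g.
#'   `"b_H1"` or `"w_H1_S1"`) clamped at the given values and not sampled.
#'   By default all node biases are clamped at [background_biases()] and
#'   only the 14 edge weights are learned; pass `fixed = NULL` to learn
#'   the biases too (see [background_biases()] for why clamping is the
#'   default).
#' @return An object of class `sbn_posterior`: `draws` (matrix, pooled
#'   post-burn-in thinned draws x parameters), `chain` (chain id per draw),
#'   `acceptance` (per chain x parameter), `spec`, `prior`, `mcmc`.
#' @export
fit_posterior <- function(trials, spec, prior = prior_spec(),
                          mcmc = mcmc_config(),
                          fixed = background_biases(spec)) {
  stopifnot(inherits(spec, "sbn_spec"), inherits(prior, "sbn_prior"),
            inherits(mcmc, "mcmc_config"))
  pn <- param_names(spec)
  pv0 <- prior_vectors(prior, spec)
  theta0 <- stats::setNames(pv0$mean, pn)  # chains start at the prior mean
  mask <- rep(TRUE, length(pn))
  if (!is.null(fixed)) {
    unknown <- setdiff(names(fixed), pn)
    if (length(unknown)) {
      stop("unknown fixed parameter(s): ", paste(unknown, collapse = ", "))
    }
    theta0[names(fixed)] <- fixed
    mask[match(names(fixed), pn)] <- FALSE
  }
  trials <- compress_trials(trials)
  model <- build_model(spec)
  X <- as_trial_matrix(trials, spec)
  mult <- as.integer(trials$multiplicity)
  pv <- prior_vectors(prior, spec)

  chains <- lapply(seq_len(mcmc$n_chains), function(i) {
    with_seed(if (is.null(mcmc$seed)) NULL else mcmc$seed + i,
      cpp_run_chain(theta0, model, X, mult, pv$mean, pv$sd, mask,
                    mcmc$n_iterations, mcmc$n_burn_in, mcmc$thinning,
                    rep(mcmc$proposal_scale, length(pn)),
                    mcmc$adapt_interval, mcmc$target_accept))
  })
  draws <- do.call(rbind, lapply(chains, `[[`, "draws"))
  colnames(draws) <- pn
  acceptance <- do.call(rbind, lapply(chains, `[[`, "acceptance"))
  colnames(acceptance) <- pn
  n_per_chain <- nrow(chains[[1]]$draws)
  structure(list(draws = draws,
                 chain = rep(seq_len(mcmc$n_chains), each = n_per_chain),
                 acceptance = acceptance,
                 spec = spec, prior = prior, mcmc = mcmc, fixed = fixed),
            class = "sbn_posterior")
}

#' @export
print.sbn_posterior <- function(x, ...) {
  cat("sbn_posterior:", nrow(x$draws), "draws (",
      length(unique(x$chain)), "chains ) over", ncol(x$draws),
      "parameters\n")
  cat("  mean acceptance:",
      round(mean(x$acceptance, na.rm = TRUE), 3), "\n")
  invisible(x)
}

#' Posterior summary table
#'
#' Per-parameter mean, standard deviation and central credible interval
#' from the pooled draws.
#'
#' @param samples an `sbn_posterior`.
#' @param level central interval coverage.
#' @return data frame with columns `parameter`, `mean`, `sd`, `lower`,
#'   `upper`.
#' @export
posterior_summary <- function(samples, level = 0.95) {
  draws <- samples$draws
  if (nrow(draws) < 2) stop("need at least 2 draws to summarize")
  a <- (1 - level) / 2
  data.frame(parameter = colnames(draws),
             mean = colMeans(draws),
             sd = apply(draws, 2, stats::sd),
             lower = apply(draws, 2, stats::quantile, probs = a),
             upper = apply(draws, 2, stats::quantile, probs = 1 - a),
             row.names = NULL)
}

#' Posterior-mean weight configuration
#'
#' @param samples an `sbn_posterior`.
#' @return an `sbn_weights` at the posterior means.
#' @export
posterior_mean_weights <- function(samples) {
  param_vector_to_weights(colMeans(samples$draws), samples$spec)
}

#' Split-chain convergence diagnostics
#'
#' Computes the split-chain potential scale reduction factor (R-hat:
#' chains are halved, and the ratio of pooled to within-half variance is
#' reported) and a crude effective sample size from lag-summed
#' autocorrelations, per parameter. Parameters whose R-hat exceeds the
#' threshold are flagged.
#'
#' @param samples an `sbn_posterior` with at least 2 chains, or a list of
#'   equal-length draw matrices.
#' @param threshold R-hat above which a parameter is flagged.
#' @return data frame with columns `parameter`, `rhat`, `ess`, `flagged`.
#' @export
convergence_diagnostics <- function(samples, threshold = 1.1) {
  if (inherits(samples, "sbn_posterior")) {
    ids <- unique(samples$chain)
    chains <- lapply(ids, function(i) {
      samples$draws[samples$chain == i, , drop = FALSE]
    })
  } else {
    chains <- lapply(samples, as.matrix)
  }
  if (length(chains) < 2) stop("need at least 2 chains")
  lens <- vapply(chains, nrow, integer(1))
  if (length(unique(lens)) != 1) stop("chains must have equal length")
  n <- lens[1]
  if (n < 4) stop("chains too short to split")
  half <- n %/% 2
  split_chains <- unlist(lapply(chains, function(ch) {
    list(ch[seq_len(half), , drop = FALSE],
         ch[(n - half + 1):n, , drop = FALSE])
  }), recursive = FALSE)
  m <- length(split_chains)
  pn <- colnames(chains[[1]])
  rhat <- ess <- numeric(length(pn))
  for (j in seq_along(pn)) {
    x <- vapply(split_chains, function(ch) ch[, j], numeric(half))
    mu <- colMeans(x)
    s2 <- apply(x, 2, stats::var)
    W <- mean(s2)
    B <- half * stats::var(mu)
    var_plus <- (half - 1) / half * W + B / half
    rhat[j] <- if (W <= 0) {
      if (stats::var(mu) <= 0) 1 else Inf
    } else {
      sqrt(var_plus / W)
    }
    ess[j] <- ess_one(unlist(lapply(split_chains, function(ch) ch[, j])),
                      m, half)
  }
  data.frame(parameter = pn, rhat = rhat, ess = ess,
             flagged = rhat > threshold, row.names = NULL)
}

# Initial-positive-sequence ESS on pooled split chains (Geyer-style
# truncation at the first non-positive paired autocorrelation sum).
ess_one <- function(x, n_chains, n_per) {
  n <- length(x)
  if (stats::var(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE,
                   demean = TRUE)$acf[, 1, 1]
  s <- 0
  k <- 2
  while (k + 1 <= length(ac)) {
    pair <- ac[k] + ac[k + 1]
    if (pair <= 0) break
    s <- s + pair
    k <- k + 2
  }
  n / (1 + 2 * s)
}

#' Write / read posterior draws as CSV
#'
#' One row per draw, one column per parameter, plus a `chain` column.
#'
#' @param samples an `sbn_posterior`.
#' @param path file path.
#' @return `write_draws_csv` returns `path` invisibly; `read_draws_csv`
#'   returns a list with `draws` and `chain`.
#' @export
write_draws_csv <- function(samples, path) {
  df <- as.data.frame(samples$draws)
  df$chain <- samples$chain
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_draws_csv
#' @export
read_draws_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  chain <- df$chain
  df$chain <- NULL
  list(draws = as.matrix(df), chain = chain)
}
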