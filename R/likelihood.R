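#' Activation probability of a node
#'
#' The generative rule of the sigmoid belief network: a node is active with
#' probability `sigma(bias + sum of weights of its active parents)`, where
#' `sigma` is the logistic function. Strictly increasing in the bias and in
#' each active-parent weight, bounded in (0, 1).
#'
#' @param bias node bias in log-odds units.
#' @param active_parent_weights numeric vector of weights on edges from
#'   currently active parents (empty if none).
#' @return probability in (0, 1).
#' @examples
#' activation_probability(0)            # 0.5
#' activation_probability(-2, 4)        # sigma(2)
#' @export
activation_probability <- function(bias, active_parent_weights = numeric()) {
  if (!all(is.finite(bias)) || !all(is.finite(active_parent_weights))) {
    stop("bias and weights must be finite")
  }
  stats::plogis(bias + sum(active_parent_weights))
}

#' Marginal log-likelihood of trials
#'
#' Computes the exact log-likelihood of a trial collection under a weight
#' configuration by summing, for every trial, over all 2^k configurations
#' of the k latent causes (and over the action node when it is unobserved
#' but one of its children is observed). Each configuration contributes the
#' product of latent Bernoulli priors and the Bernoulli likelihood of every
#' observed child at its activation probability; unobserved nodes are
#' marginalized and contribute a factor of 1. Each trial's log-likelihood
#' is scaled by its multiplicity, and the trial collection's value is the
#' sum over trials (trials are independent given the weights).
#'
#' @param weights an `sbn_weights`.
#' @param spec an `sbn_spec`.
#' @param trials an `sbn_trials` (one or more rows).
#' @return total log-likelihood (scalar; 0 for an empty collection).
#' @export
trial_log_likelihood <- function(weights, spec, trials) {
  stopifnot(inherits(weights, "sbn_weights"), inherits(spec, "sbn_spec"))
  theta <- as_param_vector(weights, spec)
  model <- build_model(spec)
  X <- as_trial_matrix(trials, spec)
  cpp_trials_loglik(theta, model, X, as.integer(trials$multiplicity))
}

# theta-level entry used by the sampler and tests.
log_posterior_theta <- function(theta, spec, trials, prior) {
  pv <- prior_vectors(prior, spec)
  model <- build_model(spec)
  X <- as_trial_matrix(trials, spec)
  cpp_trials_loglik(theta, model, X, as.integer(trials$multiplicity)) +
    sum(stats::dnorm(theta, pv$mean, pv$sd, log = TRUE))
}
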