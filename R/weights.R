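#' Weight configuration for a belief network
#'
#' Bundles the learnable quantities of the network: one weight per directed
#' edge and one bias per node, both in log-odds units. A latent node's bias
#' is the prior log-odds that the cause is active in a trial; an observable
#' or action node's bias is its background log-odds when no parent is
#' active. Positive edge weights make the child more likely when the parent
#' is active; negative weights make it less likely.
#'
#' @param spec an `sbn_spec`.
#' @param edge_weights either a single number recycled to every edge, or a
#'   named vector keyed by `"parent->child"` (unnamed edges default to 0).
#' @param biases either a single number recycled to every node, or a named
#'   vector keyed by node name (unnamed nodes default to 0).
#' @return An object of class `sbn_weights`: a list with named numeric
#'   vectors `edge_weights` (keyed `"parent->child"`) and `biases`.
#' @examples
#' spec <- default_network_spec()
#' w <- weight_config(spec, edge_weights = c("H1->S1" = 3), biases = -2)
#' @export
weight_config <- function(spec, edge_weights = 0, biases = 0) {
  en <- edge_names(spec)
  nodes <- all_nodes(spec)
  ew <- fill_named(edge_weights, en, "edge_weights")
  bs <- fill_named(biases, nodes, "biases")
  if (!all(is.finite(ew)) || !all(is.finite(bs))) {
    stop("all weights and biases must be finite")
  }
  structure(list(edge_weights = ew, biases = bs), class = "sbn_weights")
}

fill_named <- function(x, keys, what) {
  if (is.null(names(x))) {
    if (length(x) == 1L) {
      out <- stats::setNames(rep(as.numeric(x), length(keys)), keys)
      return(out)
    }
    if (length(x) != length(keys)) {
      stop("`", what, "` must be length 1, fully named, or length ",
           length(keys))
    }
    return(stats::setNames(as.numeric(x), keys))
  }
  unknown <- setdiff(names(x), keys)
  if (length(unknown)) {
    stop("unknown ", what, " name(s): ", paste(unknown, collapse = ", "))
  }
  out <- stats::setNames(rep(0, length(keys)), keys)
  out[names(x)] <- as.numeric(x)
  out
}

#' @export
print.sbn_weights <- function(x, ...) {
  cat("sbn_weights:", length(x$edge_weights), "edge weights,",
      length(x$biases), "biases\n")
  invisible(x)
}

# Flatten an sbn_weights into the canonical theta vector (param_names order).
as_param_vector <- function(weights, spec) {
  pn <- param_names(spec)
  theta <- stats::setNames(numeric(length(pn)), pn)
  theta[paste0("b_", names(weights$biases))] <- weights$biases
  theta[paste0("w_", sub("->", "_", names(weights$edge_weights), fixed = TRUE))] <-
    weights$edge_weights
  theta
}

# Inverse of as_param_vector.
param_vector_to_weights <- function(theta, spec) {
  en <- edge_names(spec)
  nodes <- all_nodes(spec)
  weight_config(spec,
    edge_weights = stats::setNames(
      theta[paste0("w_", sub("->", "_", en, fixed = TRUE))], en),
    biases = stats::setNames(theta[paste0("b_", nodes)], nodes))
}

#' Gaussian prior specification for weights and biases
#'
#' Independent Gaussian priors over every edge weight and every node bias.
#' Edge-weight priors are centered on zero: before training the agent
#' holds no belief about how latent causes or its own action shape the
#' world. Observable/action-node bias priors are likewise zero-centered.
#' Latent-node bias priors are centered on a negative value by default:
#' a hidden cause is a priori a *rare* event (active in a minority of
#' trials). This breaks the active/inactive relabeling symmetry of each
#' latent cause -- with a symmetric prior, the posterior mode in which a
#' cause is "on" outside its own trials and all its weights change sign
#' fits the data equally well -- and anchors the learned solution to the
#' interpretable one in which a cause is on exactly when its observables
#' occur.
#'
#' @param weight_mean,weight_scale prior mean and standard deviation for
#'   edge weights (log-odds units). The default scale 6 is weakly
#'   informative: link weights must be able to express near-deterministic
#'   relations (a lever that appears if and only if its context is
#'   active) and deep cross-inhibition, both of which sit at log-odds
#'   swings of 8-14 that a tight prior would truncate.
#' @param bias_mean,bias_scale prior mean and standard deviation for
#'   observable/action-node biases (used only when biases are learned;
#'   see [fit_posterior()]).
#' @param latent_bias_mean,latent_bias_scale prior mean and standard
#'   deviation for latent-node biases; the default mean -2 corresponds to
#'   a prior activation probability of about 0.12 per trial.
#' @return An object of class `sbn_prior`.
#' @export
prior_spec <- function(weight_mean = 0, weight_scale = 6,
                       bias_mean = 0, bias_scale = 2,
                       latent_bias_mean = -2, latent_bias_scale = 1.5) {
  stopifnot(is.finite(weight_mean), is.finite(bias_mean),
            is.finite(latent_bias_mean))
  if (!isTRUE(weight_scale > 0) || !isTRUE(bias_scale > 0) ||
      !isTRUE(latent_bias_scale > 0)) {
    stop("prior scales must be positive")
  }
  structure(list(weight_mean = weight_mean, weight_scale = weight_scale,
                 bias_mean = bias_mean, bias_scale = bias_scale,
                 latent_bias_mean = latent_bias_mean,
                 latent_bias_scale = latent_bias_scale),
            class = "sbn_prior")
}

# Per-parameter prior mean/sd vectors in theta order.
prior_vectors <- function(prior, spec) {
  pn <- param_names(spec)
  is_bias <- startsWith(pn, "b_")
  is_latent <- pn %in% paste0("b_", spec$latent_nodes)
  list(mean = ifelse(is_latent, prior$latent_bias_mean,
                     ifelse(is_bias, prior$bias_mean, prior$weight_mean)),
       sd = ifelse(is_latent, prior$latent_bias_scale,
                   ifelse(is_bias, prior$bias_scale, prior$weight_scale)))
}

#' Default fixed background biases
#'
#' Named vector of node biases treated as structural constants rather than
#' learned parameters, with one background log-odds per node class.
#' Clamping the biases anchors the active/inactive labeling of each latent
#' cause -- with free biases the posterior prefers relabeled or suppressor
#' modes in which causes are "on" outside their own trials and link
#' weights change sign -- and keeps the background expectation of each
#' food at a level where the absence of the other lever's food during
#' instrumental training is informative, which is what drives the learned
#' cross-inhibition behind PIT inhibition.
#'
#' @param spec an `sbn_spec`.
#' @param cue background log-odds for stimulus and lever nodes. Sounds
#'   and levers are experimenter-controlled: they essentially never occur
#'   spontaneously, so their background is set deeply negative. This also
#'   forces a cue's latent cause on in every bin the cue appears,
#'   including reinforcement omissions, which is what caps the learned
#'   cue-food weight at the empirical pairing rate.
#' @param food background log-odds for food nodes. Food has a small but
#'   real background plausibility (about 8% at the default -2.5): food
#'   must be expected enough that its *absence* during the other lever's
#'   training is informative, the pressure that builds the negative
#'   cross-context weights behind PIT inhibition.
#' @param latent prior log-odds that a latent cause is active (about 5%
#'   at the default -3, matching the base rate of a Pavlovian episode).
#' @param action base log-odds of the action node.
#' @return named numeric vector suitable for the `fixed` argument of
#'   [fit_posterior()].
#' @export
background_biases <- function(spec, cue = -8, food = -2.5, latent = -3,
                              action = 0) {
  c(stats::setNames(rep(latent, length(spec$latent_nodes)),
                    paste0("b_", spec$latent_nodes)),
    stats::setNames(rep(cue, length(spec$stimulus_nodes) +
                          length(spec$lever_nodes)),
                    paste0("b_", c(spec$stimulus_nodes, spec$lever_nodes))),
    stats::setNames(rep(food, length(spec$food_nodes)),
                    paste0("b_", spec$food_nodes)),
    stats::setNames(action, paste0("b_", spec$action_node)))
}

#' Log prior density of a weight configuration
#'
#' Sum of independent Gaussian log-densities over all edge weights and all
#' node biases under a [prior_spec()].
#'
#' @param weights an `sbn_weights`.
#' @param spec the `sbn_spec` the weights belong to.
#' @param prior an `sbn_prior`.
#' @return log-density (scalar).
#' @export
log_prior <- function(weights, spec, prior = prior_spec()) {
  stopifnot(inherits(weights, "sbn_weights"), inherits(prior, "sbn_prior"))
  theta <- as_param_vector(weights, spec)
  pv <- prior_vectors(prior, spec)
  sum(stats::dnorm(theta, pv$mean, pv$sd, log = TRUE))
}
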