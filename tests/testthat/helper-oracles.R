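# Independent brute-force oracles: plain R loops over every latent
# configuration (and over the action state where it must be marginalized),
# written without reference to the package's computational kernels.

brute_row_likelihood <- function(weights, spec, x) {
  lat <- spec$latent_nodes
  nL <- length(lat)
  ew <- weights$edge_weights
  bs <- weights$biases
  an <- spec$action_node
  total <- 0
  for (cfg in 0:(2^nL - 1)) {
    h <- as.integer(intToBits(cfg))[seq_len(nL)]
    p_lat <- prod(ifelse(h == 1, plogis(bs[lat]), 1 - plogis(bs[lat])))
    a_obs <- !is.na(x[[an]])
    a_states <- if (a_obs) x[[an]] else c(0L, 1L)
    p_children <- 0
    for (a in a_states) {
      p <- if (a_obs) 1 else dbinom(a, 1, plogis(bs[[an]]))
      for (nd in names(x)) {
        if (is.na(x[[nd]]) || nd == an) next
        eta <- bs[[nd]]
        for (e in seq_along(ew)) {
          pc <- strsplit(names(ew)[e], "->", fixed = TRUE)[[1]]
          if (pc[2] != nd) next
          state <- if (pc[1] == an) a else h[match(pc[1], lat)]
          eta <- eta + state * ew[[e]]
        }
        p <- p * dbinom(x[[nd]], 1, plogis(eta))
      }
      p_children <- p_children + p
    }
    if (a_obs) p_children <- p_children * dbinom(x[[an]], 1, plogis(bs[[an]]))
    total <- total + p_lat * p_children
  }
  log(total)
}

brute_trials_loglik <- function(weights, spec, trials) {
  obs <- observable_nodes(spec)
  df <- as.data.frame(trials)
  out <- 0
  for (i in seq_len(nrow(df))) {
    x <- as.list(df[i, obs])
    out <- out + df$multiplicity[i] * brute_row_likelihood(weights, spec, x)
  }
  out
}

# Exact posterior over latent configurations by direct Bayes enumeration.
brute_latent_posterior <- function(weights, spec, evidence) {
  lat <- spec$latent_nodes
  nL <- length(lat)
  ew <- weights$edge_weights
  bs <- weights$biases
  an <- spec$action_node
  obs <- observable_nodes(spec)
  x <- as.list(as.data.frame(evidence)[1, obs])
  w_unnorm <- numeric(2^nL)
  for (cfg in 0:(2^nL - 1)) {
    h <- as.integer(intToBits(cfg))[seq_len(nL)]
    p <- prod(ifelse(h == 1, plogis(bs[lat]), 1 - plogis(bs[lat])))
    a_obs <- !is.na(x[[an]])
    a_states <- if (a_obs) x[[an]] else c(0L, 1L)
    pc_tot <- 0
    for (a in a_states) {
      pa <- if (a_obs) 1 else dbinom(a, 1, plogis(bs[[an]]))
      for (nd in names(x)) {
        if (is.na(x[[nd]]) || nd == an) next
        eta <- bs[[nd]]
        for (e in seq_along(ew)) {
          pc <- strsplit(names(ew)[e], "->", fixed = TRUE)[[1]]
          if (pc[2] != nd) next
          state <- if (pc[1] == an) a else h[match(pc[1], lat)]
          eta <- eta + state * ew[[e]]
        }
        pa <- pa * dbinom(x[[nd]], 1, plogis(eta))
      }
      pc_tot <- pc_tot + pa
    }
    if (a_obs) pc_tot <- pc_tot * dbinom(x[[an]], 1, plogis(bs[[an]]))
    w_unnorm[cfg + 1] <- p * pc_tot
  }
  w_unnorm / sum(w_unnorm)
}

random_weights <- function(spec, sd_w = 3, sd_b = 2) {
  weight_config(spec,
    edge_weights = stats::setNames(rnorm(nrow(spec$edges), 0, sd_w),
                                   pitsbn:::edge_names(spec)),
    biases = stats::setNames(rnorm(length(pitsbn:::all_nodes(spec)), 0, sd_b),
                             pitsbn:::all_nodes(spec)))
}

random_trial <- function(spec) {
  obs <- observable_nodes(spec)
  x <- sample(c(0L, 1L, NA), length(obs), replace = TRUE)
  if (all(is.na(x))) x[1] <- 1L
  names(x) <- obs
  do.call(trial_record, c(list(spec = spec), as.list(x)))
}

# Minimal one-latent network used for closed-form and grid checks.
toy_spec <- function() {
  network_spec(latent_nodes = "H1", stimulus_nodes = character(0),
               lever_nodes = character(0), food_nodes = "F1",
               action_node = "A",
               edges = data.frame(parent = "H1", child = "F1"))
}
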