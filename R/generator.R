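#' Paradigm configuration for the synthetic PIT experiment
#'
#' Parameters of the simulated three-phase conditioning paradigm. Time is
#' discretized into trial bins. Pavlovian bins pair each sound with its
#' food; instrumental bins present one lever, with pressing emitted at
#' `press_prob` and food delivered per press at `reinforce_prob` -- a
#' random-ratio RR-k schedule modeled as per-press reward probability 1/k,
#' so the default 0.05 is RR20 ("about once every 20 presses"). Blank bins
#' with every node absent are interleaved per phase so background rates
#' (biases) are identifiable, and no-press bins make the action-outcome
#' contingency identifiable.
#'
#' @param n_pavlovian_per_cs Pavlovian bins per conditioned stimulus.
#' @param pavlovian_pairing_prob probability that the food accompanies its
#'   sound in a Pavlovian bin. The default 0.85 keeps the pairing reliable
#'   but probabilistic: occasional omissions anchor the learned
#'   sound-food expectation to an empirical rate instead of letting it
#'   saturate at the prior ceiling.
#' @param n_instrumental_per_lever instrumental bins per lever. Random
#'   ratio schedules require extensive training (an RR20 animal
#'   accumulates hundreds of presses per lever before testing), and the
#'   default 400 bins per lever reflects that scale.
#' @param press_prob probability the action is emitted in an instrumental
#'   bin. Press and no-press bins in roughly equal measure (default 0.5)
#'   make the action-outcome contingency identifiable: with near-constant
#'   pressing the action's effect is confounded with its context's.
#' @param reinforce_prob probability of food given a press (1/k for an
#'   RR-k schedule; default RR20).
#' @param n_blank all-absent bins appended to each phase.
#' @param cross_food_leak probability that the *other* instrumental food
#'   appears in a lever's session bin; nonzero values emulate procedures
#'   where the two levers share context rather than excluding each other.
#' @param seed integer seed, or NULL to use the current RNG state.
#' @return An object of class `paradigm_config`.
#' @export
paradigm_config <- function(n_pavlovian_per_cs = 100,
                            pavlovian_pairing_prob = 0.85,
                            n_instrumental_per_lever = 400,
                            press_prob = 0.5,
                            reinforce_prob = 0.05,
                            n_blank = 100,
                            cross_food_leak = 0.0,
                            seed = NULL) {
  probs <- c(pavlovian_pairing_prob, press_prob, reinforce_prob,
             cross_food_leak)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  counts <- c(n_pavlovian_per_cs, n_instrumental_per_lever, n_blank)
  if (any(counts < 0)) stop("trial counts must be non-negative")
  structure(list(n_pavlovian_per_cs = as.integer(n_pavlovian_per_cs),
                 pavlovian_pairing_prob = pavlovian_pairing_prob,
                 n_instrumental_per_lever = as.integer(n_instrumental_per_lever),
                 press_prob = press_prob,
                 reinforce_prob = reinforce_prob,
                 n_blank = as.integer(n_blank),
                 cross_food_leak = cross_food_leak,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "paradigm_config")
}

# Run expr under a seed without disturbing the caller's RNG stream;
# seed = NULL draws from the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

blank_bins <- function(spec, n) {
  obs <- observable_nodes(spec)
  if (n == 0) {
    return(trials_frame(spec, as.data.frame(matrix(integer(), 0,
      length(obs), dimnames = list(NULL, obs)))))
  }
  states <- as.data.frame(matrix(0L, n, length(obs),
                                 dimnames = list(NULL, obs)))
  trials_frame(spec, states, phase = "blank")
}

#' Generate the Pavlovian phase
#'
#' For each conditioned stimulus `S_i` (paired positionally with food
#' `F_i`), emits `n_pavlovian_per_cs` bins with the sound present and its
#' food present with probability `pavlovian_pairing_prob`; all other
#' observables and the action are absent. `n_blank` all-absent bins are
#' appended. Deterministic given `config$seed`.
#'
#' @param config a [paradigm_config()].
#' @param spec an `sbn_spec`.
#' @return an `sbn_trials`.
#' @export
generate_pavlovian_phase <- function(config, spec) {
  with_seed(config$seed, {
    obs <- observable_nodes(spec)
    blocks <- lapply(seq_along(spec$stimulus_nodes), function(i) {
      n <- config$n_pavlovian_per_cs
      states <- as.data.frame(matrix(0L, n, length(obs),
                                     dimnames = list(NULL, obs)))
      states[[spec$stimulus_nodes[i]]] <- 1L
      states[[spec$food_nodes[i]]] <-
        stats::rbinom(n, 1L, config$pavlovian_pairing_prob)
      trials_frame(spec, states, phase = "pavlovian")
    })
    do.call(bind_trials, c(blocks, list(blank_bins(spec, config$n_blank))))
  })
}

#' Generate the instrumental phase
#'
#' For each lever `L_j` (paired positionally with food `F_j`), emits
#' `n_instrumental_per_lever` bins with the lever present, no sounds, the
#' action emitted with `press_prob`, and the lever's food delivered with
#' `reinforce_prob` when the action occurred (probabilistic random-ratio
#' reinforcement). The other lever's food appears with probability
#' `cross_food_leak` (default never); the purely Pavlovian food never
#' appears. `n_blank` all-absent bins are appended. Deterministic given
#' `config$seed`.
#'
#' @inheritParams generate_pavlovian_phase
#' @return an `sbn_trials`.
#' @export
generate_instrumental_phase <- function(config, spec) {
  with_seed(config$seed, {
    obs <- observable_nodes(spec)
    levers <- spec$lever_nodes
    blocks <- lapply(seq_along(levers), function(j) {
      n <- config$n_instrumental_per_lever
      states <- as.data.frame(matrix(0L, n, length(obs),
                                     dimnames = list(NULL, obs)))
      states[[levers[j]]] <- 1L
      a <- stats::rbinom(n, 1L, config$press_prob)
      states[[spec$action_node]] <- a
      states[[spec$food_nodes[j]]] <-
        a * stats::rbinom(n, 1L, config$reinforce_prob)
      other <- setdiff(seq_along(levers), j)
      for (o in other) {
        states[[spec$food_nodes[o]]] <-
          stats::rbinom(n, 1L, config$cross_food_leak)
      }
      trials_frame(spec, states, phase = "instrumental")
    })
    do.call(bind_trials, c(blocks, list(blank_bins(spec, config$n_blank))))
  })
}

#' Generate the full training set (Pavlovian + instrumental)
#'
#' Runs both phase generators under a single seed (the Pavlovian phase
#' consumes the stream first) and binds the results.
#'
#' @inheritParams generate_pavlovian_phase
#' @return an `sbn_trials`.
#' @export
generate_paradigm <- function(config, spec) {
  with_seed(config$seed, {
    unseeded <- config
    unseeded$seed <- NULL
    bind_trials(generate_pavlovian_phase(unseeded, spec),
                generate_instrumental_phase(unseeded, spec))
  })
}

#' Define a test condition
#'
#' Maps a condition label to the lever and sound shown at test. With lever
#' `L1` (instrumental food `F1`): *baseline* plays no sound; *same* plays
#' the sound paired with the lever's own food (S1); *different* plays the
#' sound paired with the other lever's food (S2); *general* plays the sound
#' whose food was never an instrumental outcome (S3).
#'
#' @param label one of `"baseline"`, `"same"`, `"different"`, `"general"`.
#' @param lever lever node shown at test.
#' @param spec an `sbn_spec`.
#' @return An object of class `test_condition` with fields `label`,
#'   `lever`, `sound` (NA for baseline).
#' @export
test_condition <- function(label, lever = "L1", spec = default_network_spec()) {
  if (!label %in% c("baseline", "same", "different", "general")) {
    stop("unknown test condition label: ", label)
  }
  j <- match(lever, spec$lever_nodes)
  if (is.na(j)) stop("unknown lever: ", lever)
  n_lev <- length(spec$lever_nodes)
  sound <- switch(label,
    baseline = NA_character_,
    same = spec$stimulus_nodes[j],
    different = spec$stimulus_nodes[setdiff(seq_len(n_lev), j)[1]],
    general = spec$stimulus_nodes[n_lev + 1])
  structure(list(label = label, lever = lever, sound = sound),
            class = "test_condition")
}

#' Evidence trial for a test condition
#'
#' Builds the extinction-test evidence: the shown lever present, the other
#' lever absent, the shown sound (if any) present and the others absent,
#' all foods unobserved, and the action unobserved (it is clamped
#' downstream as the evaluated option, never used as evidence). Test
#' trials are never added to the training set: testing is in extinction so
#' no further learning occurs.
#'
#' @param condition a [test_condition()] (or a label passed through it).
#' @param spec an `sbn_spec`.
#' @param lever lever used when `condition` is given as a bare label.
#' @return a one-row `sbn_trials` with phase `"test"`.
#' @export
test_evidence <- function(condition, spec, lever = "L1") {
  if (is.character(condition)) {
    condition <- test_condition(condition, lever = lever, spec = spec)
  }
  states <- as.list(stats::setNames(
    rep(0L, length(spec$stimulus_nodes) + length(spec$lever_nodes)),
    c(spec$stimulus_nodes, spec$lever_nodes)))
  states[[condition$lever]] <- 1L
  if (!is.na(condition$sound)) states[[condition$sound]] <- 1L
  do.call(trial_record, c(list(spec = spec), states, list(phase = "test")))
}
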