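#' Utility vector over foods
#'
#' Subjective value of each food outcome. The default (1 per food) is the
#' hungry state; satiety is modeled by setting values to zero
#' (devaluation), either globally or per food.
#'
#' @param spec an `sbn_spec`.
#' @param value single value recycled over foods, or a named vector keyed
#'   by food node.
#' @return named non-negative numeric vector over the food nodes.
#' @export
utility_vector <- function(spec, value = 1) {
  u <- fill_named(value, spec$food_nodes, "utilities")
  if (any(u < 0)) stop("utilities must be non-negative")
  u
}

#' Evaluation configuration
#'
#' Gains of the response rule `R = alpha * E + beta * U`, where E is the
#' efficacy (probability of the action's own outcome under intervention)
#' and U the utility of additional predicted outcomes, plus the target
#' food the shown lever is known to deliver.
#'
#' @param target_food food node contingent on the shown lever.
#' @param alpha efficacy gain (>= 0).
#' @param beta utility gain (>= 0).
#' @return An object of class `eval_config`.
#' @export
evaluation_config <- function(target_food = "F1", alpha = 1, beta = 1) {
  if (alpha < 0 || beta < 0) stop("gains must be non-negative")
  structure(list(target_food = target_food, alpha = alpha, beta = beta),
            class = "eval_config")
}

# Normalize samples to a draws matrix in theta order.
draws_matrix <- function(samples, spec) {
  if (inherits(samples, "sbn_posterior")) {
    return(samples$draws)
  }
  if (inherits(samples, "sbn_weights")) {
    return(matrix(as_param_vector(samples, spec), nrow = 1,
                  dimnames = list(NULL, param_names(spec))))
  }
  if (is.matrix(samples)) return(samples)
  stop("`samples` must be an sbn_posterior, sbn_weights, or draws matrix")
}

evidence_row <- function(evidence, spec) {
  if (!inherits(evidence, "sbn_trials") || nrow(evidence) != 1) {
    stop("`evidence` must be a one-row sbn_trials")
  }
  as_trial_matrix(evidence, spec)[1, ]
}

#' Exact posterior over latent-cause configurations
#'
#' Enumerates all 2^k joint configurations of the k latent causes and
#' returns their exact posterior probabilities given the evidence:
#' `P(config | evidence)` proportional to the product of latent Bernoulli
#' priors and the Bernoulli likelihood of every observed child. Unobserved
#' nodes contribute nothing; the action node, if unobserved, is
#' marginalized when any of its children is observed.
#'
#' @param weights an `sbn_weights` (a single configuration, e.g. posterior
#'   means).
#' @param spec an `sbn_spec`.
#' @param evidence a one-row `sbn_trials` with no latent entries.
#' @return data frame with one 0/1 column per latent node and a
#'   `probability` column summing to 1.
#' @export
infer_latent_posterior <- function(weights, spec, evidence) {
  theta <- as_param_vector(weights, spec)
  p <- cpp_latent_posterior(theta, build_model(spec),
                            as.integer(evidence_row(evidence, spec)))
  k <- length(spec$latent_nodes)
  configs <- as.data.frame(lapply(seq_len(k) - 1L, function(h) {
    bitwAnd(bitwShiftR(seq_along(p) - 1L, h), 1L)
  }))
  names(configs) <- spec$latent_nodes
  configs$probability <- as.numeric(p)
  configs
}

#' Posterior-predictive probability of a food
#'
#' Probability that `food` appears given the test evidence, with the
#' action clamped to `action_state` (an intervention: pressing is the
#' option being evaluated, so the action is set, never used as evidence
#' about the latents). For each posterior draw the latent posterior is
#' computed exactly and the food's activation probability averaged over
#' it; the result is the mean over draws.
#'
#' @param samples an `sbn_posterior`, an `sbn_weights`, or a draws matrix.
#' @param spec an `sbn_spec`.
#' @param evidence a one-row `sbn_trials`; the food must be unobserved.
#' @param action_state 0 or 1.
#' @param food a food node name.
#' @return probability in (0, 1).
#' @export
predict_food_probability <- function(samples, spec, evidence, action_state,
                                     food) {
  if (!food %in% spec$food_nodes) stop("unknown food node: ", food)
  if (!action_state %in% c(0, 1)) stop("action_state must be 0 or 1")
  x <- evidence_row(evidence, spec)
  obs <- observable_nodes(spec)
  if (x[match(food, obs)] >= 0) {
    stop("food ", food, " is observed in the evidence; it must be predicted")
  }
  draws <- draws_matrix(samples, spec)
  mean(cpp_predict_food(draws, build_model(spec), as.integer(x),
                        as.integer(action_state),
                        match(food, obs) - 1L))
}

#' Efficacy of the action
#'
#' The probability of reaching the action's own goal: the predicted
#' probability of the target food with the action clamped on. Efficacy
#' reads no utilities, so it is untouched by devaluation -- the mechanism
#' behind specific PIT's immunity to satiety.
#'
#' @inheritParams predict_food_probability
#' @param config an [evaluation_config()] naming the target food.
#' @return probability in (0, 1).
#' @export
efficacy <- function(samples, spec, evidence, config) {
  predict_food_probability(samples, spec, evidence, 1L, config$target_food)
}

#' Utility of additional predicted outcomes
#'
#' Value of the rewards predicted to appear beyond the action's own
#' outcome: the utility-weighted sum, over every food other than the
#' target, of its predicted probability with the action clamped on. A cue
#' that adds a new food to the predicted scene raises U (general PIT); a
#' sated state (all-zero utilities) sends U to zero.
#'
#' @inheritParams efficacy
#' @param utilities a [utility_vector()].
#' @return non-negative value.
#' @export
utility <- function(samples, spec, evidence, utilities, config) {
  others <- setdiff(spec$food_nodes, config$target_food)
  sum(vapply(others, function(f) {
    utilities[[f]] * predict_food_probability(samples, spec, evidence, 1L, f)
  }, numeric(1)))
}

#' Response score
#'
#' Linear combination `R = alpha * E + beta * U` of efficacy and utility.
#' PIT effects are reported as differences from the baseline condition,
#' not absolute press rates.
#'
#' @inheritParams utility
#' @return real score.
#' @export
response_score <- function(samples, spec, evidence, utilities, config) {
  config$alpha * efficacy(samples, spec, evidence, config) +
    config$beta * utility(samples, spec, evidence, utilities, config)
}

#' Evaluate one test condition in full
#'
#' @param samples an `sbn_posterior` (or `sbn_weights`).
#' @param spec an `sbn_spec`.
#' @param condition a [test_condition()] or its label.
#' @param utilities a [utility_vector()]; defaults to 1 per food.
#' @param config an [evaluation_config()]; defaults to the food paired
#'   with the shown lever.
#' @param lever lever shown at test.
#' @return An object of class `sbn_evaluation`: condition label, `E`, `U`,
#'   `R`, per-food predicted probabilities under both action states, and
#'   the latent posterior (averaged over draws).
#' @export
evaluate_condition <- function(samples, spec, condition,
                               utilities = utility_vector(spec),
                               config = NULL, lever = "L1") {
  if (is.character(condition)) {
    condition <- test_condition(condition, lever = lever, spec = spec)
  }
  if (is.null(config)) {
    j <- match(condition$lever, spec$lever_nodes)
    config <- evaluation_config(target_food = spec$food_nodes[j])
  }
  evidence <- test_evidence(condition, spec)
  E <- efficacy(samples, spec, evidence, config)
  U <- utility(samples, spec, evidence, utilities, config)
  food_probs <- data.frame(
    food = spec$food_nodes,
    p_action = vapply(spec$food_nodes, function(f) {
      predict_food_probability(samples, spec, evidence, 1L, f)
    }, numeric(1)),
    p_no_action = vapply(spec$food_nodes, function(f) {
      predict_food_probability(samples, spec, evidence, 0L, f)
    }, numeric(1)),
    row.names = NULL)
  draws <- draws_matrix(samples, spec)
  model <- build_model(spec)
  x <- as.integer(evidence_row(evidence, spec))
  post <- rowMeans(vapply(seq_len(nrow(draws)), function(d) {
    as.numeric(cpp_latent_posterior(draws[d, ], model, x))
  }, numeric(2^length(spec$latent_nodes))))
  structure(list(condition = condition, label = condition$label,
                 E = E, U = U,
                 R = config$alpha * E + config$beta * U,
                 food_probs = food_probs, latent_posterior = post,
                 utilities = utilities, config = config),
            class = "sbn_evaluation")
}

#' Run the four-condition PIT test battery
#'
#' Evaluates baseline, same, different and general conditions on one lever
#' and reports efficacy, utility, response score and the PIT effect
#' (response score minus baseline) per condition. Deterministic given the
#' sample set.
#'
#' @inheritParams evaluate_condition
#' @param conditions condition labels to evaluate.
#' @return data frame with columns `condition`, `E`, `U`, `R`, `effect`.
#' @export
run_pit_battery <- function(samples, spec,
                            utilities = utility_vector(spec),
                            config = NULL, lever = "L1",
                            conditions = c("baseline", "same", "different",
                                           "general")) {
  evals <- lapply(conditions, function(lab) {
    evaluate_condition(samples, spec, lab, utilities = utilities,
                       config = config, lever = lever)
  })
  out <- data.frame(condition = conditions,
                    E = vapply(evals, `[[`, numeric(1), "E"),
                    U = vapply(evals, `[[`, numeric(1), "U"),
                    R = vapply(evals, `[[`, numeric(1), "R"),
                    row.names = NULL)
  base <- out$R[out$condition == "baseline"]
  out$effect <- if (length(base)) out$R - base else NA_real_
  out
}

#' Devaluation experiment
#'
#' Runs the PIT battery twice -- hungry (all utilities 1) and sated (all
#' utilities 0) -- and tabulates per-condition PIT effects. Satiety
#' removes the utility term entirely, so the general-PIT effect vanishes
#' exactly while efficacy, and with it specific PIT, is bit-identical
#' across states.
#'
#' @inheritParams run_pit_battery
#' @return list with battery data frames `hungry` and `sated` and an
#'   `effects` data frame (condition, hungry_effect, sated_effect).
#' @export
devaluation_experiment <- function(samples, spec, config = NULL,
                                   lever = "L1") {
  hungry <- run_pit_battery(samples, spec, utility_vector(spec, 1),
                            config = config, lever = lever)
  sated <- run_pit_battery(samples, spec, utility_vector(spec, 0),
                           config = config, lever = lever)
  list(hungry = hungry, sated = sated,
       effects = data.frame(condition = hungry$condition,
                            hungry_effect = hungry$effect,
                            sated_effect = sated$effect))
}

#' Generate, fit and evaluate in one call
#'
#' End-to-end pipeline: generate the paradigm, fit the posterior, run the
#' battery. All randomness flows from `paradigm$seed` and `mcmc$seed`.
#'
#' @param paradigm a [paradigm_config()].
#' @param spec an `sbn_spec`.
#' @param prior an [prior_spec()].
#' @param mcmc an [mcmc_config()].
#' @param utilities a [utility_vector()].
#' @param lever lever used at test.
#' @return list with `trials`, `fit`, `battery`.
#' @export
run_pipeline <- function(paradigm = paradigm_config(),
                         spec = default_network_spec(),
                         prior = prior_spec(), mcmc = mcmc_config(),
                         utilities = utility_vector(spec), lever = "L1") {
  trials <- generate_paradigm(paradigm, spec)
  fit <- fit_posterior(trials, spec, prior = prior, mcmc = mcmc)
  battery <- run_pit_battery(fit, spec, utilities = utilities, lever = lever)
  list(trials = trials, fit = fit, battery = battery)
}

#' Reinforcement-schedule sweep
#'
#' Runs the full pipeline for each per-press reward probability and
#' reports how the specific-PIT effect (`E_same - E_baseline`) changes
#' with the schedule. Under continuous reinforcement (probability 1) the
#' action already succeeds with near certainty at baseline, so a cue
#' predicting the same food has almost nothing to add and specific PIT
#' should collapse while general PIT survives.
#'
#' @param reinforce_probs per-press reward probabilities to sweep.
#' @param paradigm base [paradigm_config()]; its `reinforce_prob` and
#'   `seed` are overridden per run.
#' @param spec,prior,mcmc as in [run_pipeline()].
#' @param seed root seed; run i derives paradigm seed `seed + 101 * i` and
#'   MCMC seed `seed + 101 * i + 50`.
#' @return data frame with one row per schedule: `reinforce_prob`,
#'   `E_baseline`, `E_same`, `specific_effect`, `general_effect`.
#' @export
schedule_sweep <- function(reinforce_probs = c(0.05, 0.25, 0.5, 1.0),
                           paradigm = paradigm_config(),
                           spec = default_network_spec(),
                           prior = prior_spec(), mcmc = mcmc_config(),
                           seed = 1) {
  rows <- lapply(seq_along(reinforce_probs), function(i) {
    p <- paradigm
    p$reinforce_prob <- reinforce_probs[i]
    p$seed <- as.integer(seed + 101 * i)
    m <- mcmc
    m$seed <- as.integer(seed + 101 * i + 50)
    run <- run_pipeline(p, spec, prior, m)
    b <- run$battery
    data.frame(reinforce_prob = reinforce_probs[i],
               E_baseline = b$E[b$condition == "baseline"],
               E_same = b$E[b$condition == "same"],
               specific_effect = b$E[b$condition == "same"] -
                 b$E[b$condition == "baseline"],
               general_effect = b$effect[b$condition == "general"])
  })
  do.call(rbind, rows)
}

#' Context-overlap sweep
#'
#' Runs the full pipeline for each cross-food leak probability: the
#' probability that the other lever's food appears during a lever's
#' training sessions. With no leak the instrumental contexts exclude each
#' other's food (negative cross-weights) and the different-condition cue
#' is fully inhibited; as the leak grows the learned inhibition weakens
#' and a PIT effect emerges in the different condition.
#'
#' @param leaks cross-food leak probabilities to sweep.
#' @inheritParams schedule_sweep
#' @param lever lever used at test (its context's cross-food weight is
#'   reported).
#' @return data frame with one row per leak: `cross_food_leak`,
#'   `different_effect` (R_different - R_baseline), `w_cross` (posterior
#'   mean weight from the shown lever's context to the other instrumental
#'   food).
#' @export
context_overlap_sweep <- function(leaks = c(0, 0.1, 0.3),
                                  paradigm = paradigm_config(),
                                  spec = default_network_spec(),
                                  prior = prior_spec(), mcmc = mcmc_config(),
                                  seed = 1, lever = "L1") {
  j <- match(lever, spec$lever_nodes)
  ctx <- spec$edges$parent[spec$edges$child == lever &
                             spec$edges$parent %in% spec$latent_nodes][1]
  other_food <- spec$food_nodes[setdiff(seq_along(spec$lever_nodes), j)[1]]
  w_name <- paste0("w_", ctx, "_", other_food)
  rows <- lapply(seq_along(leaks), function(i) {
    p <- paradigm
    p$cross_food_leak <- leaks[i]
    p$seed <- as.integer(seed + 211 * i)
    m <- mcmc
    m$seed <- as.integer(seed + 211 * i + 50)
    run <- run_pipeline(p, spec, prior, m, lever = lever)
    b <- run$battery
    data.frame(cross_food_leak = leaks[i],
               different_effect = b$effect[b$condition == "different"],
               w_cross = mean(run$fit$draws[, w_name]))
  })
  do.call(rbind, rows)
}

#' Write / read a battery table as CSV
#'
#' @param battery data frame from [run_pit_battery()].
#' @param path file path.
#' @return `write_battery_csv` returns `path` invisibly; `read_battery_csv`
#'   returns the data frame.
#' @export
write_battery_csv <- function(battery, path) {
  utils::write.csv(battery, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_battery_csv
#' @export
read_battery_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
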