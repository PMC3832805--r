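spec <- default_network_spec()

test_that("latent posterior matches brute-force Bayes enumeration", {
  set.seed(61)
  for (r in 1:30) {
    w <- random_weights(spec)
    ev <- test_evidence(sample(c("baseline", "same", "different", "general"),
                               1), spec,
                        lever = sample(spec$lever_nodes, 1))
    post <- infer_latent_posterior(w, spec, ev)
    expect_equal(sum(post$probability), 1, tolerance = 1e-10)
    expect_equal(post$probability, brute_latent_posterior(w, spec, ev),
                 tolerance = 1e-10)
  }
})

test_that("latent posterior reduces to the prior when weights are zero", {
  w0 <- weight_config(spec, biases = c(H1 = -1, H2 = 0.5, H3 = -2,
                                       H4 = 0, H5 = 1))
  post <- infer_latent_posterior(w0, spec, test_evidence("same", spec))
  prior_p <- plogis(c(-1, 0.5, -2, 0, 1))
  manual <- apply(post[, spec$latent_nodes], 1, function(h) {
    prod(ifelse(h == 1, prior_p, 1 - prior_p))
  })
  expect_equal(post$probability, unname(manual), tolerance = 1e-12)
  # a strong cue-cause link raises the cause's posterior above its prior
  w1 <- weight_config(spec, edge_weights = c("H1->S1" = 5),
                      biases = c(H1 = -2, S1 = -3))
  post1 <- infer_latent_posterior(w1, spec, test_evidence("same", spec))
  expect_gt(sum(post1$probability[post1$H1 == 1]), plogis(-2))
})

test_that("food prediction is a posterior-weighted sigmoid average", {
  # degenerate zero-weight draws: sigma(bias) regardless of evidence/action
  w0 <- weight_config(spec, biases = c(F2 = -1.2))
  ev <- test_evidence("different", spec)
  expect_equal(predict_food_probability(w0, spec, ev, 1, "F2"),
               plogis(-1.2), tolerance = 1e-12)
  expect_equal(predict_food_probability(w0, spec, ev, 0, "F2"),
               plogis(-1.2), tolerance = 1e-12)
  # monotone: adding a positive active parent weight cannot decrease it
  w1 <- weight_config(spec, edge_weights = c("A->F2" = 2),
                      biases = c(F2 = -1.2))
  expect_gt(predict_food_probability(w1, spec, ev, 1, "F2"),
            predict_food_probability(w0, spec, ev, 1, "F2"))
  expect_equal(predict_food_probability(w1, spec, ev, 0, "F2"),
               plogis(-1.2), tolerance = 1e-12)  # action clamped off
  # equals the brute-force double sum on a 2-draw sample set
  set.seed(62)
  wa <- random_weights(spec)
  wb <- random_weights(spec)
  pn <- pitsbn:::param_names(spec)
  draws <- rbind(pitsbn:::as_param_vector(wa, spec),
                 pitsbn:::as_param_vector(wb, spec))
  colnames(draws) <- pn
  got <- predict_food_probability(draws, spec, ev, 1, "F1")
  manual <- mean(vapply(list(wa, wb), function(w) {
    post <- brute_latent_posterior(w, spec, ev)
    lat <- spec$latent_nodes
    sum(vapply(seq_along(post), function(cfg) {
      h <- as.integer(intToBits(cfg - 1))[seq_along(lat)]
      eta <- w$biases[["F1"]] + w$edge_weights[["A->F1"]]
      for (i in seq_along(lat)) {
        nm <- paste0(lat[i], "->F1")
        if (nm %in% names(w$edge_weights)) {
          eta <- eta + h[i] * w$edge_weights[[nm]]
        }
      }
      post[cfg] * plogis(eta)
    }, numeric(1)))
  }, numeric(1)))
  expect_equal(got, manual, tolerance = 1e-10)
  # errors: observed food, invalid action state
  ev_obs <- trial_record(spec, L1 = 1, F1 = 1)
  expect_error(predict_food_probability(w0, spec, ev_obs, 1, "F1"),
               "observed")
  expect_error(predict_food_probability(w0, spec, ev, 2, "F1"),
               "action_state")
  expect_error(predict_food_probability(w0, spec, ev, 1, "S1"),
               "unknown food")
})

test_that("efficacy ignores utilities and utility excludes the target food", {
  set.seed(63)
  w <- random_weights(spec)
  ev <- test_evidence("general", spec)
  cfg <- evaluation_config("F1")
  E <- efficacy(w, spec, ev, cfg)
  expect_equal(E, predict_food_probability(w, spec, ev, 1, "F1"))
  # utility is linear in each u_j and excludes F1
  u1 <- utility_vector(spec, c(F1 = 99, F2 = 1, F3 = 1))
  u2 <- utility_vector(spec, c(F1 = 0, F2 = 2, F3 = 2))
  U1 <- utility(w, spec, ev, u1, cfg)
  U2 <- utility(w, spec, ev, u2, cfg)
  expect_equal(U2, 2 * U1, tolerance = 1e-12)  # F1's weight is irrelevant
  expect_equal(utility(w, spec, ev, utility_vector(spec, 0), cfg), 0)
  # response score combines the two linearly
  R <- response_score(w, spec, ev, u1, cfg)
  expect_equal(R, E + U1, tolerance = 1e-12)
  cfg2 <- evaluation_config("F1", alpha = 2, beta = 0)
  expect_equal(response_score(w, spec, ev, u1, cfg2), 2 * E,
               tolerance = 1e-12)
  expect_error(utility_vector(spec, -1), "non-negative")
  expect_error(evaluation_config("F1", alpha = -1), "non-negative")
})

test_that("an untrained network responds identically across conditions", {
  w0 <- weight_config(spec, biases = c(H1 = -2, H2 = -2, H3 = -2,
                                       H4 = -2, H5 = -2, F1 = -2, F2 = -2,
                                       F3 = -2))
  b <- run_pit_battery(w0, spec)
  expect_equal(nrow(b), 4)
  expect_equal(b$condition, c("baseline", "same", "different", "general"))
  expect_true(all(abs(b$R - b$R[1]) < 1e-12))
  expect_true(all(abs(b$effect) < 1e-12))
})

test_that("battery tables round-trip through CSV", {
  w0 <- weight_config(spec)
  b <- run_pit_battery(w0, spec)
  path <- withr::local_tempfile(fileext = ".csv")
  write_battery_csv(b, path)
  back <- read_battery_csv(path)
  expect_equal(back$condition, b$condition)
  expect_equal(back$R, b$R, tolerance = 1e-12)
})

test_that("devaluation zeroes general PIT exactly and leaves efficacy bit-identical", {
  fit <- cached_default_fit()
  dev <- devaluation_experiment(fit, spec)
  sated <- dev$sated
  hungry <- dev$hungry
  expect_true(all(sated$U == 0))
  expect_identical(sated$E, hungry$E)  # efficacy never reads utilities
  expect_equal(sated$effect[sated$condition == "general"],
               sated$E[sated$condition == "general"] -
                 sated$E[sated$condition == "baseline"])
  # hungry table reproduces the plain battery
  expect_equal(hungry, run_pit_battery(fit, spec, utility_vector(spec, 1)))
  # specific PIT (an efficacy difference) is invariant under devaluation
  spec_hungry <- hungry$E[hungry$condition == "same"] -
    hungry$E[hungry$condition == "baseline"]
  spec_sated <- sated$E[sated$condition == "same"] -
    sated$E[sated$condition == "baseline"]
  expect_identical(spec_hungry, spec_sated)
})

test_that("a trained model shows the PIT battery pattern", {
  fit <- cached_default_fit()
  b <- run_pit_battery(fit, spec)
  eff <- setNames(b$effect, b$condition)
  expect_gt(eff[["same"]], 0.1)
  expect_gt(eff[["general"]], 0.1)
  expect_lt(abs(eff[["different"]]),
            0.25 * min(eff[["same"]], eff[["general"]]))
  ev <- evaluate_condition(fit, spec, "same")
  expect_equal(ev$R, ev$config$alpha * ev$E + ev$config$beta * ev$U)
  expect_equal(sum(ev$latent_posterior), 1, tolerance = 1e-10)
  expect_equal(dim(ev$food_probs), c(3L, 3L))
  expect_true(all(ev$food_probs$p_action >= 0 & ev$food_probs$p_action <= 1))
})

test_that("sweeps run end-to-end, reproducibly, with the expected schema", {
  tiny <- paradigm_config(n_pavlovian_per_cs = 15,
                          n_instrumental_per_lever = 40, n_blank = 20)
  mc <- mcmc_config(n_iterations = 800, n_burn_in = 300, thinning = 2)
  s1 <- schedule_sweep(c(0.05, 1), paradigm = tiny, mcmc = mc, seed = 71)
  s2 <- schedule_sweep(c(0.05, 1), paradigm = tiny, mcmc = mc, seed = 71)
  expect_identical(s1, s2)
  expect_equal(names(s1), c("reinforce_prob", "E_baseline", "E_same",
                            "specific_effect", "general_effect"))
  # baseline efficacy rises with the reinforcement rate
  expect_gt(s1$E_baseline[2], s1$E_baseline[1])
  c1 <- context_overlap_sweep(c(0, 0.3), paradigm = tiny, mcmc = mc,
                              seed = 72)
  expect_equal(names(c1), c("cross_food_leak", "different_effect", "w_cross"))
  expect_equal(nrow(c1), 2)
})
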