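test_that("default network has the fixed PIT adjacency", {
  spec <- default_network_spec()
  expect_equal(nrow(spec$edges), 14)
  expect_true(has_edge(spec, "A", "F1"))
  expect_true(has_edge(spec, "A", "F2"))
  expect_false(has_edge(spec, "A", "F3"))
  for (i in 1:3) {
    expect_true(has_edge(spec, paste0("H", i), paste0("S", i)))
    expect_true(has_edge(spec, paste0("H", i), paste0("F", i)))
  }
  expect_true(all(has_edge(spec, "H4", "L1"), has_edge(spec, "H4", "F1"),
                  has_edge(spec, "H4", "F2")))
  expect_true(all(has_edge(spec, "H5", "L2"), has_edge(spec, "H5", "F1"),
                  has_edge(spec, "H5", "F2")))
  # no edges into latent or action nodes, none from action to non-foods
  expect_false(any(spec$edges$child %in% c(spec$latent_nodes,
                                           spec$action_node)))
})

test_that("invalid network structures are rejected", {
  expect_error(network_spec("H1", "S1", "L1", "F1", "A",
                            data.frame(parent = "A", child = "S1")),
               "latent->observable or action->food")
  expect_error(network_spec("H1", "S1", "L1", "F1", "A",
                            data.frame(parent = "S1", child = "F1")),
               "latent->observable or action->food")
  expect_error(network_spec("H1", "S1", "L1", "F1", "A",
                            data.frame(parent = c("H1", "H1"),
                                       child = c("F1", "F1"))),
               "duplicate")
  expect_error(network_spec("H1", "H1", "L1", "F1", "A",
                            data.frame(parent = "H1", child = "F1")),
               "unique")
})

test_that("network spec round-trips through YAML and exports edges as CSV", {
  spec <- default_network_spec()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_network_spec(spec, path)
  back <- read_network_spec(path)
  expect_equal(back$edges, spec$edges)
  expect_equal(back$latent_nodes, spec$latent_nodes)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_edges_csv(spec, csv)
  edges <- read.csv(csv)
  expect_equal(names(edges), c("parent", "child"))
  expect_equal(nrow(edges), 14)
})

test_that("activation probability is the logistic of bias plus active weights", {
  expect_equal(activation_probability(0), 0.5)
  expect_equal(activation_probability(-2), plogis(-2))
  expect_equal(activation_probability(-2, 4), plogis(2))
  expect_error(activation_probability(Inf), "finite")
  expect_error(activation_probability(0, NaN), "finite")
  # strictly increasing in bias and each active weight, bounded in (0,1)
  set.seed(1)
  for (r in 1:20) {
    b <- rnorm(1, 0, 3)
    w <- rnorm(3, 0, 3)
    p <- activation_probability(b, w)
    expect_gt(p, 0); expect_lt(p, 1)
    expect_gt(activation_probability(b + 0.5, w), p)
    expect_gt(activation_probability(b, w + c(0.5, 0, 0)), p)
  }
})

test_that("marginal likelihood matches closed forms", {
  spec <- default_network_spec()
  w0 <- weight_config(spec)  # all zero
  # k observed nodes at zero weights/biases -> k * log(0.5)
  tr <- trial_record(spec, S1 = 1, F1 = 0, L2 = 1)
  expect_equal(trial_log_likelihood(w0, spec, tr), 3 * log(0.5))
  tr_all <- trial_record(spec, S1 = 0, S2 = 0, S3 = 1, L1 = 1, L2 = 0,
                         F1 = 1, F2 = 0, F3 = 0, A = 1)
  expect_equal(trial_log_likelihood(w0, spec, tr_all), 9 * log(0.5))
  # one-latent toy: P(F=1) = 0.5 sigma(bF + w) + 0.5 sigma(bF)
  toy <- toy_spec()
  wt <- weight_config(toy, edge_weights = c("H1->F1" = 2.5),
                      biases = c(F1 = -1))
  tr1 <- trial_record(toy, F1 = 1)
  expect_equal(trial_log_likelihood(wt, toy, tr1),
               log(0.5 * plogis(-1 + 2.5) + 0.5 * plogis(-1)),
               tolerance = 1e-12)
})

test_that("marginal likelihood equals brute-force enumeration on random cases", {
  spec <- default_network_spec()
  set.seed(42)
  for (r in 1:30) {
    w <- random_weights(spec)
    tr <- random_trial(spec)
    expect_equal(trial_log_likelihood(w, spec, tr),
                 brute_trials_loglik(w, spec, tr), tolerance = 1e-10)
  }
})

test_that("likelihood is invariant to multiplicity splitting and state order", {
  spec <- default_network_spec()
  set.seed(7)
  w <- random_weights(spec)
  tr_m <- trial_record(spec, S1 = 1, F1 = 1, multiplicity = 5)
  tr_split <- bind_trials(trial_record(spec, S1 = 1, F1 = 1),
                          trial_record(spec, S1 = 1, F1 = 1),
                          trial_record(spec, S1 = 1, F1 = 1),
                          trial_record(spec, S1 = 1, F1 = 1),
                          trial_record(spec, S1 = 1, F1 = 1))
  expect_equal(trial_log_likelihood(w, spec, tr_m),
               trial_log_likelihood(w, spec, tr_split))
  # naming states in a different order must not matter
  tr_a <- trial_record(spec, S1 = 1, F2 = 0, A = 1)
  tr_b <- trial_record(spec, A = 1, S1 = 1, F2 = 0)
  expect_identical(trial_log_likelihood(w, spec, tr_a),
                   trial_log_likelihood(w, spec, tr_b))
  # compression preserves the likelihood exactly
  trials <- generate_paradigm(paradigm_config(n_pavlovian_per_cs = 5,
                                              n_instrumental_per_lever = 10,
                                              n_blank = 4, seed = 3), spec)
  expect_equal(trial_log_likelihood(w, spec, trials),
               trial_log_likelihood(w, spec, compress_trials(trials)))
})

test_that("with zero weights the likelihood factorizes over nodes", {
  spec <- default_network_spec()
  w <- weight_config(spec, edge_weights = 0,
                     biases = stats::setNames(
                       rnorm(14), pitsbn:::all_nodes(spec)))
  trials <- generate_paradigm(paradigm_config(n_pavlovian_per_cs = 10,
                                              n_instrumental_per_lever = 20,
                                              n_blank = 5, seed = 11), spec)
  obs <- observable_nodes(spec)
  df <- as.data.frame(trials)
  closed <- sum(vapply(obs, function(nd) {
    v <- df[[nd]]
    b <- w$biases[[nd]]
    sum(df$multiplicity * ifelse(is.na(v), 0,
        ifelse(v == 1, plogis(b, log.p = TRUE), plogis(-b, log.p = TRUE))))
  }, numeric(1)))
  expect_equal(trial_log_likelihood(w, spec, trials), closed,
               tolerance = 1e-10)
})

test_that("log prior is an independent Gaussian sum over all parameters", {
  spec <- default_network_spec()
  w0 <- weight_config(spec)
  pr <- prior_spec(weight_scale = 1, bias_scale = 1,
                   latent_bias_mean = 0, latent_bias_scale = 1)
  d <- 14 + 14  # edges + node biases
  expect_equal(log_prior(w0, spec, pr), d * dnorm(0, log = TRUE))
  # doubling one weight's deviation lowers the log prior
  w1 <- weight_config(spec, edge_weights = c("H1->S1" = 1))
  w2 <- weight_config(spec, edge_weights = c("H1->S1" = 2))
  expect_gt(log_prior(w1, spec, pr), log_prior(w2, spec, pr))
  # matches per-parameter density sum on a random configuration
  set.seed(5)
  w <- random_weights(spec)
  pr2 <- prior_spec(weight_scale = 3, bias_scale = 1.5,
                    latent_bias_mean = -2, latent_bias_scale = 2)
  lat <- spec$latent_nodes
  manual <- sum(dnorm(w$edge_weights, 0, 3, log = TRUE)) +
    sum(dnorm(w$biases[lat], -2, 2, log = TRUE)) +
    sum(dnorm(w$biases[setdiff(names(w$biases), lat)], 0, 1.5, log = TRUE))
  expect_equal(log_prior(w, spec, pr2), manual, tolerance = 1e-12)
  expect_error(prior_spec(weight_scale = -1), "positive")
})

test_that("weight configurations validate their inputs", {
  spec <- default_network_spec()
  expect_error(weight_config(spec, edge_weights = c("H9->F1" = 1)), "unknown")
  expect_error(weight_config(spec, edge_weights = Inf), "finite")
  w <- weight_config(spec, edge_weights = c("A->F1" = 2), biases = c(A = -1))
  expect_equal(unname(w$edge_weights[["A->F1"]]), 2)
  expect_equal(sum(w$edge_weights != 0), 1)
  expect_equal(unname(w$biases[["A"]]), -1)
})
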