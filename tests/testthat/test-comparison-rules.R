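test_that("the seven variants map bijectively to flags with the right parameter counts", {
  expected_flags <- list(
    c(FALSE, FALSE, FALSE), c(TRUE, FALSE, FALSE), c(FALSE, TRUE, FALSE),
    c(TRUE, TRUE, FALSE), c(TRUE, FALSE, TRUE), c(FALSE, TRUE, TRUE),
    c(TRUE, TRUE, TRUE))
  for (m in 1:7) {
    spec <- model_spec(m)
    expect_equal(c(spec$use_internal_reference, spec$separate_weights,
                   spec$start_point_regression), expected_flags[[m]])
    expect_equal(model_spec(use_internal_reference = expected_flags[[m]][1],
                            separate_weights = expected_flags[[m]][2],
                            start_point_regression = expected_flags[[m]][3])$model, m)
  }
  expect_equal(vapply(1:7, function(m) n_free_parameters(model_spec(m)), 0L),
               c(5L, 6L, 6L, 7L, 7L, 7L, 8L))
  # the eighth flag combination is not part of the family
  expect_error(model_spec(start_point_regression = TRUE),
               class = "durddm_config_error")
  expect_error(model_spec(2, use_internal_reference = FALSE),
               class = "durddm_config_error")
})

test_that("the internal reference update is the stated weighted average", {
  expect_equal(update_internal_reference(-50, 80, 0), 80)
  expect_equal(update_internal_reference(-50, 80, 1), -50)
  expect_equal(update_internal_reference(0, -100, 0.5), -50)
  expect_error(update_internal_reference(0, 0, 1.2), class = "durddm_domain_error")
})

test_that("reference trajectory matches an independent recurrence", {
  expect_equal(reference_trajectory(c(0, 0, 0), 0.7), c(0, 0, 0))
  expect_equal(reference_trajectory(c(0, -100), 0.5), c(0, -50))
  set.seed(11)
  x <- rnorm(1000, 0, 60)
  g <- 0.9
  oracle <- numeric(1000)
  oracle[1] <- x[1]
  for (n in 2:1000) oracle[n] <- g * oracle[n - 1] + (1 - g) * x[n]
  expect_equal(reference_trajectory(x, g), oracle, tolerance = 1e-12)
  expect_error(reference_trajectory(numeric(0), 0.5), class = "durddm_domain_error")
  # convex-combination bound: the reference never exceeds past inputs
  expect_true(all(abs(reference_trajectory(x, 0.9)) <= cummax(abs(x)) + 1e-12))
})

model1_params_v <- function(v0, v1)
  individual_parameters(a = 1.5, tau = 0.15, z0 = 0.45, v0 = v0, v1 = v1)

test_that("trial dynamics follow the drift and starting-point regressions", {
  d1 <- trial_dynamics(model_spec(1), model1_params_v(v0 = 0, v1 = 0.01),
                       list(dur1_ms = 600, dur2_ms = 500))
  expect_equal(d1$v_n, 1.0)
  expect_equal(d1$z_n, 0.45)

  d6 <- trial_dynamics(model_spec(6), model6_params(),
                       list(dur1_ms = 600, dur2_ms = 500))
  expect_equal(d6$v_n, 0.0437 + 0.0096 * 100)
  expect_equal(d6$z_n, 0.4411 + 0.0007 * 100)

  # starting point outside (0, 1) is an invalid-dynamics error, not a value
  bad <- individual_parameters(a = 1.5, tau = 0.15, z0 = 0.9, z1 = 0.005,
                               v0 = 0, v1 = 0.01, v2 = -0.01)
  expect_error(trial_dynamics(model_spec(6), bad, list(dur1_ms = 600, dur2_ms = 500)),
               class = "durddm_invalid_dynamics")
})

test_that("dataset dynamics thread the reference and match a per-trial loop", {
  des <- small_design(reps = 6, seed = 3)
  trials <- generate_design_trials(des)$trials
  p7 <- individual_parameters(a = 1.5, tau = 0.15, z0 = 0.45, z1 = 0.0005,
                              v0 = 0.02, v1 = 0.011, v2 = -0.018, g = 0.7)
  spec <- model_spec(7)
  dyn <- dataset_dynamics(spec, p7, trials)
  # brute-force loop oracle over trial_dynamics with explicit state threading
  I_prev <- NULL
  for (n in seq_len(nrow(trials))) {
    one <- trial_dynamics(spec, p7, trials[n, ], I_prev = I_prev)
    expect_equal(dyn$v_n[n], one$v_n)
    expect_equal(dyn$z_n[n], one$z_n)
    expect_equal(dyn$I_n[n], one$I_n)
    I_prev <- one$I_n
  }
  # with g = 1 the reference stays at the first trial's stimulus
  p_g1 <- individual_parameters(a = 1.5, tau = 0.15, z0 = 0.45,
                                v0 = 0, v1 = 0.01, g = 1)
  dyn_g1 <- dataset_dynamics(model_spec(2), p_g1, trials)
  expect_true(all(dyn_g1$I_n == dyn_g1$I_n[1]))

  unordered <- trials[c(2, 1, 3:nrow(trials)), ]
  expect_error(dataset_dynamics(spec, p7, unordered), class = "durddm_domain_error")
})

test_that("nested variants reduce to their parents", {
  des <- small_design(reps = 4, seed = 13)
  trials <- generate_design_trials(des)$trials
  base <- list(a = 1.5, tau = 0.15, z0 = 0.45, v0 = 0.03, v1 = 0.012)

  p1 <- do.call(individual_parameters, base)
  p2 <- do.call(individual_parameters, c(base, list(g = 0)))
  d1 <- dataset_dynamics(model_spec(1), p1, trials)
  d2 <- dataset_dynamics(model_spec(2), p2, trials)
  expect_identical(d1$v_n, d2$v_n)
  expect_identical(d1$z_n, d2$z_n)

  p3 <- do.call(individual_parameters, c(base, list(v2 = -base$v1)))
  d3 <- dataset_dynamics(model_spec(3), p3, trials)
  expect_identical(d1$v_n, d3$v_n)
})

test_that("missing required parameters for a variant are rejected", {
  p1 <- model1_params()
  expect_error(validate_parameters(p1, model_spec(2)), "g is required",
               class = "durddm_domain_error")
  expect_error(validate_parameters(p1, model_spec(3)), "v2 is required",
               class = "durddm_domain_error")
  expect_error(validate_parameters(p1, model_spec(6)), class = "durddm_domain_error")
})
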