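dens <- function(t, ch, a = 1.5, v = 1.0, z = 0.45, tau = 0.15)
  exp(wfpt_log_density(t, ch, a, v, z, tau))

test_that("reflection symmetry and boundary cases hold exactly", {
  expect_equal(wfpt_log_density(0.8, "upper", 1.5, 1.2, 0.4, 0.1),
               wfpt_log_density(0.8, "lower", 1.5, -1.2, 0.6, 0.1))
  expect_identical(wfpt_log_density(0.1, "upper", 1.5, 1.2, 0.4, 0.1), -Inf)
  expect_identical(wfpt_log_density(0.1, "lower", 1.5, 1.2, 0.4, 0.1), -Inf)
  expect_error(wfpt_log_density(0.8, "upper", -1, 0, 0.5, 0),
               class = "durddm_domain_error")
  expect_error(wfpt_log_density(0.8, "upper", 1, 0, 1.2, 0),
               class = "durddm_domain_error")
})

test_that("the defective densities integrate to one", {
  iu <- integrate(function(t) sapply(t, dens, ch = "upper"), 0.15, 50,
                  rel.tol = 1e-9)$value
  il <- integrate(function(t) sapply(t, dens, ch = "lower"), 0.15, 50,
                  rel.tol = 1e-9)$value
  expect_equal(iu + il, 1, tolerance = 1e-4)
  # and the upper mass equals the closed-form absorption probability
  expect_equal(iu, choice_probability_upper(1.5, 1.0, 0.45), tolerance = 1e-4)
})

test_that("choice probability has the stated driftless limits and simulation agreement", {
  expect_equal(choice_probability_upper(1.5, 0, 0.5), 0.5)
  expect_equal(choice_probability_upper(1.5, 0, 0.3), 0.3)
  # near-zero drift is continuous
  expect_equal(choice_probability_upper(1.5, 1e-12, 0.3), 0.3, tolerance = 1e-6)
  # strong negative drift stays in [0, 1] without overflow
  expect_true(choice_probability_upper(2.5, -200, 0.5) >= 0)

  set.seed(21)
  n <- 20000
  s <- simulate_choice_rt(n, a = 1.5, v = 5, z_rel = 0.5, tau = 0)
  p <- choice_probability_upper(1.5, 5, 0.5)
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(s$choice == "upper") - p), 3 * se)
})

test_that("participant log-likelihood is the sum of per-trial densities", {
  des <- small_design(reps = 3, seed = 4)
  ds <- simulate_experiment(des, model_spec(1), model1_params(), seed = 8,
                            dt = 5e-4)
  ll <- loglik_participant(model_spec(1), model1_params(),
                           participant_trials(ds, "p01"))
  expect_equal(ll$total, sum(ll$pointwise))
  expect_length(ll$pointwise, n_trials(ds))
  expect_equal(ll$n_nonfinite, 0)

  # a driftless, unbiased trial is symmetric in the response label
  sym <- individual_parameters(a = 1.5, tau = 0.1, z0 = 0.5, v0 = 0, v1 = 0)
  tr <- data.frame(participant_id = "p01", trial_index = 1L, dur1_ms = 500,
                   dur2_ms = 500, order = "sc", response = "first_longer",
                   rt_s = 0.8)
  tr2 <- tr
  tr2$response <- "second_longer"
  expect_equal(loglik_participant(model_spec(1), sym, tr)$total,
               loglik_participant(model_spec(1), sym, tr2)$total)
})

test_that("the generating parameters beat strongly perturbed ones on average", {
  spec <- model_spec(1)
  params <- model1_params()
  wrong <- individual_parameters(a = params$a * 1.5, tau = params$tau,
                                 z0 = params$z0, v0 = params$v0, v1 = params$v1)
  des <- small_design(reps = 3, seed = 5)
  diffs <- vapply(1:5, function(s) {
    ds <- simulate_experiment(des, spec, params, seed = 100 + s, dt = 5e-4)
    tr <- participant_trials(ds, "p01")
    loglik_participant(spec, params, tr)$total -
      loglik_participant(spec, wrong, tr)$total
  }, 0)
  expect_gt(mean(diffs), 0)
})

test_that("the simulator is reproducible, offset by tau, and censors long paths", {
  set.seed(33)
  s1 <- simulate_choice_rt(50, a = 1.5, v = 0.5, z_rel = 0.5, tau = 0.2)
  set.seed(33)
  s2 <- simulate_choice_rt(50, a = 1.5, v = 0.5, z_rel = 0.5, tau = 0.2)
  expect_identical(s1, s2)
  expect_true(all(s1$rt_s > 0.2))

  set.seed(34)
  s3 <- simulate_choice_rt(20, a = 8, v = 0, z_rel = 0.5, tau = 0.1,
                           t_max = 0.05)
  expect_true(all(is.na(s3$choice)))
})

test_that("simulated experiments are seed-reproducible and order-coded correctly", {
  des <- small_design(reps = 2, seed = 6)
  ds1 <- simulate_experiment(des, model_spec(1), model1_params(), seed = 77,
                             dt = 5e-4)
  ds2 <- simulate_experiment(des, model_spec(1), model1_params(), seed = 77,
                             dt = 5e-4)
  expect_identical(ds1$trials, ds2$trials)
  expect_true(all(!is.na(ds1$trials$response)))

  # a strong positive drift weight on the difference makes "longer first
  # interval" trials yield mostly first_longer responses
  strong <- individual_parameters(a = 1.5, tau = 0.1, z0 = 0.5, v0 = 0, v1 = 0.05)
  dsS <- simulate_experiment(des, model_spec(1), strong, seed = 78, dt = 5e-4)
  first_longer_trials <- dsS$trials$dur1_ms > dsS$trials$dur2_ms
  expect_gt(mean(dsS$trials$response[first_longer_trials] == "first_longer"), 0.9)
})
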