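test_that("the joint log-posterior decomposes as likelihood plus priors", {
  spec <- model_spec(1)
  priors <- prior_spec()
  des <- small_design(reps = 2, seed = 14)
  ds <- simulate_experiment(des, spec, model1_params(), participants = 2,
                            seed = 15, dt = 5e-4)
  pn <- param_names(spec)
  K <- length(pn)
  P <- 2
  mu <- c(log(1.5), log(0.15), qlogis(0.45), 0.05, 0.012)
  log_sigma <- rep(log(0.1), K)
  theta <- rbind(mu, mu + 0.05)
  par <- c(mu, log_sigma, as.vector(t(theta)))
  lp <- log_posterior(spec, priors, ds, par)
  expect_true(is.finite(lp))

  # independent re-derivation: prior terms + Gaussian terms + likelihoods
  half_norm <- function(s, sc) log(2) - 0.5 * log(2 * pi) - log(sc) - s^2 / (2 * sc^2)
  expected <- 0
  for (k in seq_len(K)) {
    pr <- priors[[pn[k]]]
    expected <- expected + dnorm(mu[k], pr$mean_loc, pr$mean_scale, log = TRUE) +
      half_norm(exp(log_sigma[k]), pr$sd_scale) + log_sigma[k]
  }
  for (i in 1:P) {
    expected <- expected + sum(dnorm(theta[i, ], mu, exp(log_sigma), log = TRUE))
    cp <- theta[i, ]
    cp[1:2] <- exp(cp[1:2]); cp[3] <- plogis(cp[3])
    params <- individual_parameters(a = cp[1], tau = cp[2], z0 = cp[3],
                                    v0 = cp[4], v1 = cp[5])
    expected <- expected +
      loglik_participant(spec, params, participant_trials(ds, participants(ds)[i]))$total
  }
  expect_equal(lp, expected, tolerance = 1e-10)

  expect_error(log_posterior(spec, priors, ds, par[-1]),
               class = "durddm_domain_error")
})

test_that("a dataset without responses gives the prior-only posterior", {
  spec <- model_spec(1)
  priors <- prior_spec()
  skel <- generate_design_trials(small_design(reps = 2, seed = 16), 2)
  K <- n_free_parameters(spec)
  par <- c(rep(0, K), rep(log(0.2), K), rep(0, 2 * K))
  lp <- log_posterior(spec, priors, skel, par)
  expect_true(is.finite(lp))
  # editing one response time changes exactly that trial's contribution
  ds <- simulate_experiment(small_design(reps = 2, seed = 16), spec,
                            model1_params(), participants = 2, seed = 17,
                            dt = 5e-4)
  mu <- c(log(1.5), log(0.15), qlogis(0.45), 0.05, 0.012)
  par2 <- c(mu, rep(log(0.1), K), rep(mu, 2))
  lp_before <- log_posterior(spec, priors, ds, par2)
  ds_mod <- ds
  ds_mod$trials$rt_s[5] <- ds$trials$rt_s[5] + 0.25
  lp_after <- log_posterior(spec, priors, ds_mod, par2)
  pid <- ds$trials$participant_id[5]
  pw_before <- loglik_participant(spec, model1_params(),
                                  participant_trials(ds, pid))$pointwise
  pw_after <- loglik_participant(spec, model1_params(),
                                 participant_trials(ds_mod, pid))$pointwise
  expect_equal(lp_after - lp_before, sum(pw_after) - sum(pw_before),
               tolerance = 1e-8)
})

test_that("split R-hat distinguishes mixed from displaced chains", {
  expect_equal(rhat(matrix(5, 100, 4)), 1)
  set.seed(41)
  good <- matrix(rnorm(4000), 1000, 4)
  expect_lt(abs(rhat(good) - 1), 0.01)
  bad <- good + rep(c(-5, 5, -5, 5), each = 1000)[rep(1:4, each = 1000)]
  bad <- matrix(rnorm(4000), 1000, 4) + matrix(rep(c(-5, 5, 0, 2.5), each = 1000), 1000, 4)
  expect_gt(rhat(bad), 1.2)
  expect_error(rhat(matrix(rnorm(100), 100, 1)), class = "durddm_domain_error")
})

test_that("the HDI is the shortest mass interval", {
  set.seed(42)
  x <- rnorm(20000)
  h <- hdi(x, 0.95)
  expect_equal(h[1], qnorm(0.025), tolerance = 0.05)
  expect_equal(h[2], qnorm(0.975), tolerance = 0.05)
  expect_equal(hdi(rep(3.2, 60)), c(3.2, 3.2))
  y <- rexp(20000)
  hy <- hdi(y, 0.9)
  expect_lt(hy[1], quantile(y, 0.01))
  expect_error(hdi(x, 1.2), class = "durddm_domain_error")
  expect_error(hdi(x[1:10]), class = "durddm_domain_error")
})

test_that("the posterior mode is located by the density argmax", {
  set.seed(43)
  expect_equal(posterior_mode(rnorm(20000, 1.47, 0.05)), 1.47, tolerance = 0.02)
  expect_equal(posterior_mode(rep(2.5, 200)), 2.5)
  bimodal <- c(rnorm(2000, -1, 0.12), rnorm(6000, 1, 0.12))
  expect_equal(posterior_mode(bimodal), 1, tolerance = 0.1)
  expect_error(posterior_mode(rnorm(50)), class = "durddm_domain_error")
})

test_that("fits are deterministic under a fixed seed and report convergence", {
  f1 <- cached_small_fit()
  spec <- model_spec(1)
  f2 <- fit_hddm(spec, f1$dataset, n_chains = 2, n_iter = 400, seed = 3)
  expect_identical(f1$draws, f2$draws)
  expect_true(all(is.finite(f1$rhat)))
  expect_true(is.finite(f1$accept_rate))
  # group summary reports every parameter on the constrained scale
  gs <- group_summary(f1)
  expect_setequal(gs$parameter, param_names(spec))
  expect_true(all(gs$lower <= gs$mode & gs$mode <= gs$upper))
})

test_that("a single participant disables the hierarchy with a warning", {
  spec <- model_spec(1)
  ds <- simulate_experiment(small_design(reps = 2, seed = 18), spec,
                            model1_params(), seed = 19, dt = 5e-4)
  expect_warning(fit <- fit_hddm(spec, ds, n_chains = 2, n_iter = 200, seed = 4),
                 "hierarchy disabled")
  expect_false(fit$hierarchical)
  expect_false(any(grepl("^mu_", dimnames(fit$draws)[[3]])))
})

test_that("draws serialize to chain-tagged text and back", {
  fit <- cached_small_fit()
  path <- withr::local_tempfile(fileext = ".csv")
  write_draws(fit, path)
  expect_true(file.exists(paste0(path, ".meta.json")))
  back <- read_draws(path)
  expect_equal(back$draws, fit$draws, tolerance = 1e-12)
  expect_equal(back$spec$model, fit$spec$model)
  expect_equal(back$participant_ids, fit$participant_ids)
})
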