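# generate two-order binary responses from a known logistic model
logistic_trials <- function(beta0_sc, beta_sc, beta0_cs, beta_cs,
                            n_per_order = 400, seed = 1, standard = 500) {
  set.seed(seed)
  levels <- seq(400, 600, length.out = 9)
  rows <- lapply(c("sc", "cs"), function(o) {
    b0 <- if (o == "sc") beta0_sc else beta0_cs
    b <- if (o == "sc") beta_sc else beta_cs
    comp <- sample(levels, n_per_order, TRUE)
    p <- plogis(b0 + b * (comp - standard))
    longer_c <- rbinom(n_per_order, 1, p)
    data.frame(order = o, comparison_ms = comp, longer_c = longer_c,
               stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, rows)
  # response coding: comparison longer means second_longer on sc trials
  data.frame(participant_id = "p01", trial_index = seq_len(nrow(d)),
             dur1_ms = ifelse(d$order == "sc", standard, d$comparison_ms),
             dur2_ms = ifelse(d$order == "sc", d$comparison_ms, standard),
             order = d$order,
             response = ifelse(d$longer_c == 1,
                               ifelse(d$order == "sc", "second_longer", "first_longer"),
                               ifelse(d$order == "sc", "first_longer", "second_longer")),
             rt_s = 0.5, stringsAsFactors = FALSE)
}

test_that("known logistic slopes are recovered by both fitting methods", {
  errs <- vapply(1:11, function(s) {
    tr <- logistic_trials(0, 0.03, 0, 0.03, seed = s)
    fit <- fit_psychometric(tr, 500)
    abs(fit$per_order$beta[1] - 0.03) / 0.03
  }, 0)
  expect_lt(median(errs), 0.15)

  tr <- logistic_trials(0, 0.03, 0, 0.03, n_per_order = 2000, seed = 99)
  ml <- fit_psychometric(tr, 500, method = "ml")
  bay <- fit_psychometric(tr, 500, method = "bayes")
  expect_equal(bay$per_order$beta, ml$per_order$beta, tolerance = 0.05)
})

test_that("symmetric or uninformative data give null interactions and slopes", {
  tr <- logistic_trials(0.2, 0.025, 0.2, 0.025, n_per_order = 3000, seed = 3)
  fit <- fit_psychometric(tr, 500)
  expect_lt(abs(fit$coefficients[["x:ordcs"]]), 0.005)

  flat <- logistic_trials(0, 0, 0, 0, n_per_order = 2000, seed = 4)
  fit0 <- fit_psychometric(flat, 500)
  expect_lt(abs(fit0$per_order$beta[1]), 0.004)
})

test_that("PSE is the 50 percent point of the fitted curve", {
  fit <- structure(list(per_order = data.frame(order = c("sc", "cs"),
                                               beta0 = c(0, -1),
                                               beta = c(0.03, 0.02)),
                        standard_ms = 500), class = "psychometric_fit")
  expect_equal(pse(fit, "sc"), 500)
  expect_equal(pse(fit, "cs"), 550)
  # numeric root oracle
  root <- uniroot(function(d) plogis(-1 + 0.02 * (d - 500)) - 0.5,
                  c(400, 700), tol = 1e-12)$root
  expect_equal(pse(fit, "cs"), root, tolerance = 1e-9)
  fit$per_order$beta[1] <- 0
  expect_error(pse(fit, "sc"), class = "durddm_domain_error")
})

test_that("DL equals log(3)/slope and inherits its invariances", {
  fit <- structure(list(per_order = data.frame(order = c("sc", "cs"),
                                               beta0 = c(0.7, -0.3),
                                               beta = c(0.02, 0.04)),
                        standard_ms = 500), class = "psychometric_fit")
  expect_equal(dl(fit, "sc"), log(3) / 0.02)
  # numeric quantile-inversion oracle
  q <- function(p, b0, b) 500 + (qlogis(p) - b0) / b
  expect_equal(dl(fit, "sc"), (q(0.75, 0.7, 0.02) - q(0.25, 0.7, 0.02)) / 2,
               tolerance = 1e-9)
  # doubling the slope halves the DL; the intercept does not matter
  expect_equal(dl(fit, "cs"), dl(fit, "sc") / 2)
  fit$per_order$beta[2] <- -0.01
  expect_error(dl(fit, "cs"), class = "durddm_domain_error")
})

test_that("context effects carry the documented sign conventions", {
  same <- structure(list(per_order = data.frame(order = c("sc", "cs"),
                                                beta0 = c(0.1, 0.1),
                                                beta = c(0.03, 0.03)),
                         standard_ms = 500), class = "psychometric_fit")
  eff <- context_effects(same)
  expect_equal(eff$type_a, 0)
  expect_equal(eff$type_b, 0)

  # steeper sc curve = better discrimination with standard first = negative
  # Type B effect
  neg <- structure(list(per_order = data.frame(order = c("sc", "cs"),
                                               beta0 = c(0, 0),
                                               beta = c(0.04, 0.02)),
                        standard_ms = 500), class = "psychometric_fit")
  expect_lt(context_effects(neg)$type_b, 0)
})

test_that("the proportional weight difference uses weight magnitudes", {
  expect_equal(proportional_weight_difference(0.01, -0.01), 0)
  expect_equal(proportional_weight_difference(0.0096, -0.0198),
               (0.0096 - 0.0198) / (0.0096 + 0.0198))
  # antisymmetry under swapping the two magnitudes
  expect_equal(proportional_weight_difference(0.004, -0.02),
               -proportional_weight_difference(0.02, -0.004))
  expect_error(proportional_weight_difference(0.01, 0.02),
               class = "durddm_domain_error")
})

test_that("weight-effect correlations behave like Pearson's r", {
  x <- seq(-1, 1, length.out = 20)
  expect_equal(as.numeric(correlate_weights_effects(x, 2 * x + 1)), 1)
  set.seed(6)
  r <- correlate_weights_effects(rnorm(1000), rnorm(1000))
  expect_lt(abs(as.numeric(r)), 0.1)
  expect_error(correlate_weights_effects(rep(1, 5), rnorm(5)),
               class = "durddm_domain_error")
  withna <- correlate_weights_effects(c(x, NA), c(2 * x + 1, 0.5))
  expect_equal(attr(withna, "n_used"), 20)
})
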