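#' Log first-passage-time density of the Wiener diffusion
#'
#' Defective density of absorption at the given boundary at total response
#' time `t` (decision time plus non-decision time `tau`), for a diffusion
#' with boundary separation `a`, drift `v`, relative starting point `z_rel`
#' and diffusion coefficient fixed at 1. Note that the other common
#' convention fixes the diffusion coefficient at 0.1, which silently rescales
#' `a`, `v` and the starting-point slope; all quantities in this package are
#' on the unit-diffusion scale.
#'
#' The density is evaluated by the small-time/large-time series with
#' automatic switching; the truncation error is kept below `eps` in density
#' units. The upper boundary is obtained from the lower one by reflection,
#' `f(t, upper | v, z) = f(t, lower | -v, 1 - z)`.
#'
#' @param t response times in seconds.
#' @param choice `"upper"`/`"lower"` (or 1/0); recycled.
#' @param a boundary separation (> 0).
#' @param v drift rate (evidence/s).
#' @param z_rel relative starting point in (0, 1).
#' @param tau non-decision time in seconds (>= 0).
#' @param eps truncation tolerance in density units.
#' @return vector of log densities; `-Inf` for `t <= tau` (a legal
#'   likelihood value, distinct from a domain error).
#' @export
wfpt_log_density <- function(t, choice, a, v, z_rel, tau, eps = 1e-7) {
  check_wiener_domain(a, v, z_rel, tau)
  up <- as_choice_upper(choice)
  wfpt_log_density_cpp(as.numeric(t), as.integer(up),
                       as.numeric(a), as.numeric(v),
                       as.numeric(z_rel), as.numeric(tau), eps)
}

as_choice_upper <- function(choice) {
  if (is.character(choice) || is.factor(choice)) {
    choice <- as.character(choice)
    if (!all(choice %in% c("upper", "lower")))
      stop_domain("choice must be 'upper' or 'lower'")
    as.integer(choice == "upper")
  } else {
    if (!all(choice %in% c(0, 1))) stop_domain("choice must be 0/1 or 'lower'/'upper'")
    as.integer(choice)
  }
}

check_wiener_domain <- function(a, v, z_rel, tau) {
  if (any(!is.finite(a)) || any(a <= 0)) stop_domain("boundary separation a must be > 0")
  if (any(!is.finite(v))) stop_domain("drift v must be finite")
  if (any(!is.finite(z_rel)) || any(z_rel <= 0 | z_rel >= 1))
    stop_domain("relative starting point z_rel must lie in (0, 1)")
  if (any(!is.finite(tau)) || any(tau < 0)) stop_domain("non-decision time tau must be >= 0")
  invisible(TRUE)
}

#' Probability of absorption at the upper boundary
#'
#' Closed form for drifted Brownian motion between absorbing boundaries:
#' `(1 - exp(-2 v a z)) / (1 - exp(-2 v a))` for `v != 0` and `z` for
#' `v = 0`, evaluated in a numerically stable way.
#'
#' @inheritParams wfpt_log_density
#' @return probability in \[0, 1\]; vectorized.
#' @export
choice_probability_upper <- function(a, v, z_rel) {
  check_wiener_domain(a, v, z_rel, 0)
  n <- max(length(a), length(v), length(z_rel))
  a <- rep_len(a, n); v <- rep_len(v, n); z <- rep_len(z_rel, n)
  p <- numeric(n)
  for (i in seq_len(n)) {
    q <- -2 * v[i] * a[i]
    p[i] <- if (v[i] == 0) {
      z[i]
    } else if (q > 500) {
      # strong negative drift: both expm1 terms overflow; use the tail ratio
      exp(q * z[i] - q)
    } else {
      expm1(q * z[i]) / expm1(q)
    }
  }
  pmin(pmax(p, 0), 1)
}

#' Participant log-likelihood under a model variant
#'
#' Per-trial Wiener log densities at the trial-level dynamics
#' ([dataset_dynamics()]), with the upper boundary mapped to the
#' `first_longer` response. Trials whose starting point leaves (0, 1) or
#' whose response time does not exceed `tau` contribute `-Inf`; these are
#' counted in the returned diagnostics rather than raised.
#'
#' @param spec a [model_spec()].
#' @param params an [individual_parameters()] object valid for `spec`.
#' @param trials one participant's trials, ordered by `trial_index`, with
#'   responses and response times present.
#' @param standard_ms standard duration used for centering.
#' @param eps density truncation tolerance.
#' @return list with `total`, `pointwise` (one value per trial) and
#'   `n_nonfinite`.
#' @export
loglik_participant <- function(spec, params, trials, standard_ms = 500, eps = 1e-7) {
  validate_parameters(params, spec)
  if (is.unsorted(trials$trial_index, strictly = TRUE))
    stop_domain("trials must be strictly ordered by trial_index")
  if (any(is.na(trials$response)) || any(is.na(trials$rt_s)))
    stop_domain("loglik_participant requires responses and RTs on every trial")
  pw <- loglik_trials_cpp(
    rt = trials$rt_s,
    upper = as.integer(trials$response == "first_longer"),
    X1c = center_duration(trials$dur1_ms, standard_ms),
    X2c = center_duration(trials$dur2_ms, standard_ms),
    a = params$a, tau = params$tau, z0 = params$z0,
    z1 = params$z1 %||% 0, v0 = params$v0, v1 = params$v1,
    v2 = if (spec$separate_weights) params$v2 else -params$v1,
    g = params$g %||% 0,
    use_ref = spec$use_internal_reference,
    use_zreg = spec$start_point_regression,
    eps = eps)
  list(total = sum(pw), pointwise = pw, n_nonfinite = sum(!is.finite(pw)))
}

#' Simulate choices and response times from the Wiener diffusion
#'
#' Euler-Maruyama paths from `z_rel * a` with increments
#' `v dt + sqrt(dt) N(0, 1)` until absorption, plus a Brownian-bridge
#' correction for crossings inside a step (raw Euler first-passage times are
#' biased late by O(sqrt(dt))). Draws come from R's RNG, so results are
#' reproducible under `set.seed()`.
#'
#' @param n number of trials.
#' @inheritParams wfpt_log_density
#' @param dt Euler step in seconds.
#' @param t_max decision-time cap in seconds; paths not absorbed by then are
#'   returned as censored (`NA` choice and rt).
#' @param bridge apply the within-step bridge crossing correction.
#' @return data frame with `choice` (`"upper"`/`"lower"`/`NA`) and `rt_s`
#'   (first-passage time + `tau`).
#' @export
simulate_choice_rt <- function(n = 1, a, v, z_rel, tau, dt = 1e-4,
                               t_max = 30, bridge = TRUE) {
  check_wiener_domain(a, v, z_rel, tau)
  if (dt <= 0) stop_domain("dt must be > 0")
  sim <- simulate_trials_cpp(rep_len(as.numeric(v), n),
                             rep_len(as.numeric(z_rel), n),
                             a, tau, dt, t_max, bridge)
  data.frame(choice = c("lower", "upper")[sim$choice + 1L],
             rt_s = sim$rt_s, stringsAsFactors = FALSE)
}

#' Simulate a full duration-discrimination experiment
#'
#' Generates the trial skeleton of a design, threads the trial-level
#' dynamics across each participant's realized stimulus sequence, and draws
#' choices/RTs from the Wiener process. The upper boundary is mapped back to
#' the `first_longer` response. Censored (non-absorbed) trials are dropped
#' with a warning and counted in the dataset's provenance.
#'
#' @param design an [experiment_design()].
#' @param spec a [model_spec()].
#' @param params a single [individual_parameters()] object used for all
#'   participants, or a named list of such objects (names = participant ids).
#' @param participants participant ids, or an integer count; defaults to the
#'   names of `params` when it is a list.
#' @param seed integer seed; governs both the trial permutation and the
#'   diffusion noise, so a fixed seed reproduces the dataset exactly.
#' @param dt,t_max,bridge simulator controls, see [simulate_choice_rt()].
#' @return a [dd_dataset()] with responses filled in.
#' @export
simulate_experiment <- function(design, spec, params, participants = NULL,
                                seed = NULL, dt = 1e-4, t_max = 30,
                                bridge = TRUE) {
  stopifnot(inherits(design, "experiment_design"), inherits(spec, "model_spec"))
  if (inherits(params, "individual_parameters")) {
    if (is.null(participants)) participants <- 1L
    skeleton_ids <- if (is.numeric(participants) && length(participants) == 1)
      sprintf("p%02d", seq_len(participants)) else as.character(participants)
    params <- setNames(rep(list(params), length(skeleton_ids)), skeleton_ids)
  } else {
    if (is.null(names(params)))
      stop_domain("params given as a list must be named by participant id")
    skeleton_ids <- names(params)
  }
  for (p in params) validate_parameters(p, spec)

  run <- function() {
    skel <- generate_design_trials(design, skeleton_ids)
    trials <- skel$trials
    n_censored <- 0L
    for (pid in skeleton_ids) {
      idx <- which(trials$participant_id == pid)
      dyn <- dataset_dynamics(spec, params[[pid]], trials[idx, , drop = FALSE],
                              standard_ms = design$standard_ms, strict = TRUE)
      sim <- simulate_trials_cpp(dyn$v_n, dyn$z_n, params[[pid]]$a,
                                 params[[pid]]$tau, dt, t_max, bridge)
      resp <- ifelse(is.na(sim$choice), NA_character_,
                     ifelse(sim$choice == 1L, "first_longer", "second_longer"))
      n_censored <- n_censored + sum(is.na(sim$choice))
      trials$response[idx] <- resp
      trials$rt_s[idx] <- sim$rt_s
    }
    keep <- !is.na(trials$response)
    if (n_censored > 0) {
      warning(sprintf("%d simulated trial(s) not absorbed within %g s were dropped",
                      n_censored, t_max))
      trials <- trials[keep, , drop = FALSE]
    }
    dd_dataset(trials, design = design,
               provenance = c(sprintf("simulated from model %d", spec$model),
                              sprintf("censored trials dropped: %d", n_censored)))
  }
  if (is.null(seed)) run() else with_seed(derive_seed(seed, "simulate"), run())
}
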