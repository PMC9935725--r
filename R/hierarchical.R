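# --- internal helpers -------------------------------------------------------

# per-participant data in the form the likelihood kernel consumes
prepare_participant_data <- function(dataset, standard_ms) {
  ids <- participants(dataset)
  lapply(setNames(ids, ids), function(pid) {
    tr <- participant_trials(dataset, pid)
    tr <- tr[!is.na(tr$response) & !is.na(tr$rt_s), , drop = FALSE]
    list(rt = tr$rt_s,
         upper = as.integer(tr$response == "first_longer"),
         X1c = center_duration(tr$dur1_ms, standard_ms),
         X2c = center_duration(tr$dur2_ms, standard_ms),
         n = nrow(tr))
  })
}

# total log-likelihood of one participant given a constrained parameter row
# (named vector over param_names(spec))
loglik_row <- function(spec, cpar, pd, eps) {
  if (pd$n == 0) return(0)
  loglik_total_cpp(pd$rt, pd$upper, pd$X1c, pd$X2c,
                   a = cpar[["a"]], tau = cpar[["tau"]], z0 = cpar[["z0"]],
                   z1 = if (spec$start_point_regression) cpar[["z1"]] else 0,
                   v0 = cpar[["v0"]], v1 = cpar[["v1"]],
                   v2 = if (spec$separate_weights) cpar[["v2"]] else -cpar[["v1"]],
                   g = if (spec$use_internal_reference) cpar[["g"]] else 0,
                   use_ref = spec$use_internal_reference,
                   use_zreg = spec$start_point_regression,
                   eps = eps)
}

log_halfnormal <- function(sigma, scale) {
  ifelse(sigma <= 0, -Inf,
         log(2) - 0.5 * log(2 * pi) - log(scale) - sigma^2 / (2 * scale^2))
}

# univariate slice sampler with stepping out (Neal 2003); no tuning needed,
# used for the hyper-sds whose half-normal prior is not conjugate
slice_sample1 <- function(x0, logf, w = 1, max_steps = 50) {
  y <- logf(x0) - stats::rexp(1)
  L <- x0 - runif(1) * w
  R <- L + w
  j <- floor(runif(1) * max_steps)
  k <- max_steps - 1 - j
  while (j > 0 && logf(L) > y) { L <- L - w; j <- j - 1 }
  while (k > 0 && logf(R) > y) { R <- R + w; k <- k - 1 }
  repeat {
    x1 <- runif(1, L, R)
    if (logf(x1) >= y) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
  }
}

# --- exported operations ----------------------------------------------------

#' Hierarchical log-posterior density
#'
#' Joint unnormalized log density of the hierarchical model at an
#' unconstrained parameter vector laid out as
#' `c(mu (K), log_sigma (K), theta (participant-major, K per participant))`
#' with `K = n_free_parameters(spec)` in [param_names()] order. It is the
#' sum of per-participant Wiener log-likelihoods (evaluated at the
#' constrained transforms), Gaussian individual-level terms on the
#' unconstrained scale, the hyper-mean normal priors, the hyper-sd
#' half-normal priors, and the log-sigma Jacobian. `-Inf` propagates
#' cleanly. A dataset with no answered trials yields the prior-only
#' posterior.
#'
#' @param spec a [model_spec()].
#' @param priors a [prior_spec()].
#' @param dataset a [dd_dataset()].
#' @param par unconstrained parameter vector in the layout above.
#' @param standard_ms standard for centering; defaults to the dataset's
#'   design.
#' @param eps density truncation tolerance.
#' @return scalar log density.
#' @export
log_posterior <- function(spec, priors, dataset, par, standard_ms = NULL, eps = 1e-7) {
  pn <- param_names(spec)
  K <- length(pn)
  ids <- participants(dataset)
  P <- length(ids)
  if (length(par) != K * (P + 2))
    stop_domain(sprintf("parameter vector must have length %d (= %d params x (%d participants + 2 hyper levels))",
                        K * (P + 2), K, P))
  standard_ms <- standard_ms %||% (dataset$design$standard_ms %||% 500)
  mu <- par[seq_len(K)]
  log_sigma <- par[K + seq_len(K)]
  sigma <- exp(log_sigma)
  theta <- matrix(par[2 * K + seq_len(K * P)], nrow = P, ncol = K, byrow = TRUE)
  pd <- prepare_participant_data(dataset, standard_ms)
  lp <- 0
  for (k in seq_len(K)) {
    pr <- priors[[pn[k]]]
    lp <- lp + dnorm(mu[k], pr$mean_loc, pr$mean_scale, log = TRUE) +
      log_halfnormal(sigma[k], pr$sd_scale) + log_sigma[k]  # Jacobian
  }
  for (i in seq_len(P)) {
    lp <- lp + sum(dnorm(theta[i, ], mu, sigma, log = TRUE))
    cpar <- setNames(vapply(seq_len(K), function(k)
      to_constrained(theta[i, k], pn[k]), numeric(1)), pn)
    lp <- lp + loglik_row(spec, cpar, pd[[ids[i]]], eps)
    if (!is.finite(lp)) return(-Inf)
  }
  lp
}

#' Fit a model variant by hierarchical Bayesian MCMC
#'
#' Samples the hierarchical posterior with an adaptive
#' Metropolis-within-Gibbs scheme: componentwise random-walk updates of each
#' participant's unconstrained parameters (proposal scales adapted toward
#' 44% acceptance during warmup, then frozen), exact conjugate Gibbs draws
#' of the Gaussian hyper-means, and slice sampling of the hyper-sds. The
#' sampler backend is exchangeable: what the package guarantees is the
#' convergence contract — split R-hat below `rhat_threshold` for every
#' recorded parameter — not a particular algorithm.
#'
#' Defaults follow common practice for this model family: 4 chains, 2000
#' iterations each with the first 50% discarded as warm-up.
#'
#' With a single participant the hierarchy is disabled (with a warning):
#' the individual parameters are then sampled under the hyper-mean priors
#' directly.
#'
#' @param spec a [model_spec()].
#' @param dataset a clean [dd_dataset()] (answered trials only are used).
#' @param priors a [prior_spec()].
#' @param n_chains,n_iter,warmup_frac sampler schedule.
#' @param seed integer seed; fits with the same seed are identical.
#' @param standard_ms standard for centering; defaults to the dataset's
#'   design.
#' @param eps density truncation tolerance.
#' @param rhat_threshold convergence threshold on split R-hat.
#' @param max_extensions if some R-hat is still above the threshold after
#'   the initial schedule, chains are resumed (adaptation frozen, RNG
#'   streams continued) in blocks of the post-warmup length up to this many
#'   times — the usual run-until-converged practice, made reproducible.
#' @return an object of class `ddm_fit` with elements `draws` (array
#'   iteration x chain x parameter; hyper-means `mu_*` and hyper-sds
#'   `sigma_*` on the unconstrained scale, individual parameters
#'   `<name>[<id>]` on the constrained scale), `rhat`, `converged`,
#'   `accept_rate`, plus the spec/priors/data/config needed downstream.
#' @export
fit_hddm <- function(spec, dataset, priors = prior_spec(),
                     n_chains = 4, n_iter = 2000, warmup_frac = 0.5,
                     seed = 1, standard_ms = NULL, eps = 1e-7,
                     rhat_threshold = 1.01, max_extensions = 2) {
  stopifnot(inherits(spec, "model_spec"), inherits(dataset, "dd_dataset"))
  pn <- param_names(spec)
  K <- length(pn)
  standard_ms <- standard_ms %||% (dataset$design$standard_ms %||% 500)
  pd <- prepare_participant_data(dataset, standard_ms)
  ids <- names(pd)
  P <- length(ids)
  if (any(vapply(pd, function(x) x$n, 0L) == 0))
    stop_domain("every participant must have at least one answered trial")
  hierarchical <- P >= 2
  if (!hierarchical)
    warning("single participant: hierarchy disabled, sampling individual-level posterior under the hyper-mean priors")

  n_warmup <- floor(n_iter * warmup_frac)
  n_keep <- n_iter - n_warmup
  par_names_out <- c(
    if (hierarchical) c(paste0("mu_", pn), paste0("sigma_", pn)),
    as.vector(t(outer(pn, ids, function(p, id) paste0(p, "[", id, "]")))))
  npar_out <- length(par_names_out)

  prior_loc <- vapply(pn, function(p) priors[[p]]$mean_loc, 0)
  prior_scale <- vapply(pn, function(p) priors[[p]]$mean_scale, 0)
  sd_scale <- vapply(pn, function(p) priors[[p]]$sd_scale, 0)
  init_step <- c(a = 0.1, tau = 0.15, z0 = 0.15, z1 = 2e-4,
                 v0 = 0.1, v1 = 1e-3, v2 = 1e-3, g = 0.3)[pn]

  # fast transform/likelihood paths for the sampler's inner loop
  idx_log <- which(PARAM_TRANSFORMS[pn] == "log")
  idx_logit <- which(PARAM_TRANSFORMS[pn] == "logit")
  constrain_row <- function(u) {
    u[idx_log] <- exp(u[idx_log])
    u[idx_logit] <- plogis(u[idx_logit])
    names(u) <- pn
    u
  }
  ia <- match("a", pn); itau <- match("tau", pn); iz0 <- match("z0", pn)
  iz1 <- match("z1", pn); iv0 <- match("v0", pn); iv1 <- match("v1", pn)
  iv2 <- match("v2", pn); ig <- match("g", pn)
  use_ref <- spec$use_internal_reference
  use_zreg <- spec$start_point_regression
  sep_w <- spec$separate_weights
  ll_fast <- function(cp, dat)
    loglik_total_cpp(dat$rt, dat$upper, dat$X1c, dat$X2c,
                     cp[[ia]], cp[[itau]], cp[[iz0]],
                     if (use_zreg) cp[[iz1]] else 0,
                     cp[[iv0]], cp[[iv1]],
                     if (sep_w) cp[[iv2]] else -cp[[iv1]],
                     if (use_ref) cp[[ig]] else 0,
                     use_ref, use_zreg, eps)
  # the drift weights are conditionally Gaussian (the drift enters the
  # density through a quadratic exponent only), so they are Gibbs-sampled
  # exactly; these are the identity-transform components of the block
  v_idx <- if (sep_w) c(iv0, iv1, iv2) else c(iv0, iv1)
  mh_idx <- setdiff(seq_len(K), v_idx)
  drift_suff <- function(cp, dat)
    drift_block_suffstats_cpp(dat$rt, dat$upper, dat$X1c, dat$X2c,
                              cp[[ia]], cp[[itau]], cp[[iz0]],
                              if (use_zreg) cp[[iz1]] else 0,
                              if (use_ref) cp[[ig]] else 0,
                              use_ref, use_zreg, sep_w)

  # pilot posterior-mode search per participant (shared across chains): a
  # few hundred likelihood evaluations that put every chain's initial state
  # near the typical set, so warm-up is spent adapting proposals rather
  # than traveling in from the priors
  pilot_mode <- function(i) {
    u0 <- prior_loc
    u0[pn == "tau"] <- min(u0[pn == "tau"], log(0.5 * min(pd[[i]]$rt)))
    nlp <- function(u) {
      l <- ll_fast(constrain_row(u), pd[[i]]) +
        sum(dnorm(u, prior_loc, prior_scale, log = TRUE))
      if (!is.finite(l)) 1e10 else -l
    }
    if (!is.finite(-nlp(u0))) {
      for (attempt in 1:60) {
        u0 <- prior_loc + 0.3 * prior_scale * rnorm(K)
        u0[pn == "tau"] <- min(u0[pn == "tau"], log(0.5 * min(pd[[i]]$rt)))
        if (is.finite(-nlp(u0))) break
      }
      if (!is.finite(-nlp(u0)))
        dd_stop(sprintf("could not find a finite-density starting point for participant %s",
                        ids[i]), "durddm_init_error")
    }
    optim(u0, nlp, method = "Nelder-Mead",
          control = list(maxit = 400, parscale = pmax(init_step, 1e-6)))$par
  }
  pilot <- with_seed(derive_seed(seed, "fit-pilot"),
                     t(vapply(seq_len(P), pilot_mode, numeric(K))))
  pilot_mu <- colMeans(pilot)
  pilot_sd <- pmax(if (P > 1) apply(pilot, 2, sd) else init_step,
                   init_step / 2)

  # Each chain lives in its own environment so that sampling can resume
  # after the initial schedule: when any split R-hat is still above the
  # threshold the chains are extended (with adaptation frozen and each
  # chain's RNG stream restored) until the convergence contract holds or
  # the extension budget is exhausted.
  chain_init <- quote({
    set.seed(chain_seed)
    mu <- pilot_mu + 0.2 * pilot_sd * rnorm(K)
    sigma <- pilot_sd * exp(0.2 * rnorm(K))
    theta <- matrix(NA_real_, P, K)
    ll <- numeric(P)
    for (i in seq_len(P)) {
      ok <- FALSE
      for (attempt in 1:60) {
        shrink <- 0.5^((attempt - 1) %/% 10)
        u <- pilot[i, ] + init_step * shrink * rnorm(K)
        l <- ll_fast(constrain_row(u), pd[[i]])
        if (is.finite(l)) { theta[i, ] <- u; ll[i] <- l; ok <- TRUE; break }
      }
      if (!ok)
        dd_stop(sprintf("could not find a finite-density initialization for participant %s after 60 attempts",
                        ids[i]), "durddm_init_error")
    }
    cmat <- t(apply(theta, 1, constrain_row))  # P x K constrained cache

    scales <- matrix(rep(init_step, each = P), P, K)
    scales2 <- matrix(1.5, P, K)  # steps along covariance directions
    acc <- matrix(0L, P, K)
    batch <- 0L
    n_acc_total <- 0; n_prop_total <- 0
    # adaptive joint proposal: per-participant covariance learned in warmup
    # (componentwise moves alone mix slowly through the a/tau correlation)
    hist_theta <- array(NA_real_, c(n_warmup, P, K))
    chol_prop <- vector("list", P)
    joint_scale <- rep(2.38 / sqrt(K), P)
    joint_acc <- integer(P)
    joint_reps <- 3L
    scale_step <- rep(0.3, K)
    scale_acc <- integer(K)
    hist_mu <- matrix(NA_real_, n_warmup, K)
    chol_mu <- NULL
    mv_step <- 0.8
    trans_acc_mv <- 0L

    kept <- matrix(NA_real_, 0L, npar_out)
    it_done <- 0L
    rng_state <- get(".Random.seed", globalenv())
  })

  chain_advance <- quote({
    assign(".Random.seed", rng_state, globalenv())
    kept <- rbind(kept,
                  matrix(NA_real_, n_steps - max(0L, n_warmup - it_done),
                         npar_out))
    for (it in (it_done + 1L):(it_done + n_steps)) {
      for (i in seq_len(P)) {
        u_i <- theta[i, ]
        rot <- chol_prop[[i]]   # once learned, sweep along the Cholesky
        for (k in mh_idx) {     # directions of the posterior covariance:
          u_new <- u_i          # near-independent 1-d conditionals
          if (is.null(rot)) {
            u_new[k] <- u_i[k] + scales[i, k] * rnorm(1)
          } else {
            u_new <- u_i + (scales2[i, k] * rnorm(1)) * rot[k, ]
          }
          c_new <- constrain_row(u_new)
          l_new <- ll_fast(c_new, pd[[i]])
          logr <- l_new - ll[i] +
            sum(dnorm(u_new, mu, sigma, log = TRUE)) -
            sum(dnorm(u_i, mu, sigma, log = TRUE))
          n_prop_total <- n_prop_total + 1
          if (is.finite(logr) && log(runif(1)) < logr) {
            u_i <- u_new
            ll[i] <- l_new
            cmat[i, ] <- c_new
            acc[i, k] <- acc[i, k] + 1L
            n_acc_total <- n_acc_total + 1
          }
        }
        if (!is.null(chol_prop[[i]])) {
          # joint proposals from the covariance learned in warmup: the
          # componentwise sweep alone mixes slowly through within-
          # participant correlations (boundary separation vs non-decision
          # time, drift intercept vs starting point)
          for (rep_j in seq_len(joint_reps)) {
            u_new <- u_i + joint_scale[i] * drop(rnorm(K) %*% chol_prop[[i]])
            c_new <- constrain_row(u_new)
            l_new <- ll_fast(c_new, pd[[i]])
            logr <- l_new - ll[i] +
              sum(dnorm(u_new, mu, sigma, log = TRUE)) -
              sum(dnorm(u_i, mu, sigma, log = TRUE))
            if (is.finite(logr) && log(runif(1)) < logr) {
              u_i <- u_new
              ll[i] <- l_new
              cmat[i, ] <- c_new
              joint_acc[i] <- joint_acc[i] + 1L
            }
          }
        }
        theta[i, ] <- u_i
      }

      # ---- drift-weight block: collapsed Gibbs ----
      # The drift weights are conditionally Gaussian given the remaining
      # parameters, so (i) their sufficient statistics are computed once
      # per sweep, (ii) the drift hyper-means/-sds are slice-sampled from
      # the marginal with the weights integrated out in closed form (no
      # funnel), and (iii) the weights are redrawn exactly.
      dv <- length(v_idx)
      SS <- lapply(seq_len(P), function(i) drift_suff(cmat[i, ], pd[[i]]))
      if (all(vapply(SS, function(s) isTRUE(s$ok), NA))) {
        log_marg <- function(mu_v, sig_v) {
          s0inv <- 1 / sig_v^2
          tot <- P * (-sum(log(sig_v)) - 0.5 * sum(mu_v^2 * s0inv))
          for (i in seq_len(P)) {
            U <- chol(SS[[i]]$H + diag(s0inv, nrow = dv))
            y <- backsolve(U, SS[[i]]$b + s0inv * mu_v, transpose = TRUE)
            tot <- tot - sum(log(diag(U))) + 0.5 * sum(y * y)
          }
          tot
        }
        if (hierarchical) {
          for (j in seq_len(dv)) {
            k <- v_idx[j]
            mu[k] <- slice_sample1(mu[k], function(m) {
              mv <- mu[v_idx]; mv[j] <- m
              log_marg(mv, sigma[v_idx]) +
                dnorm(m, prior_loc[k], prior_scale[k], log = TRUE)
            }, w = 0.05)
            sigma[k] <- exp(slice_sample1(log(sigma[k]), function(ls) {
              sv <- sigma[v_idx]; sv[j] <- exp(ls)
              log_marg(mu[v_idx], sv) +
                log_halfnormal(exp(ls), sd_scale[k]) + ls
            }, w = 1))
          }
        }
        for (i in seq_len(P)) {
          pp <- 1 / sigma[v_idx]^2
          U <- chol(SS[[i]]$H + diag(pp, nrow = dv))
          rhs <- SS[[i]]$b + pp * mu[v_idx]
          mvec <- backsolve(U, backsolve(U, rhs, transpose = TRUE))
          beta_new <- mvec + backsolve(U, rnorm(dv))
          beta_old <- theta[i, v_idx]
          ll[i] <- ll[i] + sum(SS[[i]]$b * (beta_new - beta_old)) -
            0.5 * (drop(beta_new %*% SS[[i]]$H %*% beta_new) -
                   drop(beta_old %*% SS[[i]]$H %*% beta_old))
          theta[i, v_idx] <- beta_new
          cmat[i, v_idx] <- beta_new
        }
      }
      if (it %% 200L == 0L) {
        # refresh the incrementally tracked log-likelihoods to shed
        # floating-point drift from the exact-update bookkeeping
        for (i in seq_len(P)) ll[i] <- ll_fast(cmat[i, ], pd[[i]])
      }
      if (hierarchical) {
        for (k in seq_len(K)) {
          # conjugate Gibbs for the Gaussian hyper-mean
          prec <- P / sigma[k]^2 + 1 / prior_scale[k]^2
          m <- (sum(theta[, k]) / sigma[k]^2 + prior_loc[k] / prior_scale[k]^2) / prec
          mu[k] <- rnorm(1, m, sqrt(1 / prec))
          # slice sampling for the half-normal hyper-sd (on log scale)
          ss <- sum((theta[, k] - mu[k])^2)
          target <- function(ls) {
            s <- exp(ls)
            -P * ls - ss / (2 * s^2) - s^2 / (2 * sd_scale[k]^2) + ls
          }
          sigma[k] <- exp(slice_sample1(log(sigma[k]), target, w = 0.5))
          if (!(k %in% mh_idx)) next  # drift block: exact Gibbs needs no
                                      # funnel or rescaling machinery
          # every few iterations: exact slice update of the hyper-sd along
          # the non-centered direction (standardized deviations held fixed,
          # individual values rescaled with sigma) — self-tuning traversal
          # of the funnel of weakly identified parameters
          nc_every <- if (pn[k] %in% c("z0", "z1")) 2L else 4L
          if (it %% nc_every == 0L) {
            eta <- (theta[, k] - mu[k]) / sigma[k]
            ll_cache <- ll
            nc_target <- function(ls) {
              s <- exp(ls)
              th <- mu[k] + s * eta
              tot <- 0
              ll_try <- ll_cache
              for (i in seq_len(P)) {
                u_i <- theta[i, ]
                u_i[k] <- th[i]
                ll_try[i] <- ll_fast(constrain_row(u_i), pd[[i]])
                tot <- tot + ll_try[i]
                if (!is.finite(tot)) return(-Inf)
              }
              ll_cache <<- ll_try
              tot + log_halfnormal(s, sd_scale[k]) + ls
            }
            ls_new <- slice_sample1(log(sigma[k]), nc_target, w = 1, max_steps = 12)
            sigma[k] <- exp(ls_new)
            theta[, k] <- mu[k] + sigma[k] * eta
            ll <- ll_cache
            cmat[, k] <- vapply(theta[, k], to_constrained, 0, param = pn[k])
          }
          # group rescaling move: scales every participant's deviation and
          # the hyper-sd together (the funnel direction the conditional
          # updates cannot take); occasional 4x steps traverse the wide
          # log-sd marginals of weakly identified parameters
          kick <- if (runif(1) < 0.25) 4 else 1
          cfac <- exp(kick * scale_step[k] * rnorm(1))
          th_new <- mu[k] + cfac * (theta[, k] - mu[k])
          sg_new <- cfac * sigma[k]
          ll_new <- numeric(P)
          dlik <- 0
          for (i in seq_len(P)) {
            u_i <- theta[i, ]
            u_i[k] <- th_new[i]
            ll_new[i] <- ll_fast(constrain_row(u_i), pd[[i]])
            dlik <- dlik + ll_new[i] - ll[i]
            if (!is.finite(dlik)) break
          }
          logr <- dlik +
            sum(dnorm(th_new, mu[k], sg_new, log = TRUE)) -
            sum(dnorm(theta[, k], mu[k], sigma[k], log = TRUE)) +
            log_halfnormal(sg_new, sd_scale[k]) -
            log_halfnormal(sigma[k], sd_scale[k]) +
            (P + 1) * log(cfac)          # Jacobian of the scaling map
          if (is.finite(logr) && log(runif(1)) < logr) {
            theta[, k] <- th_new
            sigma[k] <- sg_new
            ll <- ll_new
            cmat[, k] <- vapply(th_new, to_constrained, 0, param = pn[k])
            scale_acc[k] <- scale_acc[k] + 1L
          }
        }
        # multivariate group translation: shifts all participants and the
        # hyper-means along directions drawn from the learned hyper-mean
        # covariance; individual deviations (and so their Gaussian terms)
        # are unchanged, only the likelihood and the hyper-mean priors move.
        # This is the move that tracks across-parameter trade-offs at the
        # group level (e.g. bias carried by the starting point vs the drift
        # intercept).
        if (!is.null(chol_mu)) {
          for (rep_t in 1:3) {
            dvec <- mv_step * drop(rnorm(K) %*% chol_mu)
            mu_new <- mu + dvec
            th_new <- theta + matrix(dvec, P, K, byrow = TRUE)
            ll_new <- numeric(P)
            dlik <- 0
            for (i in seq_len(P)) {
              ll_new[i] <- ll_fast(constrain_row(th_new[i, ]), pd[[i]])
              dlik <- dlik + ll_new[i] - ll[i]
              if (!is.finite(dlik)) break
            }
            logr <- dlik +
              sum(dnorm(mu_new, prior_loc, prior_scale, log = TRUE)) -
              sum(dnorm(mu, prior_loc, prior_scale, log = TRUE))
            if (is.finite(logr) && log(runif(1)) < logr) {
              mu <- mu_new
              theta <- th_new
              ll <- ll_new
              cmat <- t(apply(th_new, 1, constrain_row))
              trans_acc_mv <- trans_acc_mv + 1L
            }
          }
        }
      } else {
        # hierarchy off: individual parameters get the hyper-mean priors
        mu <- prior_loc
        sigma <- prior_scale
      }
      if (it <= n_warmup) {
        hist_theta[it, , ] <- theta
        if (it %% 25 == 0) {
          batch <- batch + 1L
          delta <- min(0.1, 1 / sqrt(batch))
          rate <- acc / 25
          if (is.null(chol_prop[[1]]))
            scales <- scales * exp(ifelse(rate > 0.44, delta, -delta))
          else
            scales2 <- scales2 * exp(ifelse(rate > 0.44, delta, -delta))
          acc[] <- 0L
          jrate <- joint_acc / (25 * joint_reps)
          joint_scale <- joint_scale * exp(ifelse(jrate > 0.23, delta, -delta))
          joint_acc[] <- 0L
          # the rescaling moves are one-dimensional: target 44% acceptance
          srate <- scale_acc / 25
          scale_step <- scale_step * exp(ifelse(srate > 0.44, delta, -delta))
          scale_acc[] <- 0L
          mvrate <- trans_acc_mv / (25 * 3)
          mv_step <- mv_step * exp(if (mvrate > 0.23) delta else -delta)
          trans_acc_mv <- 0L
        }
        if (hierarchical) hist_mu[it, ] <- mu
        if (it >= 150 && it %% 50 == 0) {
          win <- max(1, it - 500):it
          for (i in seq_len(P)) {
            cv <- var(hist_theta[win, i, , drop = TRUE]) +
              diag(1e-10 + 1e-6 * init_step^2, K)
            ch <- tryCatch(chol(cv), error = function(e) NULL)
            if (!is.null(ch)) chol_prop[[i]] <- ch
          }
          if (hierarchical) {
            cvm <- var(hist_mu[win, , drop = FALSE]) +
              diag(1e-10 + 1e-6 * init_step^2, K)
            chm <- tryCatch(chol(cvm), error = function(e) NULL)
            if (!is.null(chm)) chol_mu <- chm
          }
        }
      } else {
        kept[it - n_warmup, ] <- c(
          if (hierarchical) c(mu, sigma),
          as.vector(cmat))  # param-major: matches par_names_out ordering
      }
    }
    it_done <- it_done + n_steps
    rng_state <- get(".Random.seed", globalenv())
  })

  new_chain <- function(chain_seed) {
    e <- new.env(parent = environment())
    e$chain_seed <- chain_seed
    eval(chain_init, e)
    e
  }
  advance <- function(e, n_steps) {
    e$n_steps <- as.integer(n_steps)
    eval(chain_advance, e)
    invisible(e)
  }

  chains <- lapply(seq_len(n_chains), function(cc)
    new_chain(derive_seed(seed, paste0("fit-chain-", cc))))
  for (e in chains) advance(e, n_iter)

  assemble <- function() {
    nk <- nrow(chains[[1]]$kept)
    d <- array(NA_real_, c(nk, n_chains, npar_out),
               dimnames = list(NULL, paste0("chain", seq_len(n_chains)),
                               par_names_out))
    for (cc in seq_len(n_chains)) d[, cc, ] <- chains[[cc]]$kept
    d
  }
  compute_rhat <- function(d) {
    if (n_chains >= 2)
      vapply(par_names_out, function(p) rhat(d[, , p, drop = FALSE]), 0)
    else setNames(rep(NA_real_, npar_out), par_names_out)
  }
  draws <- assemble()
  rh <- compute_rhat(draws)
  extensions <- 0L
  while (n_chains >= 2 && extensions < max_extensions &&
         any(rh >= rhat_threshold, na.rm = TRUE)) {
    extensions <- extensions + 1L
    for (e in chains) advance(e, max(n_iter - n_warmup, 200L))
    draws <- assemble()
    rh <- compute_rhat(draws)
  }

  structure(list(
    draws = draws, spec = spec, priors = priors, participant_ids = ids,
    standard_ms = standard_ms, dataset = dataset, seed = seed,
    config = list(n_chains = n_chains, n_iter = n_iter,
                  warmup_frac = warmup_frac, eps = eps,
                  extensions = extensions,
                  n_kept_per_chain = nrow(chains[[1]]$kept)),
    hierarchical = hierarchical,
    rhat = rh,
    converged = all(is.na(rh) | rh < rhat_threshold),
    accept_rate = mean(vapply(chains, function(e)
      e$n_acc_total / max(e$n_prop_total, 1), 0)),
    move_rates = with(chains[[1]], list(
      component = acc / nrow(kept),
      joint = joint_acc / (nrow(kept) * joint_reps),
      scale = scale_acc / nrow(kept),
      translate_mv = trans_acc_mv / (nrow(kept) * 3),
      scale_step = scale_step,
      mv_step = mv_step))),
    class = "ddm_fit")
}

#' @export
print.ddm_fit <- function(x, ...) {
  cat("<ddm_fit> model", x$spec$model, "|", length(x$participant_ids),
      "participant(s) |", dim(x$draws)[2], "chains x", dim(x$draws)[1],
      "kept draws\n")
  cat("  converged:", x$converged, "| max R-hat:",
      round(max(x$rhat, na.rm = TRUE), 4),
      "| mean acceptance:", round(x$accept_rate, 3), "\n")
  invisible(x)
}

#' Pooled posterior draws as a matrix
#' @param fit a `ddm_fit`.
#' @return matrix (chains x iterations) rows by parameter columns.
#' @export
posterior_matrix <- function(fit) {
  d <- fit$draws
  matrix(aperm(d, c(1, 2, 3)), nrow = dim(d)[1] * dim(d)[2],
         dimnames = list(NULL, dimnames(d)[[3]]))
}

#' Individual-level draws of one parameter
#' @param fit a `ddm_fit`.
#' @param param parameter name (e.g. `"v1"`).
#' @param scale `"constrained"` (as stored) or `"unconstrained"`.
#' @return matrix draws x participants.
#' @export
individual_draws <- function(fit, param, scale = c("constrained", "unconstrained")) {
  scale <- match.arg(scale)
  cols <- paste0(param, "[", fit$participant_ids, "]")
  m <- posterior_matrix(fit)[, cols, drop = FALSE]
  if (scale == "unconstrained") m[] <- to_unconstrained(m, param)
  colnames(m) <- fit$participant_ids
  m
}

#' Split-chain potential scale reduction factor
#'
#' Gelman-Rubin R-hat computed on split chains: each chain is halved, the
#' between- and within-sequence variances are compared. Values near 1
#' indicate the chains agree; fits in this package are flagged converged
#' only when every parameter is below 1.01. Chains with zero variance (a
#' constant parameter) return 1 by convention.
#'
#' @param x a `ddm_fit`, or a draws matrix/array (iterations x chains).
#' @param parameter parameter name when `x` is a fit.
#' @return scalar R-hat.
#' @export
rhat <- function(x, parameter = NULL) {
  if (inherits(x, "ddm_fit")) {
    if (is.null(parameter)) stop_domain("give a parameter name")
    x <- x$draws[, , parameter, drop = FALSE]
  }
  m <- if (length(dim(x)) == 3) x[, , 1] else as.matrix(x)
  if (ncol(m) < 2) stop_domain("R-hat needs at least 2 chains")
  nh <- floor(nrow(m) / 2)
  halves <- do.call(cbind, lapply(seq_len(ncol(m)), function(j)
    cbind(m[seq_len(nh), j], m[nh + seq_len(nh), j])))
  W <- mean(apply(halves, 2, var))
  B <- nh * var(colMeans(halves))
  if (!is.finite(W) || W == 0) return(1)
  sqrt(((nh - 1) / nh * W + B / nh) / W)
}

#' Highest density interval
#'
#' Shortest contiguous interval containing the requested posterior mass:
#' over the sorted sample, the narrowest window spanning
#' `ceiling(mass * n)` values.
#'
#' @param samples numeric vector (>= 50 values).
#' @param mass probability mass in (0, 1).
#' @return numeric `c(lower, upper)`.
#' @export
hdi <- function(samples, mass = 0.95) {
  if (mass <= 0 || mass >= 1) stop_domain("mass must lie in (0, 1)")
  samples <- samples[is.finite(samples)]
  n <- length(samples)
  if (n < 50) stop_domain("hdi needs at least 50 samples")
  s <- sort(samples)
  m <- ceiling(mass * n)
  widths <- s[m:n] - s[seq_len(n - m + 1)]
  j <- which.min(widths)
  c(s[j], s[j + m - 1])
}

#' Posterior mode from samples
#'
#' Argmax of a Gaussian kernel density estimate with the normal-reference
#' bandwidth. With several equally high peaks the lower value is returned
#' (the grid argmax takes the first maximum).
#'
#' @param samples numeric vector (>= 100 values).
#' @return scalar mode estimate.
#' @export
posterior_mode <- function(samples) {
  samples <- samples[is.finite(samples)]
  if (length(samples) < 100) stop_domain("posterior_mode needs at least 100 samples")
  if (max(samples) == min(samples)) return(samples[1])
  d <- density(samples, bw = stats::bw.nrd(samples), n = 1024)
  d$x[which.max(d$y)]
}

#' Group-level posterior summary
#'
#' Mode and 95% HDI of every hyper-mean, reported on the constrained scale
#' (the hyper-mean of a log/logit parameter is back-transformed, i.e. the
#' group median).
#'
#' @param fit a hierarchical `ddm_fit`.
#' @param mass HDI mass.
#' @return data frame with `parameter`, `mode`, `lower`, `upper`.
#' @export
group_summary <- function(fit, mass = 0.95) {
  if (!fit$hierarchical) stop_domain("fit has no group level")
  pn <- param_names(fit$spec)
  pm <- posterior_matrix(fit)
  rows <- lapply(pn, function(p) {
    u <- pm[, paste0("mu_", p)]
    x <- to_constrained(u, p)
    h <- hdi(x, mass)
    data.frame(parameter = p, mode = posterior_mode(x),
               lower = h[1], upper = h[2], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Serialize posterior draws as chain-tagged delimited text
#'
#' Writes a CSV with columns `chain, iteration, parameter, value` plus a
#' JSON metadata sidecar (`<path>.meta.json`) holding the model spec,
#' priors, participants, seed and sampler configuration, sufficient for
#' downstream model comparison and prediction.
#'
#' @param fit a `ddm_fit`.
#' @param path output CSV path.
#' @export
write_draws <- function(fit, path) {
  d <- fit$draws
  nit <- dim(d)[1]; nch <- dim(d)[2]; pnames <- dimnames(d)[[3]]
  long <- data.frame(
    chain = rep(seq_len(nch), each = nit, times = length(pnames)),
    iteration = rep(seq_len(nit), times = nch * length(pnames)),
    parameter = rep(pnames, each = nit * nch),
    value = as.vector(d))
  write.csv(long, path, row.names = FALSE)
  meta <- list(model = fit$spec$model,
               participants = fit$participant_ids,
               standard_ms = fit$standard_ms,
               seed = fit$seed,
               config = fit$config,
               hierarchical = fit$hierarchical,
               converged = fit$converged,
               rhat_max = max(fit$rhat, na.rm = TRUE),
               priors = lapply(unclass(fit$priors), function(x) x))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Load serialized posterior draws
#'
#' Rebuilds a `ddm_fit`-like object (without the original dataset) from the
#' files written by [write_draws()].
#'
#' @param path CSV path given to [write_draws()].
#' @return object of class `ddm_fit`.
#' @export
read_draws <- function(path) {
  long <- read.csv(path, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  pnames <- unique(long$parameter)
  nch <- max(long$chain); nit <- max(long$iteration)
  d <- array(NA_real_, c(nit, nch, length(pnames)),
             dimnames = list(NULL, paste0("chain", seq_len(nch)), pnames))
  for (p in pnames)
    for (cc in seq_len(nch)) {
      sel <- long$parameter == p & long$chain == cc
      d[, cc, p] <- long$value[sel][order(long$iteration[sel])]
    }
  priors <- do.call(prior_spec, lapply(meta$priors, function(x)
    list(mean_loc = x$mean_loc, mean_scale = x$mean_scale, sd_scale = x$sd_scale)))
  structure(list(draws = d, spec = model_spec(meta$model), priors = priors,
                 participant_ids = meta$participants,
                 standard_ms = meta$standard_ms, dataset = NULL,
                 seed = meta$seed, config = meta$config,
                 hierarchical = meta$hierarchical,
                 rhat = setNames(rep(NA_real_, length(pnames)), pnames),
                 converged = meta$converged, accept_rate = NA_real_),
            class = "ddm_fit")
}
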