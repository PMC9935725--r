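#' Pointwise log-likelihood matrix over posterior draws
#'
#' Entry (s, n) is the log density of trial n under draw s's
#' individual-level parameters, with the internal-reference state recomputed
#' per draw along each participant's session. Trials are ordered by
#' (participant, trial_index), matching the clean dataset.
#'
#' @param fit a `ddm_fit`.
#' @param dataset dataset to evaluate; defaults to the fitted data.
#' @param max_draws optionally thin to at most this many draws (evenly
#'   spaced over the pooled posterior).
#' @return object of class `pointwise_loglik`: a draws x trials matrix with
#'   attributes `trial_id` (participant/trial labels) and `draw_id`.
#' @export
pointwise_loglik <- function(fit, dataset = NULL, max_draws = NULL) {
  dataset <- dataset %||% fit$dataset
  if (is.null(dataset)) stop_domain("no dataset stored in fit; pass one explicitly")
  missing_ids <- setdiff(participants(dataset), fit$participant_ids)
  if (length(missing_ids))
    stop_domain(paste0("dataset has participants absent from the fit: ",
                       paste(missing_ids, collapse = ", ")))
  spec <- fit$spec
  pn <- param_names(spec)
  pm <- posterior_matrix(fit)
  S <- nrow(pm)
  keep <- if (!is.null(max_draws) && max_draws < S)
    round(seq(1, S, length.out = max_draws)) else seq_len(S)
  pm <- pm[keep, , drop = FALSE]
  ids <- participants(dataset)
  blocks <- lapply(ids, function(pid) {
    tr <- participant_trials(dataset, pid)
    tr <- tr[!is.na(tr$response) & !is.na(tr$rt_s), , drop = FALSE]
    list(pid = pid, tr = tr)
  })
  ll <- matrix(NA_real_, nrow(pm), sum(vapply(blocks, function(b) nrow(b$tr), 0L)))
  trial_id <- unlist(lapply(blocks, function(b)
    paste0(b$pid, ":", b$tr$trial_index)))
  for (s in seq_len(nrow(pm))) {
    col <- 1L
    for (b in blocks) {
      vals <- setNames(pm[s, paste0(pn, "[", b$pid, "]")], pn)
      params <- do.call(individual_parameters, as.list(vals))
      l <- loglik_participant(spec, params, b$tr,
                              standard_ms = fit$standard_ms,
                              eps = fit$config$eps %||% 1e-7)
      ll[s, col:(col + nrow(b$tr) - 1L)] <- l$pointwise
      col <- col + nrow(b$tr)
    }
  }
  structure(ll, trial_id = trial_id, draw_id = keep,
            class = c("pointwise_loglik", "matrix", "array"))
}

#' Maximum-likelihood fit of the generalized Pareto distribution
#'
#' Profile-likelihood estimator on a data-driven grid (Zhang & Stephens,
#' 2009) with the weak shape regularization used in the PSIS literature.
#'
#' @param x positive exceedances over the tail threshold.
#' @return list with shape `k` and scale `sigma`.
#' @keywords internal
gpd_fit <- function(x) {
  x <- sort.int(x)
  n <- length(x)
  m <- 30L + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  theta <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (3 * xstar)
  prof <- vapply(theta, function(th) {
    k <- -mean(log1p(-th * x))
    n * (log(th / k) + k - 1)
  }, 0)
  w <- exp(prof - max(prof))
  w <- w / sum(w)
  th_hat <- sum(theta * w)
  k <- mean(log1p(-th_hat * x))       # shape (positive = heavy tail)
  sigma <- -k / th_hat
  k <- (n * k + 5) / (n + 10)         # weakly informative shape prior
  list(k = k, sigma = sigma)
}

qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma / k * ((1 - p)^(-k) - 1)
}

#' Pareto-smoothed importance-sampling leave-one-out cross-validation
#'
#' Approximates exact leave-one-out predictive densities from a single
#' posterior sample. For each trial the importance ratios are the
#' reciprocal likelihoods; the `M = min(0.2 S, 3 sqrt(S))` largest ratios
#' are replaced by expected order statistics of a generalized Pareto fit to
#' the tail, weights are truncated at `S^(3/4)` times the mean weight, and
#' the pointwise elpd is the smoothed-weight average of the predictive
#' density. Trials whose Pareto shape exceeds 0.7 are reported, never
#' silently dropped; trials whose likelihood is `-Inf` under every draw are
#' flagged and excluded with a warning.
#'
#' @param ll a [pointwise_loglik()] matrix (>= 100 draws).
#' @return object of class `loo_result`: list with `elpd`, `se`,
#'   `pointwise`, `pareto_k`, `n_high_k` (shapes above 0.7) and the trial
#'   ids.
#' @export
psis_loo <- function(ll) {
  S <- nrow(ll)
  if (S < 100) stop_domain("psis_loo needs at least 100 posterior draws")
  N <- ncol(ll)
  trial_id <- attr(ll, "trial_id") %||% as.character(seq_len(N))
  all_ninf <- apply(ll, 2, function(col) all(!is.finite(col)))
  if (any(all_ninf)) {
    warning(sprintf("%d trial(s) with -Inf likelihood under every draw were excluded",
                    sum(all_ninf)))
    ll <- ll[, !all_ninf, drop = FALSE]
    trial_id <- trial_id[!all_ninf]
    N <- ncol(ll)
  }
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  pw <- numeric(N)
  kk <- numeric(N)
  for (n in seq_len(N)) {
    l <- ll[, n]
    lr <- -l                      # log importance ratios
    fin_max <- max(lr[is.finite(lr)])
    lr[lr == Inf] <- fin_max      # zero-likelihood draws join the ratio tail
    lr <- lr - fin_max
    r <- exp(lr)                  # raw ratios, max = 1
    ord <- order(r)
    tail_idx <- ord[(S - M + 1):S]
    u <- r[ord[S - M]]            # threshold below the M largest
    exceed <- r[tail_idx] - u
    if (length(unique(exceed)) >= 5 && sd(exceed) > 0) {
      gf <- gpd_fit(exceed[exceed > 0] + 1e-12)
      smoothed <- u + vapply((seq_len(M) - 0.5) / M, qgpd, 0,
                             k = gf$k, sigma = gf$sigma)
      r[tail_idx[order(r[tail_idx])]] <- sort(smoothed)
      kk[n] <- gf$k
    } else {
      kk[n] <- -Inf               # degenerate tail: no smoothing needed
    }
    r <- pmin(r, S^0.75 * mean(r))   # truncation
    lw <- log(r)
    # elpd_n = log( sum w * p(y_n) / sum w )
    num <- log_sum_exp(lw + l)
    den <- log_sum_exp(lw)
    pw[n] <- num - den
  }
  structure(list(elpd = sum(pw),
                 se = sqrt(N * var(pw)),
                 pointwise = pw,
                 pareto_k = kk,
                 n_high_k = sum(kk > 0.7),
                 trial_id = trial_id),
            class = "loo_result")
}

log_sum_exp <- function(x) {
  x <- x[!is.na(x)]
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' @export
print.loo_result <- function(x, ...) {
  cat("<loo_result> elpd =", round(x$elpd, 1), "SE =", round(x$se, 1),
      "|", length(x$pointwise), "trials |", x$n_high_k, "Pareto k > 0.7\n")
  invisible(x)
}

#' Compare models by expected log predictive density
#'
#' Differences are taken relative to the model with the highest elpd (the
#' best model sits at 0). The standard error of each difference uses the
#' paired pointwise contributions, not independent pooling, so models that
#' err on the same trials are not spuriously separated.
#'
#' @param results named list of [psis_loo()] results computed on the
#'   identical trial set.
#' @return data frame ordered best-first with `model`, `elpd`, `se`,
#'   `elpd_diff`, `se_diff`.
#' @export
elpd_compare <- function(results) {
  if (is.null(names(results)))
    names(results) <- paste0("model", seq_along(results))
  ids <- lapply(results, function(r) r$trial_id)
  if (length(unique(vapply(results, function(r) length(r$pointwise), 0L))) != 1 ||
      !all(vapply(ids, identical, TRUE, y = ids[[1]])))
    stop_domain("all results must be computed on the identical trial set")
  elpds <- vapply(results, function(r) r$elpd, 0)
  best <- which.max(elpds)
  rows <- lapply(seq_along(results), function(j) {
    dpw <- results[[j]]$pointwise - results[[best]]$pointwise
    data.frame(model = names(results)[j],
               elpd = elpds[j],
               se = results[[j]]$se,
               elpd_diff = sum(dpw),
               se_diff = sqrt(length(dpw) * var(dpw)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$elpd), , drop = FALSE]
}
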