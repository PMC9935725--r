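#' Per-participant psychometric fit
#'
#' Logistic regression of the probability of judging the comparison longer
#' than the standard on the centered comparison duration, the stimulus
#' order, and their interaction — fitted per participant, then reduced to a
#' per-order intercept/slope pair. The default method is maximum likelihood
#' via [glm()]; `method = "bayes"` uses a posterior-mode (MAP) fit under
#' weak zero-centred normal priors, which agrees with ML in the large-data
#' limit and doubles as the regularized fallback under complete separation.
#'
#' @param trials one participant's trials (canonical columns), responses
#'   present on the trials to use.
#' @param standard_ms the standard duration in ms.
#' @param method `"ml"` or `"bayes"`.
#' @return object of class `psychometric_fit`: per-order coefficients
#'   (`beta0` in logit units at the standard, `beta` in logit per ms),
#'   method and convergence metadata.
#' @export
fit_psychometric <- function(trials, standard_ms = 500, method = c("ml", "bayes")) {
  method <- match.arg(method)
  tr <- annotate_comparison(trials)
  tr <- tr[!is.na(tr$comparison_longer), , drop = FALSE]
  for (o in c("sc", "cs")) {
    lev <- unique(tr$comparison_ms[tr$order == o])
    if (length(lev) < 2)
      stop_domain(sprintf("order '%s' needs >= 2 comparison levels with responses", o))
  }
  x <- tr$comparison_ms - standard_ms
  ord <- factor(tr$order, levels = c("sc", "cs"))
  y <- tr$comparison_longer
  X <- cbind(1, x, ord == "cs", x * (ord == "cs"))
  colnames(X) <- c("b0", "bx", "b_cs", "bx_cs")

  coefs <- NULL
  converged <- TRUE
  if (method == "ml") {
    fit <- suppressWarnings(glm(y ~ x * ord, family = binomial()))
    separated <- any(fitted(fit) > 1 - 1e-8) || any(fitted(fit) < 1e-8) ||
      !fit$converged || any(abs(coef(fit)[c("x", "x:ordcs")]) > 1)
    if (separated) {
      warning("complete or quasi-complete separation: falling back to a weakly regularized fit")
      method <- "bayes"
      converged <- FALSE
    } else {
      coefs <- coef(fit)
    }
  }
  if (method == "bayes") {
    # MAP under b ~ N(0, 5) for intercepts, N(0, 1) for per-ms slopes
    psd <- c(5, 1, 5, 1)
    nlp <- function(b) {
      eta <- drop(X %*% b)
      -sum(y * eta - log1p(exp(eta))) + sum(b^2 / (2 * psd^2))
    }
    opt <- optim(c(0, 0.01, 0, 0), nlp, method = "BFGS",
                 control = list(maxit = 500))
    coefs <- setNames(opt$par, c("(Intercept)", "x", "ordcs", "x:ordcs"))
    converged <- converged && opt$convergence == 0
  }
  per_order <- data.frame(
    order = c("sc", "cs"),
    beta0 = c(coefs[["(Intercept)"]], coefs[["(Intercept)"]] + coefs[["ordcs"]]),
    beta = c(coefs[["x"]], coefs[["x"]] + coefs[["x:ordcs"]]),
    stringsAsFactors = FALSE)
  structure(list(per_order = per_order, method = method,
                 converged = converged, standard_ms = standard_ms,
                 coefficients = coefs),
            class = "psychometric_fit")
}

order_row <- function(fit, order) {
  r <- fit$per_order[fit$per_order$order == order, ]
  if (!nrow(r)) stop_domain(paste0("unknown order: ", order))
  r
}

#' Point of subjective equality
#'
#' Comparison duration at which the fitted psychometric function crosses
#' 50%: `standard_ms - beta0 / beta`.
#'
#' @param fit a [fit_psychometric()] object.
#' @param order `"sc"` or `"cs"`.
#' @return PSE in ms.
#' @export
pse <- function(fit, order) {
  r <- order_row(fit, order)
  if (r$beta == 0) stop_domain("zero psychometric slope: PSE undefined")
  fit$standard_ms - r$beta0 / r$beta
}

#' Difference limen
#'
#' Half the distance between the 75% and 25% points of the psychometric
#' function; for the logistic this is `log(3) / beta`. Smaller DL means
#' better discrimination.
#'
#' @inheritParams pse
#' @return DL in ms.
#' @export
dl <- function(fit, order) {
  r <- order_row(fit, order)
  if (r$beta <= 0) stop_domain("non-positive psychometric slope: DL undefined")
  log(3) / r$beta
}

#' Type A and Type B context effects of one participant
#'
#' Sign conventions, fixed package-wide: `type_a = pse_sc - pse_cs` and
#' `type_b = dl_sc - dl_cs`, so a negative Type B effect (the classical
#' finding) means discrimination is better when the standard precedes the
#' comparison.
#'
#' @param fit a [fit_psychometric()] object.
#' @param v1,v2 optional drift weights of the participant; when given, the
#'   proportional weight difference ([proportional_weight_difference()]) is
#'   filled in.
#' @return one-row data frame with `pse_sc`, `pse_cs`, `dl_sc`, `dl_cs`,
#'   `type_a`, `type_b`, `prop_weight_diff`.
#' @export
context_effects <- function(fit, v1 = NULL, v2 = NULL) {
  out <- data.frame(
    pse_sc = pse(fit, "sc"), pse_cs = pse(fit, "cs"),
    dl_sc = dl(fit, "sc"), dl_cs = dl(fit, "cs"))
  out$type_a <- out$pse_sc - out$pse_cs
  out$type_b <- out$dl_sc - out$dl_cs
  out$prop_weight_diff <- if (!is.null(v1) && !is.null(v2))
    proportional_weight_difference(v1, v2) else NA_real_
  out
}

#' Proportional difference of the stimulus weights
#'
#' `(w1 - w2) / (w1 + w2)` on weight magnitudes, with `w1 = v1` and
#' `w2 = -v2`: the second-stimulus drift weight enters the drift regression
#' subtractively, so its magnitude is the negated coefficient. Negative
#' values mean the second stimulus weighs more.
#'
#' @param v1 drift weight of the first stimulus (per ms).
#' @param v2 drift weight of the second stimulus (per ms, typically < 0).
#' @return dimensionless proportional difference; vectorized.
#' @export
proportional_weight_difference <- function(v1, v2) {
  w1 <- v1
  w2 <- -v2
  if (any(w1 + w2 <= 0))
    stop_domain("weight magnitudes must have a positive sum")
  (w1 - w2) / (w1 + w2)
}

#' Correlate weight asymmetries with context effects
#'
#' Pearson correlation across participants between the proportional weight
#' difference and an effect measure (e.g. the Type B effect). Pairs with
#' missing values are deleted listwise and reported via the `n_used`
#' attribute.
#'
#' @param weight_diffs per-participant proportional weight differences.
#' @param effects per-participant effect values, same order.
#' @return Pearson r with attribute `n_used`.
#' @export
correlate_weights_effects <- function(weight_diffs, effects) {
  if (length(weight_diffs) != length(effects))
    stop_domain("inputs must have the same length")
  ok <- is.finite(weight_diffs) & is.finite(effects)
  if (sum(ok) < 3) stop_domain("need at least 3 complete participant pairs")
  if (sd(weight_diffs[ok]) == 0 || sd(effects[ok]) == 0)
    stop_domain("zero variance: correlation undefined")
  r <- cor(weight_diffs[ok], effects[ok])
  attr(r, "n_used") <- sum(ok)
  r
}

#' Context-effect table for a whole dataset
#'
#' Fits the psychometric model per participant and assembles the exportable
#' effects table.
#'
#' @param dataset a [dd_dataset()].
#' @param standard_ms standard duration; defaults to the dataset's design.
#' @param method psychometric fitting method, see [fit_psychometric()].
#' @return data frame with one row per participant.
#' @export
effects_table <- function(dataset, standard_ms = NULL, method = "ml") {
  standard_ms <- standard_ms %||% (dataset$design$standard_ms %||% 500)
  rows <- lapply(participants(dataset), function(pid) {
    fit <- fit_psychometric(participant_trials(dataset, pid), standard_ms, method)
    cbind(data.frame(participant_id = pid, stringsAsFactors = FALSE),
          context_effects(fit))
  })
  do.call(rbind, rows)
}
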