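# Transforms mapping each parameter's support to the real line. The Gaussian
# hyper-distributions of the hierarchy live on the unconstrained scale.
PARAM_TRANSFORMS <- c(a = "log", tau = "log", z0 = "logit", z1 = "identity",
                      v0 = "identity", v1 = "identity", v2 = "identity",
                      g = "logit")

to_unconstrained <- function(value, param) {
  switch(PARAM_TRANSFORMS[[param]],
         log = log(value), logit = logit(value), identity = value)
}

to_constrained <- function(u, param) {
  switch(PARAM_TRANSFORMS[[param]],
         log = exp(u), logit = inv_logit(u), identity = u)
}

#' Prior specification for hierarchical fitting
#'
#' For every parameter the hierarchy places a Gaussian hyper-distribution on
#' the unconstrained scale (log for `a` and `tau`, logit for `z0` and `g`,
#' identity for the drift/starting-point slopes, which are per-ms
#' quantities). Each parameter carries a normal prior on the hyper-mean
#' (`mean_loc`, `mean_scale`) and a half-normal prior on the hyper-sd
#' (`sd_scale`). The defaults are weakly informative on the scales implied
#' by durations in ms and evidence-per-second drifts; every fitted object
#' records the priors actually used.
#'
#' @param ... per-parameter overrides, e.g.
#'   `v0 = list(mean_loc = 0, mean_scale = 1)`.
#' @return an object of class `prior_spec`: a named list with elements
#'   `transform`, `mean_loc`, `mean_scale`, `sd_scale` per parameter.
#' @export
prior_spec <- function(...) {
  defaults <- list(
    a   = list(mean_loc = 0,    mean_scale = 1,   sd_scale = 0.5),
    tau = list(mean_loc = -1.5, mean_scale = 1,   sd_scale = 0.5),
    z0  = list(mean_loc = 0,    mean_scale = 1,   sd_scale = 0.5),
    z1  = list(mean_loc = 0,    mean_scale = 0.1, sd_scale = 0.5),
    v0  = list(mean_loc = 0,    mean_scale = 2,   sd_scale = 0.5),
    v1  = list(mean_loc = 0,    mean_scale = 0.1, sd_scale = 0.5),
    v2  = list(mean_loc = 0,    mean_scale = 0.1, sd_scale = 0.5),
    g   = list(mean_loc = 0,    mean_scale = 1,   sd_scale = 0.5))
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown))
    stop_config(paste0("unknown parameter(s) in prior_spec: ",
                       paste(unknown, collapse = ", ")))
  for (p in names(overrides))
    defaults[[p]] <- modifyList(defaults[[p]], overrides[[p]])
  for (p in names(defaults)) defaults[[p]]$transform <- PARAM_TRANSFORMS[[p]]
  structure(defaults, class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat("<prior_spec> hyper-mean ~ normal(loc, scale) on the unconstrained scale;",
      "hyper-sd ~ half-normal(scale)\n")
  for (p in names(x))
    cat(sprintf("  %-3s [%8s]  mean ~ N(%g, %g)   sd ~ halfN(%g)\n",
                p, x[[p]]$transform, x[[p]]$mean_loc, x[[p]]$mean_scale,
                x[[p]]$sd_scale))
  invisible(x)
}

#' Representative group-level parameters for the weighted-stimulus model
#'
#' A plausible group-level parameter set for Model 6 (separate stimulus
#' weights plus a starting-point regression) in auditory duration
#' discrimination around a 500-ms standard: moderate caution, a short
#' non-decision time, a slight bias toward the "second longer" boundary, a
#' small positive influence of the first stimulus on the starting point, and
#' a second-stimulus weight about twice the magnitude of the first (the
#' configuration that produces a negative Type B effect). Used as the
#' default generating condition of the synthetic-cohort tools.
#'
#' @return named list of constrained-scale group means.
#' @export
reference_group_means <- function() {
  list(a = 1.4736, tau = 0.1456, z0 = 0.4411, z1 = 0.0007,
       v0 = 0.0437, v1 = 0.0096, v2 = -0.0198)
}

#' Modest between-participant spreads on the unconstrained scale
#'
#' Companion to [reference_group_means()]: hyper-sds chosen so that
#' individual parameters stay within the range typically reported for
#' duration-discrimination cohorts.
#'
#' @return named list of unconstrained-scale group sds.
#' @export
reference_group_sds <- function() {
  list(a = 0.1, tau = 0.2, z0 = 0.1, z1 = 0.0002,
       v0 = 0.05, v1 = 0.002, v2 = 0.004, g = 0.5)
}

#' Draw a synthetic cohort of individual parameter sets
#'
#' Samples each participant's unconstrained parameters from Gaussians
#' centred at the (transformed) group means with the given unconstrained-
#' scale sds — the generative assumption of the hierarchical model.
#'
#' @param spec a [model_spec()].
#' @param n number of participants (ids `"p01"...`).
#' @param group_means named list of constrained-scale group means covering
#'   [param_names()] of `spec`.
#' @param group_sds named list of unconstrained-scale group sds.
#' @param seed integer seed.
#' @return named list of [individual_parameters()] objects.
#' @export
draw_cohort_parameters <- function(spec, n,
                                   group_means = reference_group_means(),
                                   group_sds = reference_group_sds(),
                                   seed = NULL) {
  pn <- param_names(spec)
  missing_p <- setdiff(pn, names(group_means))
  if (length(missing_p))
    stop_config(paste0("group_means missing: ", paste(missing_p, collapse = ", ")))
  ids <- sprintf("p%02d", seq_len(n))
  draw <- function() {
    out <- list()
    for (id in ids) {
      vals <- sapply(pn, function(p) {
        u <- to_unconstrained(group_means[[p]], p) +
          (group_sds[[p]] %||% 0) * rnorm(1)
        to_constrained(u, p)
      })
      out[[id]] <- do.call(individual_parameters, as.list(vals))
    }
    out
  }
  if (is.null(seed)) draw() else with_seed(derive_seed(seed, "cohort"), draw())
}
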