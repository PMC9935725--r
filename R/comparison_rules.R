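#' Specify one of the seven model variants
#'
#' The model family is indexed by three structural flags: whether the first
#' stimulus representation is replaced by a geometrically updated internal
#' reference, whether the two stimuli carry separate drift weights (a single
#' difference weight otherwise), and whether the starting point is a linear
#' function of the first stimulus/reference. The seven valid flag
#' combinations map bijectively onto model numbers 1-7:
#'
#' | model | internal reference | separate weights | starting-point regression |
#' |-------|--------------------|------------------|---------------------------|
#' | 1     | no                 | no               | no                        |
#' | 2     | yes                | no               | no                        |
#' | 3     | no                 | yes              | no                        |
#' | 4     | yes                | yes              | no                        |
#' | 5     | yes                | no               | yes                       |
#' | 6     | no                 | yes              | yes                       |
#' | 7     | yes                | yes              | yes                       |
#'
#' Either `model` or the three flags may be given; if both are given they are
#' cross-checked.
#'
#' @param model integer 1-7, or `NULL` to use the flags.
#' @param use_internal_reference replace the first stimulus by the internal
#'   reference \eqn{I_n}.
#' @param separate_weights independent drift weights for the two stimuli.
#' @param start_point_regression starting point linear in the first
#'   stimulus/reference.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(model = NULL,
                       use_internal_reference = NULL,
                       separate_weights = NULL,
                       start_point_regression = NULL) {
  flag_table <- data.frame(
    model = 1:7,
    use_internal_reference = c(FALSE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE),
    separate_weights       = c(FALSE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE),
    start_point_regression = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  flags_given <- !is.null(use_internal_reference) || !is.null(separate_weights) ||
    !is.null(start_point_regression)
  if (is.null(model) && !flags_given)
    stop_config("give either model = 1..7 or the three structural flags")
  if (flags_given) {
    f <- c(use_internal_reference %||% FALSE,
           separate_weights %||% FALSE,
           start_point_regression %||% FALSE)
    row <- which(flag_table$use_internal_reference == f[1] &
                 flag_table$separate_weights == f[2] &
                 flag_table$start_point_regression == f[3])
    if (!length(row))
      stop_config("flag combination (no reference, single weight, starting-point regression) is not one of the seven model variants")
    if (!is.null(model) && as.integer(model) != flag_table$model[row])
      stop_config(sprintf("model = %d does not match the given flags (which define model %d)",
                          as.integer(model), flag_table$model[row]))
    model <- flag_table$model[row]
  }
  model <- as.integer(model)
  if (is.na(model) || model < 1 || model > 7)
    stop_config("model must be an integer in 1..7")
  row <- flag_table[flag_table$model == model, ]
  structure(list(model = model,
                 use_internal_reference = row$use_internal_reference,
                 separate_weights = row$separate_weights,
                 start_point_regression = row$start_point_regression),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec> model", x$model,
      "| internal reference:", x$use_internal_reference,
      "| separate weights:", x$separate_weights,
      "| z regression:", x$start_point_regression, "\n")
  invisible(x)
}

#' Names of the free individual-level parameters of a model variant
#' @param spec a [model_spec()].
#' @return character vector in canonical order.
#' @export
param_names <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  c("a", "tau", "z0",
    if (spec$start_point_regression) "z1",
    "v0", "v1",
    if (spec$separate_weights) "v2",
    if (spec$use_internal_reference) "g")
}

#' Number of free individual-level parameters of a model variant
#' @param spec a [model_spec()].
#' @export
n_free_parameters <- function(spec) length(param_names(spec))

#' Individual-level parameter set
#'
#' @param a boundary separation (> 0, evidence units).
#' @param tau non-decision time in seconds (>= 0).
#' @param z0 starting-point intercept, relative units in (0, 1).
#' @param v0 drift intercept (evidence/s).
#' @param v1 drift weight of the first stimulus/reference (evidence/s per ms).
#' @param v2 drift weight of the second stimulus (evidence/s per ms); only
#'   used with separate weights, and fixed at `-v1` otherwise.
#' @param z1 starting-point slope per ms; only used with a starting-point
#'   regression.
#' @param g internal-reference weight in \[0, 1\]; only used with the
#'   internal reference.
#' @return an object of class `individual_parameters`.
#' @export
individual_parameters <- function(a, tau, z0, v0, v1,
                                  v2 = NULL, z1 = NULL, g = NULL) {
  if (a <= 0) stop_domain("boundary separation a must be > 0")
  if (tau < 0) stop_domain("non-decision time tau must be >= 0")
  if (z0 <= 0 || z0 >= 1) stop_domain("starting-point intercept z0 must lie in (0, 1)")
  if (!is.null(g) && (g < 0 || g > 1)) stop_domain("reference weight g must lie in [0, 1]")
  structure(list(a = a, tau = tau, z0 = z0, v0 = v0, v1 = v1,
                 v2 = v2, z1 = z1, g = g),
            class = "individual_parameters")
}

#' Check a parameter set against a model variant
#' @param params an [individual_parameters()] object.
#' @param spec a [model_spec()].
#' @return `params`, invisibly.
#' @export
validate_parameters <- function(params, spec) {
  stopifnot(inherits(params, "individual_parameters"), inherits(spec, "model_spec"))
  if (spec$use_internal_reference && is.null(params$g))
    stop_domain("model uses the internal reference: g is required")
  if (spec$separate_weights && is.null(params$v2))
    stop_domain("model uses separate weights: v2 is required")
  if (spec$start_point_regression && is.null(params$z1))
    stop_domain("model uses a starting-point regression: z1 is required")
  invisible(params)
}

# the single declared conversion point between physical durations and the
# magnitudes entering the model equations: durations in ms, centered on the
# declared standard
center_duration <- function(dur_ms, standard_ms) dur_ms - standard_ms

#' One step of the internal-reference update
#'
#' The internal reference follows a geometrically weighted moving average of
#' first-stimulus representations: `g * I_prev + (1 - g) * X1`. With `g = 0`
#' the reference equals the current first stimulus and the model reduces to
#' the plain difference model; with `g = 1` the reference never moves.
#'
#' @param I_prev previous internal reference (centered ms).
#' @param X1 current first-stimulus magnitude (centered ms).
#' @param g reference weight in \[0, 1\].
#' @return updated reference (centered ms); vectorized over inputs.
#' @export
update_internal_reference <- function(I_prev, X1, g) {
  if (any(g < 0 | g > 1)) stop_domain("reference weight g must lie in [0, 1]")
  g * I_prev + (1 - g) * X1
}

#' Internal-reference trajectory across a session
#'
#' Applies the geometric update along a sequence of first-stimulus
#' magnitudes. The reference is initialized at the first trial's stimulus,
#' `I_1 = X1_1`, so the first trial behaves identically with and without the
#' internal reference.
#'
#' @param X1_sequence first-stimulus magnitudes (centered ms) in
#'   presentation order.
#' @param g reference weight in \[0, 1\].
#' @return numeric vector of references, same length as the input.
#' @export
reference_trajectory <- function(X1_sequence, g) {
  if (!length(X1_sequence)) stop_domain("X1_sequence must be non-empty")
  if (g < 0 || g > 1) stop_domain("reference weight g must lie in [0, 1]")
  x <- c(X1_sequence[1], (1 - g) * X1_sequence[-1])
  as.numeric(filter(x, g, method = "recursive"))
}

#' Trial-level drift rate and starting point
#'
#' Computes the diffusion dynamics of a single trial under a model variant:
#' `v_n = v0 + v1 * (I_n or X1) + v2 * X2` (with `v2 = -v1` for
#' single-weight variants) and `z_n = z0 + z1 * (I_n or X1)` when the
#' starting-point regression is active, `z0` otherwise. Stimulus magnitudes
#' are physical durations centered on the standard.
#'
#' @param spec a [model_spec()].
#' @param params an [individual_parameters()] object valid for `spec`.
#' @param trial a one-row trial data frame (or list) with `dur1_ms`,
#'   `dur2_ms`.
#' @param I_prev internal reference before this trial (centered ms), or
#'   `NULL` on a participant's first trial.
#' @param standard_ms standard duration used for centering.
#' @return list with `v_n` (evidence/s), `z_n` (relative units) and `I_n`
#'   (centered ms; equals the centered first stimulus when the internal
#'   reference is off). A starting point outside (0, 1) raises an
#'   invalid-dynamics error; model fitting treats that state as
#'   log-likelihood `-Inf` rather than an estimate.
#' @export
trial_dynamics <- function(spec, params, trial, I_prev = NULL, standard_ms = 500) {
  validate_parameters(params, spec)
  X1 <- center_duration(trial$dur1_ms, standard_ms)
  X2 <- center_duration(trial$dur2_ms, standard_ms)
  I_n <- if (spec$use_internal_reference && !is.null(I_prev))
    update_internal_reference(I_prev, X1, params$g) else X1
  v2 <- if (spec$separate_weights) params$v2 else -params$v1
  v_n <- params$v0 + params$v1 * I_n + v2 * X2
  z_n <- if (spec$start_point_regression) params$z0 + params$z1 * I_n else params$z0
  if (z_n <= 0 || z_n >= 1)
    dd_stop(sprintf("starting point z_n = %.4f outside (0, 1) on trial with dur1 = %g, dur2 = %g",
                    z_n, trial$dur1_ms, trial$dur2_ms),
            "durddm_invalid_dynamics")
  list(v_n = v_n, z_n = z_n, I_n = I_n)
}

#' Dynamics for an ordered sequence of one participant's trials
#'
#' Threads the internal-reference state across trials in presentation order
#' and returns the per-trial drift rates and starting points. State is never
#' carried across participants or sessions.
#'
#' @param spec a [model_spec()].
#' @param params an [individual_parameters()] object valid for `spec`.
#' @param trials data frame of one participant's trials, ordered by
#'   `trial_index`.
#' @param standard_ms standard duration used for centering.
#' @param strict if `TRUE` (default), a starting point outside (0, 1) raises
#'   an invalid-dynamics error naming the trial; if `FALSE` the offending
#'   values are returned as-is and flagged in the `valid` column, so the
#'   likelihood can assign `-Inf` instead of crashing.
#' @return data frame with columns `v_n`, `z_n`, `I_n`, `valid`, aligned
#'   1:1 with `trials`.
#' @export
dataset_dynamics <- function(spec, params, trials, standard_ms = 500, strict = TRUE) {
  validate_parameters(params, spec)
  if (length(unique(trials$participant_id)) > 1)
    stop_domain("dataset_dynamics expects trials of a single participant")
  if (is.unsorted(trials$trial_index, strictly = TRUE))
    stop_domain("trials must be strictly ordered by trial_index")
  X1 <- center_duration(trials$dur1_ms, standard_ms)
  X2 <- center_duration(trials$dur2_ms, standard_ms)
  I_n <- if (spec$use_internal_reference) reference_trajectory(X1, params$g) else X1
  v2 <- if (spec$separate_weights) params$v2 else -params$v1
  v_n <- params$v0 + params$v1 * I_n + v2 * X2
  z_n <- if (spec$start_point_regression) params$z0 + params$z1 * I_n
         else rep(params$z0, length(X1))
  valid <- z_n > 0 & z_n < 1
  if (strict && !all(valid))
    dd_stop(paste0("starting point outside (0, 1) on trial(s) ",
                   paste(head(trials$trial_index[!valid], 5), collapse = ", ")),
            "durddm_invalid_dynamics")
  data.frame(v_n = v_n, z_n = z_n, I_n = I_n, valid = valid)
}
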