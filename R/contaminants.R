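#' EWMA fast-guess cutoff for one participant
#'
#' Fast guesses are very fast responses at chance accuracy. To locate them,
#' trials with unequal durations (where a correct response is defined as
#' choosing the physically longer stimulus) are sorted by ascending response
#' time and an exponentially weighted moving average of correctness, started
#' at 0.5, is tracked against the upper control limit
#' `0.5 + L * 0.5 * sqrt(lambda / (2 - lambda) * (1 - (1 - lambda)^(2t)))`
#' (Bernoulli(0.5) variance). The cutoff is the response time of the first
#' trial at which the EWMA exceeds the limit and stays above it for the
#' remainder; 0 if it is exceeded from the first trial, and `Inf` (whole
#' session flagged) if the limit is never persistently exceeded.
#'
#' @param trials one participant's trials with responses and RTs.
#' @param lambda EWMA smoothing weight.
#' @param L control-limit width in EWMA standard deviations.
#' @param standard_ms unused in the statistic itself (correctness is defined
#'   from the physical durations); kept for interface symmetry.
#' @return list with `cutoff_s`, `lambda`, `L`, `n_scoreable`, and the
#'   per-trial `rt_s`, `ewma`, `ucl` traces (ascending-RT order).
#' @export
ewma_cutoff <- function(trials, lambda = 0.01, L = 1.5, standard_ms = NULL) {
  scoreable <- !is.na(trials$response) & !is.na(trials$rt_s) &
    trials$dur1_ms != trials$dur2_ms
  tr <- trials[scoreable, , drop = FALSE]
  if (nrow(tr) < 20)
    dd_stop(sprintf("only %d scoreable trials (< 20): cannot run EWMA screening",
                    nrow(tr)), "durddm_insufficient_data")
  ord <- order(tr$rt_s)
  tr <- tr[ord, , drop = FALSE]
  correct <- as.integer((tr$dur1_ms > tr$dur2_ms & tr$response == "first_longer") |
                        (tr$dur2_ms > tr$dur1_ms & tr$response == "second_longer"))
  n <- length(correct)
  ewma <- as.numeric(filter(lambda * correct, 1 - lambda, method = "recursive",
                            init = 0.5))
  t_idx <- seq_len(n)
  ucl <- 0.5 + L * 0.5 * sqrt(lambda / (2 - lambda) * (1 - (1 - lambda)^(2 * t_idx)))
  exceed <- ewma > ucl
  below <- which(!exceed)
  cutoff <- if (!length(below)) 0
            else if (max(below) == n) Inf
            else tr$rt_s[max(below) + 1L]
  list(cutoff_s = cutoff, lambda = lambda, L = L, n_scoreable = n,
       rt_s = tr$rt_s, ewma = ewma, ucl = ucl)
}

#' Screen every participant of a dataset for fast guesses
#'
#' Runs [ewma_cutoff()] per participant and applies the exclusion rule: a
#' participant whose fast guesses (responses faster than their cutoff)
#' exceed 10% of all their responses — equal-duration trials included in the
#' denominator — is marked excluded. The boundary is strict: exactly 10% is
#' retained. Participants with too few scoreable trials are skipped with a
#' warning and never excluded.
#'
#' @param dataset a [dd_dataset()].
#' @param lambda,L EWMA controls, see [ewma_cutoff()].
#' @param fast_threshold exclusion threshold on the fast-guess proportion.
#' @param floor_s absolute response-time floor in seconds; responses faster
#'   than this are counted for removal regardless of the EWMA cutoff.
#' @return a `screening_report` data frame, one row per participant:
#'   `participant_id`, `cutoff_s`, `n_responses`, `n_fast_guesses`,
#'   `prop_fast_guesses`, `excluded`, `n_below_floor`, plus the settings as
#'   attributes.
#' @export
screen_participants <- function(dataset, lambda = 0.01, L = 1.5,
                                fast_threshold = 0.10, floor_s = 0.100) {
  rows <- lapply(participants(dataset), function(pid) {
    tr <- participant_trials(dataset, pid)
    answered <- tr[!is.na(tr$response) & !is.na(tr$rt_s), , drop = FALSE]
    cutoff <- tryCatch(ewma_cutoff(tr, lambda, L)$cutoff_s,
                       durddm_insufficient_data = function(e) {
                         warning(sprintf("participant %s: %s", pid, conditionMessage(e)))
                         NA_real_
                       })
    n_fast <- if (is.na(cutoff)) NA_integer_ else sum(answered$rt_s < cutoff)
    prop <- if (is.na(cutoff)) NA_real_ else n_fast / nrow(answered)
    data.frame(participant_id = pid,
               cutoff_s = cutoff,
               n_responses = nrow(answered),
               n_fast_guesses = n_fast,
               prop_fast_guesses = prop,
               excluded = !is.na(prop) && prop > fast_threshold,
               n_below_floor = sum(answered$rt_s < floor_s),
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  attr(report, "lambda") <- lambda
  attr(report, "L") <- L
  attr(report, "fast_threshold") <- fast_threshold
  attr(report, "floor_s") <- floor_s
  class(report) <- c("screening_report", class(report))
  report
}

#' Apply the screening exclusion rules
#'
#' Drops participants whose fast-guess proportion exceeds the threshold
#' (strictly), then removes remaining responses faster than the absolute
#' floor (100 ms by default). The operation is idempotent on its own output
#' and the clean trial count plus removed count equals the original count.
#'
#' @param dataset a [dd_dataset()].
#' @param report optional precomputed [screen_participants()] report; if
#'   `NULL`, screening is run with the settings below.
#' @inheritParams screen_participants
#' @return list with `dataset` (clean) and `report` (with attributes
#'   `n_participants_dropped`, `n_trials_dropped_with_participants`,
#'   `n_removed_floor`).
#' @export
apply_exclusions <- function(dataset, report = NULL, lambda = 0.01, L = 1.5,
                             fast_threshold = 0.10, floor_s = 0.100) {
  if (is.null(report))
    report <- screen_participants(dataset, lambda, L, fast_threshold, floor_s)
  drop_ids <- report$participant_id[report$excluded %in% TRUE]
  tr <- dataset$trials
  with_part <- tr$participant_id %in% drop_ids
  tr2 <- tr[!with_part, , drop = FALSE]
  fast_floor <- !is.na(tr2$rt_s) & tr2$rt_s < floor_s
  clean <- tr2[!fast_floor, , drop = FALSE]
  attr(report, "n_participants_dropped") <- length(drop_ids)
  attr(report, "n_trials_dropped_with_participants") <- sum(with_part)
  attr(report, "n_removed_floor") <- sum(fast_floor)
  out <- dd_dataset(clean, design = dataset$design,
                    provenance = c(dataset$provenance,
                                   sprintf("screening: dropped %d participant(s), removed %d response(s) below %g s",
                                           length(drop_ids), sum(fast_floor), floor_s)))
  list(dataset = out, report = report)
}

#' Write a screening report as delimited text
#' @param report a [screen_participants()] report.
#' @param path output file.
#' @export
write_screening_report <- function(report, path) {
  write.csv(as.data.frame(report), path, row.names = FALSE, na = "")
  invisible(path)
}
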