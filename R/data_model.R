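#' Canonical trial-table columns
#'
#' Column set of the delimited-text interchange format: one row per
#' two-interval trial.
#' @keywords internal
DATASET_COLUMNS <- c("participant_id", "trial_index", "dur1_ms", "dur2_ms",
                     "order", "response", "rt_s")

ORDER_LEVELS <- c("sc", "cs")
RESPONSE_LEVELS <- c("first_longer", "second_longer")

#' Describe a duration-discrimination experiment design
#'
#' A design for the classical two-interval paradigm: on each trial a standard
#' stimulus of fixed duration and a comparison stimulus of varying duration
#' are presented in order `sc` (standard first) or `cs` (comparison first).
#'
#' @param standard_ms duration of the standard stimulus in ms.
#' @param comparison_levels_ms ordered vector of comparison durations in ms.
#'   Defaults to 9 equally spaced levels spanning 400-600 ms.
#' @param n_trials_per_level_per_order replications of each
#'   (comparison level x order) cell per participant.
#' @param isi_ms inter-stimulus interval in ms (metadata only; it does not
#'   enter any model equation).
#' @param order_scheme `"random_intermixed"` presents both orders in a
#'   seeded pseudo-random sequence; `"blocked_sc"` / `"blocked_cs"` present a
#'   single order throughout.
#' @param seed integer seed controlling trial-sequence permutation.
#' @return an object of class `experiment_design`.
#' @export
experiment_design <- function(standard_ms = 500,
                              comparison_levels_ms = seq(400, 600, length.out = 9),
                              n_trials_per_level_per_order = 10,
                              isi_ms = 1000,
                              order_scheme = c("random_intermixed", "blocked_sc", "blocked_cs"),
                              seed = NULL) {
  order_scheme <- match.arg(order_scheme)
  if (!is.numeric(standard_ms) || length(standard_ms) != 1 || standard_ms <= 0)
    stop_domain("standard_ms must be a single positive duration in ms")
  if (!is.numeric(comparison_levels_ms) || length(comparison_levels_ms) < 1 ||
      any(comparison_levels_ms <= 0))
    stop_domain("comparison_levels_ms must be positive durations in ms")
  n_trials_per_level_per_order <- as.integer(n_trials_per_level_per_order)
  if (is.na(n_trials_per_level_per_order) || n_trials_per_level_per_order < 1)
    stop_domain("n_trials_per_level_per_order must be >= 1")
  structure(
    list(standard_ms = standard_ms,
         comparison_levels_ms = as.numeric(comparison_levels_ms),
         n_trials_per_level_per_order = n_trials_per_level_per_order,
         isi_ms = isi_ms,
         order_scheme = order_scheme,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("<experiment_design>\n")
  cat("  standard:", x$standard_ms, "ms; comparisons:",
      paste(x$comparison_levels_ms, collapse = ", "), "ms\n")
  cat("  ", x$n_trials_per_level_per_order, " trials/cell; ISI ", x$isi_ms,
      " ms; scheme ", x$order_scheme, "\n", sep = "")
  invisible(x)
}

#' Assemble a trial dataset
#'
#' Bundles a trial table with its (optional) design and free-text provenance.
#' Trials are ordered by participant and trial index; all invariants are
#' checked on construction.
#'
#' @param trials data frame with the canonical columns (see
#'   [read_dataset()]); `response`/`rt_s` may be `NA` for design-only rows.
#' @param design optional [experiment_design()] the trials realize.
#' @param provenance character vector of free-text provenance notes.
#' @return an object of class `dd_dataset`.
#' @export
dd_dataset <- function(trials, design = NULL, provenance = character()) {
  trials <- normalize_trials(trials)
  x <- structure(list(trials = trials, design = design,
                      provenance = as.character(provenance)),
                 class = "dd_dataset")
  validate_dataset(x)
  x
}

normalize_trials <- function(trials) {
  if (!is.data.frame(trials))
    stop_validation("trials must be a data frame")
  missing_cols <- setdiff(DATASET_COLUMNS, names(trials))
  if (length(missing_cols))
    stop_config(paste0("missing required columns: ",
                       paste(missing_cols, collapse = ", ")))
  trials <- trials[DATASET_COLUMNS]
  trials$participant_id <- as.character(trials$participant_id)
  trials$trial_index <- as.integer(trials$trial_index)
  trials$dur1_ms <- as.numeric(trials$dur1_ms)
  trials$dur2_ms <- as.numeric(trials$dur2_ms)
  trials$order <- as.character(trials$order)
  trials$response <- as.character(trials$response)
  trials$response[!is.na(trials$response) & trials$response == ""] <- NA_character_
  trials$rt_s <- as.numeric(trials$rt_s)
  ord <- order(trials$participant_id, trials$trial_index)
  trials <- trials[ord, , drop = FALSE]
  rownames(trials) <- NULL
  trials
}

#' Validate a dataset against the trial invariants
#'
#' Checks positive durations, order labels, response labels, positive
#' response times, strictly increasing trial indices within participant and
#' (when a design with a declared standard is present) that the standard
#' occupies the interval implied by the order label.
#'
#' @param x a `dd_dataset`.
#' @return `x`, invisibly; a validation error lists offending rows.
#' @export
validate_dataset <- function(x) {
  tr <- x$trials
  bad <- function(cond, what) {
    idx <- which(cond)
    if (length(idx))
      stop_validation(paste0(what, " (rows ", paste(head(idx, 10), collapse = ", "),
                             if (length(idx) > 10) ", ..." else "", ")"))
  }
  bad(is.na(tr$participant_id) | tr$participant_id == "", "missing participant_id")
  bad(is.na(tr$trial_index) | tr$trial_index < 1, "trial_index must be an integer >= 1")
  bad(is.na(tr$dur1_ms) | tr$dur1_ms <= 0, "dur1_ms must be > 0")
  bad(is.na(tr$dur2_ms) | tr$dur2_ms <= 0, "dur2_ms must be > 0")
  bad(is.na(tr$order) | !(tr$order %in% ORDER_LEVELS),
      "order must be 'sc' or 'cs'")
  bad(!is.na(tr$response) & !(tr$response %in% RESPONSE_LEVELS),
      "response must be 'first_longer' or 'second_longer'")
  bad(!is.na(tr$response) & is.na(tr$rt_s), "rt_s missing for answered trial")
  bad(!is.na(tr$rt_s) & tr$rt_s <= 0, "rt_s must be > 0")
  for (pid in unique(tr$participant_id)) {
    ti <- tr$trial_index[tr$participant_id == pid]
    if (any(diff(ti) <= 0))
      stop_validation(paste0("trial_index not strictly increasing for participant ", pid))
  }
  if (!is.null(x$design)) {
    std <- x$design$standard_ms
    std1 <- tr$order == "sc" & tr$dur1_ms != std
    std2 <- tr$order == "cs" & tr$dur2_ms != std
    bad(std1 | std2,
        "standard duration must be first on 'sc' and second on 'cs' trials")
  }
  invisible(x)
}

#' @export
print.dd_dataset <- function(x, ...) {
  tr <- x$trials
  cat("<dd_dataset> ", nrow(tr), " trials, ",
      length(unique(tr$participant_id)), " participant(s), ",
      sum(!is.na(tr$response)), " answered\n", sep = "")
  if (!is.null(x$design)) print(x$design)
  if (length(x$provenance)) cat("  provenance:", paste(x$provenance, collapse = "; "), "\n")
  invisible(x)
}

#' Number of trials in a dataset
#' @param x a `dd_dataset`.
#' @export
n_trials <- function(x) nrow(x$trials)

#' Participant identifiers of a dataset
#' @param x a `dd_dataset`.
#' @export
participants <- function(x) unique(x$trials$participant_id)

#' Extract one participant's trials
#' @param x a `dd_dataset`.
#' @param id participant identifier.
#' @return data frame of that participant's trials in presentation order.
#' @export
participant_trials <- function(x, id) {
  tr <- x$trials[x$trials$participant_id == id, , drop = FALSE]
  if (!nrow(tr)) stop_domain(paste0("unknown participant: ", id))
  rownames(tr) <- NULL
  tr
}

#' Read a trial dataset from delimited text
#'
#' Reads a comma-separated UTF-8 file with a header row. The canonical
#' columns are `participant_id, trial_index, dur1_ms, dur2_ms, order,
#' response, rt_s`; foreign headers can be ingested through `dialect`, a
#' named character vector mapping canonical names to the file's column names
#' (e.g. `c(rt_s = "RT")`). Missing values are empty fields. Rows failing
#' numeric coercion are reported with their file line numbers.
#'
#' @param path file to read.
#' @param dialect optional named character vector, canonical -> file column.
#' @param design optional [experiment_design()] to attach and validate
#'   against.
#' @return a [dd_dataset()].
#' @export
read_dataset <- function(path, dialect = NULL, design = NULL) {
  if (!file.exists(path)) stop_config(paste0("file not found: ", path))
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                  na.strings = "", fileEncoding = "UTF-8")
  if (!is.null(dialect)) {
    if (is.null(names(dialect)) || !all(names(dialect) %in% DATASET_COLUMNS))
      stop_config("dialect must be a named vector mapping canonical column names")
    for (canon in names(dialect)) {
      file_col <- dialect[[canon]]
      if (!file_col %in% names(raw))
        stop_config(paste0("mapped column '", file_col, "' not present in file"))
      names(raw)[names(raw) == file_col] <- canon
    }
  }
  missing_cols <- setdiff(DATASET_COLUMNS, names(raw))
  if (length(missing_cols))
    stop_config(paste0("missing required columns: ",
                       paste(missing_cols, collapse = ", ")))
  # numeric coercion with line-number reporting (line 1 is the header)
  for (col in c("trial_index", "dur1_ms", "dur2_ms", "rt_s")) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    failed <- which(!is.na(raw[[col]]) & is.na(vals))
    if (length(failed))
      stop_validation(paste0("column ", col, " not numeric at line(s) ",
                             paste(failed + 1L, collapse = ", ")))
    raw[[col]] <- vals
  }
  dd_dataset(raw, design = design,
             provenance = paste0("read from ", path))
}

#' Write a trial dataset as delimited text
#'
#' Writes the canonical comma-separated format with a header row, rows
#' ordered by (participant, trial_index), missing values as empty fields.
#' `write_dataset` followed by [read_dataset()] reproduces the dataset
#' field-by-field.
#'
#' @param dataset a [dd_dataset()].
#' @param path output file.
#' @export
write_dataset <- function(dataset, path) {
  validate_dataset(dataset)
  con <- tryCatch(file(path, "w", encoding = "UTF-8"),
                  error = function(e) stop_config(paste0("cannot write: ", path)))
  on.exit(close(con))
  write.csv(dataset$trials, con, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Generate the trial skeleton of a design
#'
#' Expands a design into a response-free trial table. Under the
#' `random_intermixed` scheme every (comparison level x order) cell appears
#' exactly `n_trials_per_level_per_order` times per participant in a seeded
#' pseudo-random permutation; blocked schemes use a single order. The first
#' and second durations are assigned from the standard and comparison
#' according to the order label.
#'
#' @param design an [experiment_design()].
#' @param participants participant identifiers (character vector), or a
#'   single integer n for ids `"p01"..."pn"`.
#' @return a [dd_dataset()] with `response`/`rt_s` missing.
#' @export
generate_design_trials <- function(design, participants = 1L) {
  stopifnot(inherits(design, "experiment_design"))
  if (is.numeric(participants) && length(participants) == 1)
    participants <- sprintf("p%02d", seq_len(participants))
  orders <- switch(design$order_scheme,
                   random_intermixed = ORDER_LEVELS,
                   blocked_sc = "sc",
                   blocked_cs = "cs")
  cells <- expand.grid(comparison_ms = design$comparison_levels_ms,
                       order = orders,
                       rep = seq_len(design$n_trials_per_level_per_order),
                       stringsAsFactors = FALSE)
  build <- function(pid) {
    idx <- if (design$order_scheme == "random_intermixed")
      sample.int(nrow(cells)) else seq_len(nrow(cells))
    c2 <- cells[idx, , drop = FALSE]
    data.frame(participant_id = pid,
               trial_index = seq_len(nrow(c2)),
               dur1_ms = ifelse(c2$order == "sc", design$standard_ms, c2$comparison_ms),
               dur2_ms = ifelse(c2$order == "sc", c2$comparison_ms, design$standard_ms),
               order = c2$order,
               response = NA_character_,
               rt_s = NA_real_,
               stringsAsFactors = FALSE)
  }
  trials <- with_seed(design$seed,
                      do.call(rbind, lapply(participants, build)))
  dd_dataset(trials, design = design,
             provenance = "generated from experiment_design")
}

#' Comparison duration and comparison-coded response of each trial
#'
#' Helper used by psychometric and posterior-predictive summaries: the
#' comparison duration is the non-standard interval implied by the order
#' label, and `comparison_longer` recodes the response as 1 when the
#' comparison was judged longer.
#'
#' @param trials canonical trial data frame.
#' @return `trials` with `comparison_ms` and `comparison_longer` columns.
#' @export
annotate_comparison <- function(trials) {
  trials$comparison_ms <- ifelse(trials$order == "sc", trials$dur2_ms, trials$dur1_ms)
  trials$comparison_longer <- ifelse(
    is.na(trials$response), NA_integer_,
    as.integer((trials$order == "sc" & trials$response == "second_longer") |
               (trials$order == "cs" & trials$response == "first_longer")))
  trials
}
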