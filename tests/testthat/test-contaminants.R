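# constructed sessions with a known fast-guess structure
make_session <- function(n_fast = 0, n_good = 200, p_fast_correct = 0.5,
                         p_good_correct = 0.9, fast_range = c(0.10, 0.25),
                         good_range = c(0.30, 0.70), seed = 1,
                         participant = "p01") {
  set.seed(seed)
  n <- n_fast + n_good
  dur2 <- sample(c(450, 475, 525, 550), n, TRUE)
  rt <- c(runif(n_fast, fast_range[1], fast_range[2]),
          runif(n_good, good_range[1], good_range[2]))
  correct <- c(rbinom(n_fast, 1, p_fast_correct),
               rbinom(n_good, 1, p_good_correct))
  longer_first <- 500 > dur2
  response <- ifelse(correct == 1,
                     ifelse(longer_first, "first_longer", "second_longer"),
                     ifelse(longer_first, "second_longer", "first_longer"))
  dd_dataset(data.frame(participant_id = participant, trial_index = seq_len(n),
                        dur1_ms = 500, dur2_ms = dur2, order = "sc",
                        response = response, rt_s = rt))
}

test_that("accurate slow sessions are essentially unflagged", {
  ds <- make_session(n_fast = 0, n_good = 400, p_good_correct = 1,
                     good_range = c(0.4, 0.9), seed = 2)
  cut <- ewma_cutoff(participant_trials(ds, "p01"))
  # the EWMA needs a handful of correct trials to clear the control limit,
  # so a few of the fastest (still correct) responses may sit below the
  # cutoff — but only a negligible fraction, and nobody is excluded
  rep <- screen_participants(ds)
  expect_false(rep$excluded)
  expect_lt(rep$prop_fast_guesses, 0.05)
  expect_lt(cut$cutoff_s, quantile(ds$trials$rt_s, 0.05))
})

test_that("chance-level sessions are flagged wholesale", {
  set.seed(3)
  n <- 200
  dur2 <- sample(c(450, 550), n, TRUE)
  correct <- rep(c(1, 0), n / 2)   # alternating: EWMA pinned at 0.5
  longer_first <- 500 > dur2
  response <- ifelse(correct == 1,
                     ifelse(longer_first, "first_longer", "second_longer"),
                     ifelse(longer_first, "second_longer", "first_longer"))
  ds <- dd_dataset(data.frame(participant_id = "p01", trial_index = 1:n,
                              dur1_ms = 500, dur2_ms = dur2, order = "sc",
                              response = response, rt_s = runif(n, 0.2, 1)))
  cut <- ewma_cutoff(participant_trials(ds, "p01"))
  expect_identical(cut$cutoff_s, Inf)
  rep <- screen_participants(ds)
  expect_equal(rep$prop_fast_guesses, 1)
  expect_true(rep$excluded)
})

test_that("a fast-guess region is located near the accuracy transition", {
  hits <- vapply(1:5, function(s) {
    ds <- make_session(n_fast = 150, n_good = 850, fast_range = c(0.10, 0.25),
                       good_range = c(0.30, 0.70), seed = 100 + s)
    cut <- ewma_cutoff(participant_trials(ds, "p01"))$cutoff_s
    cut >= 0.20 && cut <= 0.32
  }, NA)
  expect_gte(sum(hits), 4)
})

test_that("too few scoreable trials is an explicit error", {
  ds <- make_session(n_good = 30, seed = 4)
  tr <- participant_trials(ds, "p01")
  tr$dur2_ms <- 500   # equal durations: nothing scoreable
  expect_error(ewma_cutoff(tr), class = "durddm_insufficient_data")
})

test_that("exclusion rules drop the right participants and responses", {
  clean <- make_session(n_fast = 0, n_good = 300, p_good_correct = 0.95,
                        good_range = c(0.35, 0.8), seed = 5, participant = "good")
  # ~15% fast guesses at chance
  noisy <- make_session(n_fast = 52, n_good = 300, seed = 6, participant = "fast")
  both <- dd_dataset(rbind(clean$trials, noisy$trials))
  res <- apply_exclusions(both)
  expect_true("good" %in% participants(res$dataset))
  expect_false("fast" %in% participants(res$dataset))
  expect_equal(n_trials(res$dataset) +
                 attr(res$report, "n_trials_dropped_with_participants") +
                 attr(res$report, "n_removed_floor"),
               n_trials(both))
  # idempotent on its own output
  res2 <- apply_exclusions(res$dataset)
  expect_equal(res2$dataset$trials, res$dataset$trials)
})

test_that("the 10 percent rule is strict and the 100 ms floor applies", {
  # construct a session where the EWMA cutoff cleanly separates a fast
  # block at exactly 10% of all responses
  ds <- make_session(n_fast = 40, n_good = 360, fast_range = c(0.11, 0.2),
                     good_range = c(0.4, 0.8), p_good_correct = 0.97, seed = 7)
  rep <- screen_participants(ds)
  expect_gt(rep$prop_fast_guesses, 0)
  # exclusion is strictly-greater-than: at a threshold equal to the observed
  # proportion the participant is retained, just below it they are dropped
  at <- screen_participants(ds, fast_threshold = rep$prop_fast_guesses)
  expect_false(at$excluded)
  below <- screen_participants(ds, fast_threshold = rep$prop_fast_guesses - 1e-9)
  expect_true(below$excluded)

  # sub-100 ms responses are removed even for retained participants
  tr <- make_session(n_fast = 0, n_good = 300, p_good_correct = 0.95,
                     good_range = c(0.35, 0.8), seed = 8)$trials
  tr$rt_s[1:3] <- c(0.05, 0.08, 0.09)
  tr <- tr[order(tr$trial_index), ]
  ds2 <- dd_dataset(tr)
  res <- apply_exclusions(ds2)
  expect_equal(attr(res$report, "n_removed_floor"), 3)
  expect_true(all(res$dataset$trials$rt_s >= 0.1))
})
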