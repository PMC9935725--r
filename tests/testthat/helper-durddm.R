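# shared builders for the test suite; everything is generated in code

small_design <- function(reps = 3, seed = 1) {
  experiment_design(n_trials_per_level_per_order = reps, seed = seed)
}

# deterministic response fill-in for I/O tests that do not need a diffusion
fill_responses <- function(dataset, seed = 1) {
  tr <- dataset$trials
  set.seed(seed)
  tr$response <- sample(c("first_longer", "second_longer"), nrow(tr), TRUE)
  tr$rt_s <- round(runif(nrow(tr), 0.3, 1.5), 4)
  dd_dataset(tr, design = dataset$design, provenance = dataset$provenance)
}

model1_params <- function() {
  individual_parameters(a = 1.5, tau = 0.15, z0 = 0.45, v0 = 0.05, v1 = 0.012)
}

model6_params <- function() {
  individual_parameters(a = 1.4736, tau = 0.1456, z0 = 0.4411, z1 = 0.0007,
                        v0 = 0.0437, v1 = 0.0096, v2 = -0.0198)
}

# memoized small hierarchical fit shared by downstream-module tests
.fit_cache <- new.env(parent = emptyenv())
cached_small_fit <- function() {
  if (is.null(.fit_cache$fit)) {
    spec <- model_spec(1)
    params <- draw_cohort_parameters(
      spec, 3,
      group_means = list(a = 1.5, tau = 0.15, z0 = 0.45, v0 = 0.05, v1 = 0.012),
      group_sds = list(a = 0.1, tau = 0.1, z0 = 0.1, v0 = 0.03, v1 = 0.002),
      seed = 5)
    ds <- simulate_experiment(small_design(reps = 3, seed = 2), spec, params,
                              seed = 9, dt = 5e-4)
    .fit_cache$fit <- fit_hddm(spec, ds, n_chains = 2, n_iter = 400, seed = 3)
  }
  .fit_cache$fit
}
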