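# durddm

Diffusion decision models for two-interval duration discrimination.

In the classical paradigm an observer hears (or sees) a standard stimulus
of fixed duration — 500 ms here — and a comparison of varying duration
(400–600 ms), in either order, and judges which interval was longer.
Performance shows two well-known context effects: the presentation order
shifts the point of subjective equality (**Type A** effect / time-order
error) and changes the difference limen (**Type B** effect; the classical
"negative" direction means discrimination is better when the standard
comes first). Both implicate stimulus history: the percept of the first
interval is blended with a memory of previous trials.

`durddm` embeds the two standard accounts of that blending — an
**internal reference** updated trial by trial,
`I_n = g·I_{n−1} + (1−g)·X_{1,n}`, and **sensation weighting**, separate
drift weights for the two intervals — inside a diffusion decision model,
so that choices *and* full response-time distributions are modeled
jointly. Trial-level drift and starting point are

    v_n = v0 + v1·(X_{1,n} or I_n) + v2·X_{2,n}
    z_n = z0 + z1·(X_{1,n} or I_n)          (optional)

with stimulus magnitudes in ms centered on the standard and a Wiener
first-passage likelihood (diffusion coefficient fixed at 1). Crossing the
mechanisms gives seven nested variants (`model_spec(1)`–`model_spec(7)`,
5–8 free parameters each).

The package covers the full analysis pipeline around this model family:

* synthetic experiment generation (`experiment_design()`,
  `simulate_experiment()`), delimited-text I/O (`read_dataset()`,
  `write_dataset()`);
* EWMA fast-guess screening with the 10%-exclusion and 100-ms rules
  (`screen_participants()`, `apply_exclusions()`);
* hierarchical Bayesian estimation with an adaptive MCMC backend,
  split-R-hat convergence checking and reproducible run-until-converged
  extensions (`fit_hddm()`, `rhat()`, `hdi()`, `posterior_mode()`);
* Pareto-smoothed importance-sampling approximate leave-one-out model
  comparison (`pointwise_loglik()`, `psis_loo()`, `elpd_compare()`);
* per-participant psychometric functions with PSE/DL and Type A / Type B
  context effects (`fit_psychometric()`, `context_effects()`,
  `effects_table()`);
* posterior predictive checks of choice proportions and RT quantiles
  (`posterior_predictive_datasets()`, `ppc_summary()`);
* a YAML-configured pipeline (`cmd_simulate()` … `cmd_ppc()`) with a thin
  Rscript dispatcher in `inst/cli/durddm.R`.

See the methods vignette
(`vignettes/duration-discrimination-ddm.Rmd`) for the model, priors,
sampler and design decisions.

## Worked example

Simulate a small cohort from the weighted-stimulus variant with a
starting-point regression (Model 6), fit it, and look at the group level:

```r
library(durddm)

spec   <- model_spec(6)
design <- experiment_design(n_trials_per_level_per_order = 10)   # 180 trials
cohort <- draw_cohort_parameters(spec, 6, seed = 101)
data   <- simulate_experiment(design, spec, cohort, seed = 202)

fit <- fit_hddm(spec, data, n_chains = 4, n_iter = 2000, seed = 7)
fit
#> <ddm_fit> model 6 | 6 participant(s) | 4 chains x 1000 kept draws
#>   converged: TRUE | max R-hat: 1.0079 | mean acceptance: 0.456
group_summary(fit)
#>   parameter         mode         lower        upper
#> 1         a  1.464463827  1.2498284795  1.688084619
#> 2       tau  0.133855638  0.1041583485  0.176837248
#> 3        z0  0.454461273  0.4101871550  0.487228887
#> 4        z1  0.000898465  0.0003859882  0.001400296
#> 5        v0  0.038680356 -0.1358415044  0.197902961
#> 6        v1  0.008374871  0.0042034975  0.012290336
#> 7        v2 -0.020538847 -0.0323711394 -0.011559129
```

The mode/HDI columns are the group-level posterior summaries on each
parameter's natural scale: boundary separation `a` (response caution),
non-decision time `tau` in seconds, starting-point intercept `z0` (below
0.5 = a-priori bias toward "second longer"), per-ms starting-point slope
`z1`, drift intercept `v0` and the per-ms stimulus weights `v1`, `v2`.
Here `|v2| ≈ 2·v1`: the second interval weighs about twice the first,
which is exactly the configuration that produces the classical negative
Type B effect:

```r
eff <- effects_table(data)
median(eff$type_b)
#> [1] -22.1108
```

Negative `type_b = dl_sc − dl_cs` means discrimination is better when the
standard precedes the comparison.

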