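---
title: "Modeling duration discrimination with trial-level diffusion dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling duration discrimination with trial-level diffusion dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(durddm)
```

## The problem

In a two-interval duration-discrimination task a standard stimulus of fixed
duration (here 500 ms) and a comparison stimulus of varying duration
(400-600 ms) are presented one after the other, and the observer judges
which interval was longer. Performance in this task shows two classical
context effects. The *Type A effect* (time-order error) is a shift of the
point of subjective equality (PSE) with presentation order; the *Type B
effect* is an order-dependent change of the difference limen (DL), with the
classical "negative" direction meaning better discrimination when the
standard comes first. Both effects implicate stimulus history: the percept
of the first interval is blended with a memory trace of previous trials.

`durddm` embeds two accounts of that blending inside a diffusion decision
model (DDM), so that both choices and full response-time distributions are
modeled:

* the **internal reference** account: the effective first-interval
  magnitude on trial $n$ is a geometrically updated reference
  $I_n = g\,I_{n-1} + (1-g)\,X_{1,n}$ with weight $g \in [0,1]$; $g = 0$
  recovers the plain difference model;
* the **sensation weighting** account: the two intervals carry separate
  weights in the drift regression, absorbed here as
  $v_n = v_0 + v_1 X_{1,n} + v_2 X_{2,n}$ (reference levels and bias of the
  original formulation are absorbed into the intercept $v_0$, which is why
  they do not appear as free quantities anywhere in the package).

Crossing these mechanisms with an optional starting-point regression
$z_n = z_0 + z_1 (X_{1,n}\ \text{or}\ I_n)$ yields seven nested variants
(`model_spec(1)` ... `model_spec(7)`; see `?model_spec` for the table),
with 5, 6, 6, 7, 7, 7 and 8 free individual-level parameters.

Stimulus magnitudes entering all equations are physical durations in ms
centered on the standard, so `dur = 600` at a 500-ms standard enters as
+100. Drifts are in evidence per second with the **diffusion coefficient
fixed at 1**; the alternative 0.1 convention, which also circulates,
silently rescales boundary separation, drifts and the starting-point slope.
The per-ms slopes this implies are the natural scale for the defaults
below.

## Trial-level likelihood

Each trial contributes the defective first-passage-time density of a Wiener
process with boundary separation $a$, drift $v_n$, relative start $z_n$ and
non-decision time $\tau$; the upper boundary is mapped to the "first
interval longer" response. The density is evaluated by the standard
small-time/large-time series with automatic switching; the truncation
tolerance is `eps = 1e-7` in density units (configurable). A starting point
that leaves $(0,1)$ is not clipped: it signals a $-\infty$ log-likelihood
so that samplers and optimizers steer away — clipping would silently
distort the posterior. The same applies to response times at or below
$\tau$.

The stochastic simulator is an Euler–Maruyama scheme (`dt = 1e-4` s by
default) with a Brownian-bridge correction for boundary crossings inside a
step; without the correction, first-passage times carry an
$O(\sqrt{dt})\approx 6$ ms late bias that is visible against the analytic
density at the package's own tolerance. Non-absorbed paths (cap 30 s) are
censored, dropped with a warning and counted in the dataset's provenance.

## Internal-reference initialization

On a participant's first trial the reference is initialized at that trial's
first-stimulus magnitude, $I_1 = X_{1,1}$. This makes trial 1 identical
under reference and non-reference variants and avoids an extra free
parameter; initializing at the standard (i.e. centered 0) or estimating the
start would be alternatives, but with hundreds of trials per session the
influence of the initialization decays geometrically and is negligible.
Reference state is never carried across participants or sessions.

## Hierarchical model and priors

Each parameter gets a Gaussian hyper-distribution on an unconstrained
scale: $\log a$, $\log\tau$, $\mathrm{logit}\,z_0$, $\mathrm{logit}\,g$,
identity for $v_0, v_1, v_2, z_1$. Default hyper-mean priors are
normal(0, 1) on $\log a$, normal(−1.5, 1) on $\log\tau$, normal(0, 1) on
the logits, normal(0, 2) on $v_0$ and normal(0, 0.1) on the per-ms slopes;
hyper-sds are half-normal(0.5). These are weakly informative on the scales
implied by ms-centered stimuli and second-valued RTs; they are
configuration (`prior_spec()`), not constants, and every fit records the
priors used.

### Sampler

`fit_hddm()` uses an adaptive Metropolis-within-Gibbs scheme built from
moves chosen for this posterior's geometry:

* componentwise random-walk updates of each participant's unconstrained
  parameters, switching after covariance learning to sweeps along the
  Cholesky directions of each participant's posterior covariance;
* repeated joint proposals from that covariance (the boundary/non-decision
  and bias trade-offs defeat axis-aligned moves alone);
* exact conjugate Gibbs draws of Gaussian hyper-means and slice sampling of
  hyper-sds;
* *collapsed* updates of the drift-weight block: the drift enters the
  Wiener density only through $\exp(c_n v_n - v_n^2 t_n/2)$, so
  $(v_0, v_1, v_2)$ are conditionally Gaussian given the other parameters.
  Their hyper-means and hyper-sds are slice-sampled from the marginal with
  the weights integrated out in closed form, and the weights are then
  redrawn exactly — this removes both the autocorrelation and the funnel
  of the drift family entirely;
* non-centered group moves for the remaining parameters: rescaling all
  deviations together with their hyper-sd (the funnel direction), periodic
  slice versions of the same move, and multivariate translations of all
  participants with the hyper-means along the learned hyper-mean
  covariance.

Initialization starts every chain near a pilot posterior mode found by a
short per-participant Nelder–Mead search, with bounded retries to a finite
density. Defaults mirror common practice for this model family: 4 chains,
2000 iterations, the first 50% discarded as warm-up. Convergence is judged
by split R-hat; a fit is marked converged only when every recorded
parameter is below 1.01. If the initial schedule misses that bar, chains
are *resumed* — adaptation frozen, RNG streams continued — in blocks of the
post-warmup length, up to `max_extensions` times. That is the ordinary
run-until-converged practice made reproducible: the same seed always yields
the same draws. Iteration counts are not comparable across MCMC backends;
the convergence contract, not a particular iteration count, is the
normative quantity, and this backend typically needs one or two extensions
of the 4 × 2000 schedule at the reference problem size below.

The sampler operates on unconstrained scales throughout, where the
hierarchy's Gaussians live; no Jacobian terms are needed for the
individual-level terms because the priors are *defined* on that scale.

## Screening for fast guesses

Fast guesses are very fast responses at chance accuracy. Trials with
unequal durations are sorted by ascending RT and an exponentially weighted
moving average of correctness, initialized at 0.5, is compared with the
control limit $0.5 + L \cdot 0.5\sqrt{\lambda/(2-\lambda)\,
(1-(1-\lambda)^{2t})}$. The cutoff is the RT of the first trial from which
the EWMA stays above the limit; participants whose below-cutoff responses
exceed 10% of *all* their responses (equal-duration trials included in the
denominator, strictly greater than) are excluded, and any remaining
response faster than 100 ms is removed. The smoothing weight
$\lambda = 0.01$ and limit width $L = 1.5$ are conventional values in the
RT-modeling literature; both are configuration keys recorded in every
screening report. One consequence of the EWMA's warm-in worth knowing: even
a fully accurate session needs on the order of a dozen trials before the
statistic clears the limit, so the fastest few *correct* responses always
sit below the cutoff. For realistic session lengths (several hundred
trials) that is a negligible fraction; for very short sessions the
proportion rule would bite, which is why the pipeline exposes a screening
bypass and the package's own short-session examples use it.

## Psychometrics and context effects

Per participant, the probability of judging the comparison longer is
fitted by a logistic regression on the centered comparison duration, the
stimulus order and their interaction (`fit_psychometric()`); maximum
likelihood is the default because it is deterministic, and a MAP variant
under weak normal priors serves both as the Bayesian option and as the
fallback under complete separation (the two agree in the large-data
limit). Derived quantities, per order $o$:

* PSE$_o$ = standard − $\beta_{0,o}/\beta_o$ (50% point),
* DL$_o$ = $\log 3 / \beta_o$ (half the 25-75% spread),
* Type A = PSE$_{sc}$ − PSE$_{cs}$, Type B = DL$_{sc}$ − DL$_{cs}$.

The sign conventions are fixed package-wide and printed in every exported
effects table; negative Type B is the classical direction. The
proportional weight difference is computed on weight *magnitudes*,
$(w_1 - w_2)/(w_1 + w_2)$ with $w_1 = v_1$ and $w_2 = -v_2$, because the
second-stimulus weight enters the drift regression subtractively (fitted
$v_2$ is negative); the raw-coefficient alternative is near-degenerate in
its denominator and was rejected.

## Posterior prediction

`posterior_predictive_datasets()` draws parameter sets uniformly without
replacement from the post-warmup posterior (500 by default), simulates each
on the fitted trial skeleton preserving participant structure, and
`ppc_summary()` compares per (comparison level × order) cell the replicate
distribution of choice probabilities and pooled RT quantiles
(10/30/50/70/90%) with the empirical statistics, using 95% highest-density
intervals. Per-participant summaries are available behind a flag.

## The synthetic-experiment generator

`experiment_design()` + `simulate_experiment()` emulate the paradigm the
package targets: 500-ms standard, comparison levels defaulting to 9 equally
spaced values over 400-600 ms, randomly intermixed or blocked orders, a
1000-ms inter-stimulus interval carried as metadata. The exact level grid
and per-cell trial counts of any given experiment are configuration, never
hard-coded. `reference_group_means()` provides a representative Model-6
group-level parameter set for auditory duration discrimination at this
standard (moderate caution $a \approx 1.47$, short non-decision time
$\approx 0.15$ s, slight bias toward "second longer", a second-stimulus
weight about twice the first — the configuration that yields a negative
Type B effect), and `reference_group_sds()` adds modest between-participant
spread on the unconstrained scale. What the generator does *not* emulate:
sequential dependencies beyond the internal reference (e.g. post-error
slowing), lapses/contaminants unless constructed explicitly, session or
fatigue effects, and the asymmetric RT patterns that real observers show
when the first interval is clearly the longer one. Passing recovery and
calibration checks on generated data therefore demonstrates internal
consistency of the estimation machinery, not adequacy for any particular
real dataset.

## Problem sizes used by the test suite and acceptance script

The package's own checks run at sizes chosen to exercise the claims at the
reference study conditions: simulator-vs-density agreement over a 27-point
parameter grid at $10^5$ trials each; reduction identities on a 504-trial
session; one hierarchical recovery replicate at 21 participants × 360
trials with the 4 × 2000 schedule plus extensions; exact-vs-approximate
leave-one-out on a 40-trial single-participant fit with 40 brute-force
refits; model selection over five seeded 6-participant cohorts; context
effects from a 21-participant × 720-trial heterogeneous cohort; screening
over 100 replicate 1000-trial sessions. Where a claim is distributional
(majorities across seeds), the number of seeds is the package's choice and
is stated in the test itself.

## Known limitations

* No inter-trial variability parameters (the "full" diffusion model's
  drift/start/non-decision variabilities) — deliberately out of scope.
* The likelihood treats response times measured from second-stimulus
  offset at face value; anticipatory decisions during the second interval
  (suggested by implausibly small fitted non-decision times in this
  paradigm) are not modeled.
* Single session per participant; no roving-standard designs.
* The sampler's convergence contract is checked by split R-hat only; no
  rank-normalized or ESS-based diagnostics are exposed.
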