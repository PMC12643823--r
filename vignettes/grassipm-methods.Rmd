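---
title: "Methods: the integrated population model, its derived analyses, and the synthetic study"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the integrated population model, its derived analyses, and the synthetic study}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the science it implements:
the joint model, the conventions behind every derived quantity, the design
choices that were genuinely open, and what the synthetic study does and
does not establish.

## The joint model

Three datasets from one intensively monitored breeding population are
fitted under a single latent demographic process.

**State process.** Two sexes, three stages. Writing `N_{s,t}` for the
adults of sex `s` present in season `t`:

```
S_{s,t} ~ Binomial(N_{s,t-1}, phi_a,s,t)                    surviving adults
R_{s,t} ~ Poisson(N_{f,t-1} * F_{t-1} * 1/2 * phi_j,s,t)    local recruits
I_{s,t} ~ DiscreteUniform(0, 175)                           immigrants
N_{s,t} = S_{s,t} + R_{s,t} + I_{s,t}
```

Binomial and Poisson draws carry demographic stochasticity. The `1/2` is
the offspring sex ratio: fecundity `F` is offspring per female, and each
offspring is male or female with equal probability. The recurrence is
sex-structured because the sensitivity analysis reports sex-specific
contributions; with symmetric sexes it collapses to the familiar scalar
form `N_t = I_t + N_{t-1} phi_a,t + N_{t-1} F_{t-1} phi_j,t / 2` whose
constant-rate growth factor is `phi_a + F phi_j / 2` (a closed form the
test suite checks against long-run dynamics).

**Counts.** `y_t ~ Poisson(N_{m,t} + N_{f,t})`, the standard state-space
observation choice for unique-individuals counts. The count is an index:
detection is not modelled at the count level, so the latent `N` tracks the
scale of the counts, not a detection-corrected census. This matters for
interpretation, not for the vital rates, which are identified by the
capture histories.

**Capture histories.** Sex- and age-structured Cormack–Jolly–Seber model,
conditional on first capture, fitted through m-arrays (one per sex for
juvenile first-releases, one per sex for adult releases; a
juvenile-marked bird moves to its sex's adult array after its first
recapture). A design question with no single textbook answer: when is a
juvenile-marked bird detected at the "juvenile" rate? Conditional on
first capture, such a bird is next detectable one year later, when it is
biologically an adult. Because the study design gives juveniles distinct
recapture priors, we apply the juvenile recapture probability to the
*first occasion after juvenile marking* and the sex's adult probability
thereafter; survival is the juvenile rate over the first interval, adult
rates after. This keeps the juvenile recapture parameter identified (it
is the detection rate of returning first-year birds) and is implemented
identically in the R likelihood (`cjs_log_likelihood()`,
`expand_cjs_rates()`) and in the JAGS model; tests verify the m-array
cell probabilities against exhaustive enumeration of latent fates.

**Productivity.** `J_t ~ Poisson(B_t F_t / k)` with `B_t` the annual
census of nesting females and `J_t` the juveniles actually recorded. `k`,
uniform on `[1, 3]`, absorbs the undercount of juveniles (only a fraction
`1/k` of each cohort is found); it is a single scalar because one
detection regime spans the study. Note `F` and `k` enter productivity
only through `F/k`: they are separated *only* because `F` also drives the
recruit term of the state process, so the count likelihood calibrates
`k`. The test suite checks exactly this: `F/k` tracks the observed
juvenile yield per female, and the `F`–`k` split is recovered on
synthetic data where the truth is known. For this to work `B_t` must
track the female population (the field protocol tallies nesting females
whether or not individually identified); substituting the sparse
female *resight* count for `B_t` inflates `F` and is the kind of misuse
the documentation of `build_productivity()` warns about.

**Priors.** Uniform throughout, on ranges supported by the species'
published demography: adult apparent survival 0.3–0.9; juvenile 0.1–0.5;
recapture 0–1 (adult male), 0–0.5 (juvenile male), 0–0.3 (females, both
ages); immigrants 0–175 per sex per year; fecundity 0–14; `k` 1–3;
initial population 80–350 individuals, implemented as an independent
discrete uniform 40–175 per sex so the total spans the stated range.
Annual survival, fecundity, and immigration each receive their uniform
prior independently per year (the analyses need annual series); recapture
probabilities are sex-by-age constants by default.

**MCMC.** Defaults mirror the full analysis: 3 chains of 1,500,000
iterations, burn-in 750,000, thinning 100. `mcmc_config(fast = TRUE)`
(3 x 20,000 / 10,000 / 10) is the desk-scale profile; the replicate
simulation studies in the test suite use 2 x 6,000 / 3,000 / 5, which on
this problem reproduces the fast-profile posteriors to well within
Monte-Carlo error (checked during development via potential scale
reduction, which `fit_ipm()` always reports and warns on above 1.1).
These reduced profiles are the package's chosen problem sizes for
simulation studies; single production fits should use the default.

## Known identifiability limits

* Juvenile survival and juvenile recapture are only jointly identified
  (few returning first-year birds carry the information); the stated
  priors do real work here, and posterior summaries of `phi_j` should be
  read with that in mind.
* Locally hatched juveniles that are never banded but survive and return
  enter the data as unmarked adults, and the model's immigrant stage
  absorbs them. "Immigration" therefore means *apparent* immigration, as
  it must in any single-site study.
* The initial-abundance prior (80–350) can sit below the population's
  actual starting size; the first annual growth rate then absorbs the
  discrepancy and comes out inflated. The derived analyses therefore
  treat the first transition separately (below).

## Stochastic growth and perturbation analysis

`lambda_t = N_t / N_{t-1}` on total abundance, and
`lambda_s = (prod lambda_t)^(1/T)`, computed on the log scale. By default
all available transitions enter; `drop_first_transition = TRUE` excludes
the first, which is the convention used in the workflow scripts because
of the initial-prior artifact above.

Sensitivity and elasticity of `lambda_s` are numerical: every annual
estimate of one vital rate is multiplied by `1 + delta` (default
`delta = 0.05`), the deterministic stage model is re-projected from the
same initial abundances, and `lambda_s` recomputed once. Then

```
sensitivity = (lambda_s' - lambda_s) / mean_t |v'_t - v_t|
elasticity  = ((lambda_s' - lambda_s) / lambda_s) / delta
```

The denominator convention for sensitivity (the across-year mean absolute
change in the rate) is one of several defensible readings of "averaging
the percent change across years"; it is pinned here, documented, and for
`delta -> 0` converges to the derivative of `lambda_s` with respect to a
proportional rescaling, divided by the mean rate (tested against central
differences). Survival probabilities perturbed past 1 are clipped with a
warning. A rate that is identically zero cannot be perturbed
proportionally: sensitivity is reported as 0 with a warning, with an
additive one-individual fallback for immigration.

## Weather metrics

Three breeding-season (May 1–August 31) covariates per year:

* **Mean daily-high wet-bulb temperature** (deg C): the Stull (2011)
  empirical formula applied to each day's maximum temperature and maximum
  relative humidity, averaged over the season. The formula's validity
  envelope (about -20 to 50 deg C, humidity >= 5%) is enforced with a
  warning.
* **Storm count**: days whose rainfall strictly exceeds 18.21 mm. The
  constant is the site's operative storm definition (one standard
  deviation above mean rain-day rainfall). The defining prose is
  internally inconsistent about whether 18.21 mm is the mean or the
  threshold; the package follows the operative reading (threshold =
  18.21 mm) and additionally offers `storm_threshold_from_data()`
  (mean + 1 SD over days with rain > 0) for the other reading.
* **Seasonal ESPI**: the May–August sum of the monthly El Nino–Southern
  Oscillation Precipitation Index, used lagged by two years. Lagged
  values for the first two study years are missing, never imputed.

Total May–August precipitation (and its 2-year lag) is computed alongside
as the projectable proxy for lagged ESPI.

## Path analysis

Seven multiple linear regressions per posterior draw: each z-scaled vital
rate on the three z-scaled weather metrics, and z-scaled `lambda_t` on
the six z-scaled vital-rate series (immigration enters as the male +
female sum by default, matching a single "immigration" effect; a
sex-split option exists). Net weather effects are
`sum_rate a(weather->rate) * b(rate->lambda)` computed *within* each
draw, never from averaged coefficients, and summarised afterwards — the
order of operations is part of the contract and is tested.

Alignment: every series is labelled by its end year `t`. The weather of
year `t` — including the lagged ESPI, the documented driver of return
rates in this system — predicts apparent survival over `t-1 -> t`
(apparent survival confounds mortality with emigration, so conditions at
`t` legitimately shape it), immigrant arrivals at `t`, fecundity of
season `t`, and `lambda_t`. This keeps the path analysis consistent with
the projection regression, which pairs `lambda_t` with precipitation at
`t - 2`.

Scaling: weather is z-scaled once across the study years; vital-rate
series are re-scaled within each posterior draw (each draw is a different
series, and per-draw scaling keeps every regression well posed). Years
with missing lagged ESPI are dropped from the weather regressions only.
With eight transitions and six predictors the `lambda` regression is
near-saturated; its per-draw coefficients are noisy and only their
posterior summaries are meaningful — which is precisely how the
uncertainty-propagating design uses them.

## Population projection

`lambda_t` (posterior mean, first transition dropped) is regressed on
2-year-lagged May–August precipitation; the fitted line plus residual
standard deviation define the projection model. For each GCM,
`lambda_t = intercept + slope * precip_{t-2}` for 2021–2100 (so the
precipitation series must start in 2019), optionally plus a Normal
residual draw per year (`mode = "stochastic"`); `lambda` is truncated
below at 0 and `N` accumulates multiplicatively from the final estimated
population size. Deterministic mode is seed-invariant; stochastic mode is
bit-reproducible given a seed. The ensemble summary reports per-year
across-trajectory medians, means, and central 95% intervals: across GCMs
only in deterministic mode, across GCMs and residual replicates in
stochastic mode (both spreads are legitimate readings of projection
uncertainty; the package provides both rather than choosing silently).
Projecting growth directly from precipitation, rather than through the
vital rates, forgoes compensatory dynamics among rates — appropriate when
no strong opposing weather effects are found, which the path analysis
itself establishes.

## The synthetic study

The generator emulates the statistical structure the model assumes, with
known truth, so that calibration is checkable end to end:

* **Population**: individual-based. Adults survive each interval as
  Bernoulli trials at the year's sex-specific rate; each female produces
  a Poisson number of offspring (sex ratio 1:1); juveniles survive their
  first year at the juvenile rate and recruit; Poisson immigrants arrive
  per sex per year. Defaults ("paper-like") match the study's magnitudes:
  nine seasons, adult survival 0.58/0.51 (m/f), juvenile 0.21/0.20,
  fecundity 2.4, immigration means 79/40, a few hundred adults starting
  near the demographic equilibrium of those rates so the population is
  roughly stationary.
* **Observation**: adults detected with sex-specific probabilities
  (0.60 m / 0.20 f); juveniles found in their hatch year with probability
  `1/k_true` (`k_true = 2`); juvenile sex recorded only if molecularly
  sexed (6%) or learned at a later recapture — so, as in the field data,
  the unknown-sex juveniles are exactly the never-resighted ones, and
  their random 1:1 assignment mixes the sexes in the juvenile release
  cohorts.
* **Weather**: daily maxima around seasonal means; zero-inflated gamma
  rainfall whose yearly level shares a latent wetness factor with the
  seasonal ESPI, giving a configurable ESPI–precipitation correlation
  (target 0.5, matching the site's observed ~0.53); rainfall parameters
  chosen so seasonal totals (~350–850 mm realised range) and storm counts
  (~4–16 per season) sit in the study's reported ranges. Weather affects
  vital rates on the logit scale (survival) or log scale (fecundity,
  immigration) per standard deviation of each metric, so rates stay in
  range while remaining linear on the analysis scale.
* **Profiles**: `"paper-like"` (weak weather effects, the default
  conditions for calibration tests), `"null-weather"` (all effects zero;
  used to check that net weather effects cover zero), and `"decline"`
  (depressed survival and immigration, a strong negative lagged-ESPI
  effect, rising projected precipitation; used to check that a configured
  decline is projected as one).

What the generator does *not* emulate: spatial structure and movement
(emigration is folded into apparent survival), nest-level biology
(clutches, renesting, brood parasitism), observer effort variation across
years, and temporal autocorrelation in weather beyond the shared yearly
wetness factor. Passing tests therefore establish that the pipeline
recovers truth under the model's own assumptions at realistic sample
sizes — the classic simulation-based calibration claim — not that those
assumptions hold for any particular field system.

## Numerical choices and degenerate inputs

* Likelihoods are computed in log space; the CJS `chi` recursion uses
  `log1p` where it matters. Zero Poisson means with positive counts give
  an honest `-Inf`, not an error.
* JAGS discrete-uniform priors (immigrants, initial abundance) are
  implemented as categorical draws over the integer support; tiny
  constants (1e-10) keep Poisson means strictly positive in JAGS.
* `zscale()` refuses constant series; the generator maps a constant
  weather metric to a zero effect instead.
* Empty m-array release rows (cohorts with no releases) are retained with
  size-zero multinomials, which JAGS accepts.
* The stage model run from posterior-mean rates is not the posterior mean
  of stage-model runs; on the paper-like fixture the two agree within 15%
  per year, and the test suite pins that bound.
* Projected `N` is floored at zero; `lambda` draws are truncated below at
  zero and not truncated above.

## Problem sizes used by the tests

Simulation studies in the test suite use the paper-like conditions
(nine years, ~450 adults, ~3,600 encounter records) with the reduced
MCMC profile: 20 replicates for survival-coverage calibration, 10 for the
null-weather path check, with fixed seeds throughout. The acceptance
script runs one full pipeline at the fast MCMC profile. These sizes are
the package's choices for routine verification; nothing prevents running
the same studies at the full MCMC length.
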