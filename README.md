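# grassipm

Demographic analysis of a declining grassland songbird population:
a Bayesian two-sex integrated population model (IPM), perturbation
sensitivity of stochastic population growth, a posterior-propagating path
analysis of weather effects on vital rates, and climate-driven population
projection to 2100.

The package is written for population ecologists working with
mark-recapture, count, and productivity data from a single intensively
monitored site — here, a grasshopper sparrow (*Ammodramus savannarum*)
population breeding in tallgrass prairie — who want to ask how
breeding-season weather shapes vital rates and what projected precipitation
regimes imply for persistence.

## The model

Three annual datasets are fitted jointly:

* **Counts** `y_t`: unique individuals observed each breeding season,
  modelled as `y_t ~ Poisson(N_t)` around a latent two-sex population.
* **Capture histories**: sex- and age-structured Cormack–Jolly–Seber (CJS)
  likelihood (via m-arrays) for apparent survival `phi` and recapture
  probability `p`. Birds marked as juveniles survive their first interval
  at the juvenile rate and carry a juvenile recapture probability at the
  first occasion after marking, adult rates thereafter.
* **Productivity** `J_t ~ Poisson(B_t F_t / k)`: juveniles recorded per
  female census `B_t`, with a shared denominator `k in [1, 3]` absorbing
  the known undercount of juveniles (nest searches find between a third
  and all of each cohort).

The latent state has three stages per sex: surviving adults
`S_{s,t} ~ Binomial(N_{s,t-1}, phi_a,s,t)`, locally produced recruits
`R_{s,t} ~ Poisson(N_f,t-1 F_{t-1} (1/2) phi_j,s,t)`, and immigrants
`I_{s,t}` with a discrete-uniform 0–175 prior. All vital-rate priors are
uniform on ranges supported by the species' literature (adult survival
0.3–0.9, juvenile 0.1–0.5, fecundity 0–14, ...). Fitting is MCMC through
JAGS (`rjags`).

Derived analyses:

* annual growth `lambda_t = N_t / N_{t-1}` and its geometric mean
  `lambda_s`; sensitivity and elasticity of `lambda_s` to each vital rate
  by 5% perturbation of every annual estimate;
* a seven-regression path analysis (each z-scaled vital rate on the three
  z-scaled weather metrics — mean daily-high wet-bulb temperature, storm
  count, 2-year-lagged seasonal ESPI — plus z-scaled `lambda_t` on the
  vital rates), refitted once per posterior draw, with net weather
  effects `sum_rate a(weather->rate) * b(rate->lambda)`;
* a linear regression of `lambda_t` on 2-year-lagged May–August
  precipitation (the projectable proxy for lagged ESPI), used to project
  `N` for 2021–2100 under each GCM's downscaled precipitation series.

A synthetic-data generator (`simulation_truth()`, `simulate_weather()`,
`simulate_population()`, `make_study_fixture()`) emulates the whole study —
marked individuals, partial detection, unknown-sex juveniles, weather with
a configurable ESPI–precipitation correlation, and per-GCM projections —
so every stage is testable end to end with known truth.

## Worked example

The `analysis/` scripts run the full pipeline on a generated study:

```sh
Rscript analysis/01_simulate.R       # synthetic study -> results/fixture/
Rscript analysis/02_fit_ipm.R        # fit the IPM (fast MCMC profile)
Rscript analysis/03_sensitivity.R    # lambda_s, sensitivities, elasticities
Rscript analysis/04_weather_paths.R  # weather metrics + path analysis
Rscript analysis/05_projection.R     # climate-driven projection to 2100
```

With the default seed the run prints, among other things:

```
True adult survival (m/f):  0.58 / 0.51
lambda_s (dropping first):       0.9791

Net weather effects on annual growth (mean [95% CrI]):
      weather  mean lower  upper
 wetbulb_mean -0.17 -0.41  0.091
     n_storms  0.16 -0.22  0.536
    espi_lag2 -0.51 -0.75 -0.183

lambda ~ lagged precip: intercept 1.1117, slope -1.884e-04 per mm
Projected mean annual growth 2021-2100: 0.999 (95% PI 0.732-1.269)
Across-GCM median population in 2100: 145 (95% PI 10-2407)
```

Read: the fitted stochastic growth rate sits just below 1; the
generator's built-in negative lagged-ESPI pathway is recovered as the
strongest net weather effect (its interval excludes 0); growth declines
with lagged precipitation, and the median projection shrinks from ~350
individuals to ~145 by 2100, with wide prediction intervals — the same
qualitative behaviour the method reports on field data.

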