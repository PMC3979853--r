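# nmixtrend

Binomial (N-)mixture modelling of repeated line-transect counts:
abundance corrected for imperfect detection, hierarchical Bayesian trend
estimation, and simulation-based power analysis for monitoring design.

## The problem

Transect counts of territorial songbirds miss birds, and the fraction
missed changes with habitat, weather and between years.  A monitoring
scheme that reads raw counts as abundance confounds population change with
detectability change.  The motivating system is the monitoring of singing
male Aquatic Warblers (*Acrocephalus paludicola*) on fen mires: 50 one-km
transects, each surveyed three times within one week (closure), habitat
scored at five points per transect into four vegetation-height,
water-depth and litter-cover categories.

With repeated counts $y_{itj}$ on transect $i$, year $t$, visit $j$, the
binomial mixture model separates the latent "super-population" from
detection:

$$N_{it} \sim \mathrm{Poisson}(\lambda_{it}),\qquad
  y_{itj}\mid N_{it} \sim \mathrm{Binomial}(N_{it}, p_{itj}),$$

$$\log \lambda_{it} = \beta_0 + b_i + r\,t + \beta^\top x_{it},\qquad
  \mathrm{logit}\, p_{itj} = \alpha_{year[t]} + \alpha_{rain} z_{itj} +
  \alpha^\top v_{it},$$

with a transect random effect $b_i \sim N(0, \sigma_b^2)$ and a yearly
log-linear trend $r$ ($100(e^r-1)$ = percent change per year).  The
package provides:

* `nmix()` — maximum-likelihood fitting of the mixture (latent abundance
  marginalised in C++), with `print`/`summary`/`coef`/`logLik`/`predict`/
  `fitted`/`residuals`/`simulate`/`plot` methods;
* `candidate_specs()`, `fit_candidates()`, `aic_table()` — the 45-model
  candidate set and AIC selection with Akaike weights;
* `nmix_trend()` — the Bayesian trend model (adaptive-Metropolis sampler
  on the marginal likelihood, exact draws of the latent abundances), with
  `annual_totals()`, `correction_factor()`, `extrapolate_population()`,
  `trend_summary()` and `posterior_predictive_check()`;
* `simulate_survey()` / `power_scenario()` / `run_power_analysis()` — a
  survey generator emulating the monitoring design, and the power
  comparison of detection-corrected versus raw-count trend estimation.

## Worked example

```r
library(nmixtrend)
sim <- simulate_survey(generator_config(n_transects = 50, n_years = 3, seed = 1))
sim$dataset
#> Repeated transect count survey
#>   50 transects, 3 year(s) (1-3), 3 visits per transect-year
#>   150 transect-years; counts: mean 11.5, sd 5.6, range 1-28 (0 missing)

fit <- nmix(sim$dataset, abundance = "water",
            detection = c("Year", "rain", "vegetation"))
fit
#> Binomial mixture model (ML): water | Year + rain + vegetation
#>   logLik -1201.78 on k = 12 parameters, AIC 2427.57 (K = 128)

aic_table(fit_candidates(sim$dataset,
                         specs = list(fit$spec,
                                      nmix_spec("water", "vegetation"),
                                      nmix_spec("water", "constant")),
                         nstarts = 2, hessian = FALSE))
#>                               model  k      AIC    delta  weight
#> 1                water | vegetation  9 2424.870 0.000000 0.74...
#> 2  water | Year + rain + vegetation 12 2427.569 2.698640 0.19...
#> 3                  water | constant  6 2429.887 5.016849 0.06...

bay <- nmix_trend(sim$dataset, config = trend_control("desk", seed = 1))
trend_summary(bay)$percent_change
#>      mean        sd       lcl       ucl
#> 10.853860  6.676832 -1.861238 24.050079

annual_totals(bay)
#>   year      mean       sd     lcl  ucl
#> 1    1  799.3879 59.16445 708.000  933
#> 2    2  912.4885 45.79298 832.000 1008
#> 3    3 1016.8883 72.30402 901.975 1192

correction_factor(bay)
#>   year max_round_count     mean      lcl      ucl
#> 1    1             528 1.513992 1.340909 1.767045
#> 2    2             572 1.595260 1.454545 1.762238
#> 3    3             659 1.543078 1.368703 1.808801

posterior_predictive_check(bay, seed = 1, ndraws = 600)
#> Posterior predictive check: Bayesian p-value = 0.46, slope = 1.040
```

Reading: the generator planted a +8%/yr trend; the posterior says
+10.9%/yr (95% CrI −1.9 to +24.1).  The estimated super-population totals
run ~1.5× above the best single-round raw counts — the size of the
correction a detection-naive census would need — and a predictive p-value
near 0.5 with a calibration slope near 1 indicates the model reproduces
its own data comfortably.  Field data are read with
`read_survey_dataset("counts.csv", "site_covariates.csv",
"obs_covariates.csv")`; column layouts are documented in
`?survey_dataset`.

A power comparison at the monitoring target (20% decline over 10 years):

```r
sc  <- power_scenario(n_sims = 200, seed = 1, estimator = "rawcount")
run_power_analysis(sc)   # raw-count regression on yearly totals
sc2 <- power_scenario(n_sims = 40, seed = 1, estimator = "mixture")
run_power_analysis(sc2)  # Bayesian mixture fit per simulation (slow)
```

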