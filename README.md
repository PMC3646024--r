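# nmixterra

Terrain-driven abundance estimation for terrestrial salamanders (and other
cryptic, repeatedly-counted taxa) with imperfect detection.

Woodland plethodontid salamanders are hard to count: on any visit most
individuals are underground or under cover, so raw counts confound how many
animals are present with how detectable they were that day. `nmixterra`
implements the full analysis chain for separating the two at fine spatial
scale:

* **Microclimate covariates from a DEM** — slope/aspect (northness,
  eastness), topographic position index (TPI, 90 m neighbourhood),
  topographic wetness index (TWI, D8 flow accumulation with pit filling),
  potential relative radiation (PRR, hillshade summed over a solar
  schedule), curvature, distance to stream, NDVI from red/NIR bands, all
  smoothed with a 9 m × 9 m focal mean.
* **Bayesian binomial-mixture (N-mixture) abundance models** —
  `N_i ~ Poisson(λ_i)`, `log λ_i = x_i'β`; `y_ij | N_i ~ Binomial(N_i,
  p_ij)`, `logit p_ij = w_ij'α (+ ε_ij)` — with Poisson, zero-inflated
  Poisson, and plot-survey detection-random-effect parameterizations,
  fitted by a data-augmented Metropolis-within-Gibbs sampler (C++ core),
  with Gelman–Rubin diagnostics and a chi-square posterior predictive
  check (Bayesian p-value).
* **Credible-interval covariate selection** — the staged procedure that
  screens detection covariates first, then abundance covariates, retaining
  terms whose 95% CRI excludes zero (with parent-term hierarchy for
  quadratics and interactions).
* **Leave-one-out cross-validation** of site abundance with exceedance
  accounting, and **landscape abundance projection** (posterior mean of
  `exp(x'β)` per pixel).
* **Three-state multistate occupancy models** (conditional binomial
  parameterization: ψ, R, p, δ; maximum likelihood) for demographic
  cohorts — gravid females and juveniles — plus the summary regressions
  relating cohort occurrence to abundance and temperature.
* **A seeded synthetic-data generator** that reproduces the study design
  (135 plots of 3 m × 3 m, ≥ 75 m apart, 7 surveys) and the exact
  generating hierarchy the models assume, so the whole pipeline is
  testable without field data.

## Worked example

Simulate the default study and fit the final model (Poisson abundance,
detection random effect), then look at the posterior:

```r
library(nmixterra)

sim <- simulate_study(seed = 1)   # 135 x 7 counts at the default truth
spec <- nmix_spec(
  abundance_terms = c("NDVI", "TPI", "TWI", "PRR", "TWI:PRR"),
  detection_terms = c("Date", "Bark", "Soak.Rain", "Soak.Rain^2",
                      "Temp", "Temp^2"),
  detection_random_effect = TRUE)
fit <- nmix_fit(sim$data, spec, mcmc_config(seed = 1))
tidy(fit)
```

```
   parameter            mean     sd   lower  upper  rhat
 1 beta[(Intercept)]   0.497 0.123   0.269   0.757 1.01
 2 beta[NDVI]          0.429 0.0777  0.270   0.583 1.00
 3 beta[TPI]          -0.437 0.0710 -0.578  -0.297 1.000
 4 beta[TWI]          -0.434 0.0766 -0.586  -0.288 1.01
 5 beta[PRR]          -0.257 0.0725 -0.399  -0.112 1.00
 6 beta[TWI:PRR]      -0.295 0.0655 -0.420  -0.168 1.000
 7 alpha[(Intercept)] -1.62  0.168  -1.96   -1.32  1.00
 ...
15 mean_detection      0.166 0.0230  0.124   0.211 1.00
```

Abundance coefficients are on the log scale, detection on the logit scale;
`mean_detection` is detection at average covariates (the inverse logit of
the detection intercept, here 0.166 against a generating value of
`plogis(-1.64) = 0.163`). The generating abundance coefficients (0.445,
0.422, −0.371, −0.326, −0.241, −0.283) all fall inside their 95% CRIs.

```r
glance(fit)
#> bayes_p 0.320   chisq_ratio 1.04   (well-specified: p_B near 0.5)

ab <- fit$site_abundance$mean
mean(ab)                          # 2.24 salamanders per 9 m^2 plot
mean(density_from_abundance(ab))  # 0.249 per m^2
```

Downstream stages chain off the same objects: `select_covariates()` for
CRI-based model construction, `loo_cross_validate()` for the per-site
cross-validation table, `predict_abundance()` for a landscape abundance
raster, `fit_multistate()` + `conditional_occurrence()` +
`cohort_landscape_summary()` for the cohort analyses, or simply
`run_pipeline(pipeline_config(...))` for the whole chain with CSV/ASCII-grid
artifacts and a seed manifest. A thin CLI lives at
`inst/scripts/nmixterra-cli.R`.

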