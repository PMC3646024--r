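---
title: "Terrain-driven salamander abundance: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Terrain-driven salamander abundance: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmixterra)
```

`nmixterra` estimates the fine-scale abundance of terrestrial plethodontid
salamanders — cryptic animals with detection probabilities well under 0.5 —
from repeated plot counts, linking abundance to microclimate covariates
derived from a digital elevation model. This vignette documents the models,
the numerical choices, and what the synthetic-data machinery does and does
not demonstrate.

## The binomial-mixture (N-mixture) abundance model

Each of $S$ plots holds a latent abundance $N_i$; each of $J$ repeat surveys
detects every individual independently with probability $p_{ij}$:

$$N_i \sim \mathrm{Poisson}(\lambda_i), \qquad
  \log \lambda_i = \mathbf{x}_i^\top \boldsymbol\beta,$$
$$y_{ij} \mid N_i \sim \mathrm{Binomial}(N_i, p_{ij}), \qquad
  \mathrm{logit}\, p_{ij} = \mathbf{w}_{ij}^\top \boldsymbol\alpha
  \;[+\;\varepsilon_{ij}],$$

with three parameterizations of the abundance/detection process:

* **Poisson** — the base model above;
* **zero-inflated Poisson (ZIP)** — $N_i = 0$ with probability $\phi$,
  otherwise Poisson, for landscapes with structurally empty plots;
* **detection random effect** — $\varepsilon_{ij} \sim \mathcal N(0,
  \sigma_p^2)$ per plot-survey cell, absorbing unexplained detection
  heterogeneity (weather micro-variation, observer variation).

The model assumes population closure over the survey window (a short spring
active season), independent detections, and no double counting.

### Priors and sampling

Regression coefficients get $\mathcal N(0, 10^6)$ priors (`prior_sd =
1000`). The paper-style analysis leaves $\sigma_p$'s prior unstated; we use
half-Normal(0, 10), weakly informative on the logit scale, and a
$\mathrm{Beta}(1,1)$ (uniform) posterior update for $\phi$ via its
conjugate Gibbs step. The sampler (in C++) is data-augmented
Metropolis-within-Gibbs:

* latent $N_i$: discrete random walk with steps $\pm 1, \pm 2$, bounded
  below by $\max_j y_{ij}$ and above by `n_max` (default
  $\max(y) + 50$; the fit warns if any draw touches the bound);
* $\beta_k$, $\alpha_k$: componentwise Gaussian random walks, scales
  adapted during burn-in to a 0.44 acceptance rate (Roberts–Rosenthal
  batch adaptation), frozen afterwards so the post-burn-in chain is a
  valid Markov chain;
* $\varepsilon_{ij}$: cellwise Gaussian random walk under the
  $\mathcal N(0, \sigma_p^2)$ prior;
* $\sigma_p$: random walk on $\log \sigma_p$ with the Jacobian correction;
* ZIP structural zeros: Gibbs, available only to sites with all-zero
  histories.

Default run lengths are desk-scale — 3 chains of 20,000 iterations, 10,000
burn-in, thinning 10 — and reproduce long-run posteriors to Monte-Carlo
accuracy on the study design used here; the historical long run
(500,000/250,000/50) is one `mcmc_config()` call away. Convergence is
monitored with the Gelman–Rubin statistic computed from its defining
variance decomposition; fits flag `converged = FALSE` when any
$\hat R > 1.1$. Reproducibility: every chain, generator and pipeline stage
derives a child seed from one integer seed, so identical calls give
identical results bit for bit.

### Posterior predictive checking

Fit is assessed with a chi-square discrepancy
$T(y, \theta) = \sum_{ij} (y_{ij} - N_i p_{ij})^2 / (N_i p_{ij} +
\epsilon)$, computed per retained draw for the data and for a replicate
dataset drawn from the same $(N_i, p_{ij})$. The Bayesian p-value is the
fraction of draws with $T(y^{rep}) \ge T(y)$; values near 0.5 indicate
adequate fit, values near 0 overdispersion the model cannot absorb. The
$\epsilon = 0.5$ guard keeps cells with $N_i p_{ij} = 0$ finite; it is a
numerical convention, stated here because the discrepancy's absolute value
(but not its calibration) depends on it.

## Terrain covariates

From a north-up DEM (row 1 = north) the package derives: Horn-stencil
slope and aspect (northness = cos aspect, eastness = sin aspect); TPI,
elevation minus the mean within a 90 m circular neighbourhood (ravines
negative); TWI, $\ln(a/\tan\beta)$ with specific catchment area $a$ from D8
flow accumulation on a priority-flood pit-filled surface and slope floored
at 0.1° to avoid division by zero; PRR, hillshade summed over every hour
of the 1st and 15th of April–October at the site latitude (38.78° N by
default) using a NOAA-style declination/hour-angle solar position without
atmospheric refraction (the index is explicitly *relative*); curvature
(negative Laplacian, scaled per 100 m); and Euclidean distance to streams
(D8 accumulation above a threshold). Every layer passes through a
9 m × 9 m focal mean before plot extraction, absorbing GPS placement error
of the same order as the 3 m grid. The optional insolation adjustment to
TWI scales each cell's accumulation weight by $(1 - \text{hillshade})$ at
a fixed sun position; the exact historical adjustment is not published, so
the package defaults to unadjusted TWI and documents this weighting as its
own interpretation.

All covariates are standardized (mean 0, sample SD 1) before fitting.
Quadratic and interaction terms (`"Temp^2"`, `"TWI:PRR"`) are formed from
the *already standardized* linear terms and not re-standardized — this
keeps parent and child terms on one scale, so coefficient signs and
magnitudes compare directly.

## Covariate selection

Model construction is staged: (1) all three parameterizations are fit
with the full covariate sets and ranked by $|p_B - 0.5|$ (Bayesian
p-value closest to 0.5), gated on $\hat R \le 1.1$ — the published
procedure says only "assessed model fit", so the ranking rule is this
package's explicit operationalization; (2) all detection covariates are
fit with constant abundance, and those whose 95% CRI excludes zero are
retained; (3) the retained set is refit to confirm sign stability; (4)
abundance covariates are screened the same way under the confirmed
detection model; (5) the final joint model is fit. A retained quadratic or
interaction always keeps its linear parents (the published final model
retains a linear temperature term whose CRI spans zero alongside its
significant quadratic — the hierarchy rule encodes exactly that).

## Cross-validation

Leave-one-out refits mask one site's counts (covariates untouched) and
compare the full-model posterior-mean abundance with the held-out site's
posterior *predictive* abundance (a $\lambda$ draw then a Poisson draw;
a $\lambda$-only option exists). An exceedance is a full-model estimate
outside the LOO 95% CRI. The error-rate denominator defaults to the
reference arithmetic of $S - 1$ compared sites (134 of 135); the
alternative "all compared sites" convention is an argument, because the
published denominator is not explained and we decline to guess intent.

## Multistate occupancy for demographic cohorts

Whether gravid females (reproductive effort) and juveniles (recruitment)
occur at occupied plots is modelled with a three-state occupancy model in
the conditional binomial parameterization: occupancy $\psi$, conditional
cohort presence $R$, detection $p$ (shared between occupied states by
default) and cohort classification $\delta$. The history likelihood
enumerates the three latent states; fitting is maximum likelihood (BFGS,
five seeded starts) with standard errors from the inverse observed
information, mirroring standard occupancy software practice rather than
MCMC. Published cohort "detection probabilities" could be either $\delta$
or $p\,\delta$; both are reported, labelled, in every fit. With
$R = \delta = 1$ the model collapses exactly to single-season two-state
occupancy, which the tests exploit as a nesting check.

## The synthetic-data generator

Because no field data are distributed, the generator *is* the study
design: 135 plots of 3 m × 3 m at ≥ 75 m spacing, 7 surveys, counts from
the exact Poisson–Binomial hierarchy above. Generating coefficients
default to the published posterior means (abundance: intercept 0.445,
NDVI 0.422, TPI −0.371, TWI −0.326, PRR −0.241, TWI×PRR −0.283;
detection: intercept −1.64, Date 0.904, Bark 0.263, Soak.Rain −0.491,
Soak.Rain² 0.463, Temp 0.144, Temp² −0.220). Values the paper-style
analysis does not report were fixed once, before any testing, at
field-plausible levels and are not tuned: $\sigma_p = 0.5$ (moderate
unexplained detection variation), $\phi = 0$ (the selected field model was
the random-effects, not the ZIP, parameterization), a parametric maximum
surface temperature $28 + 1.5\,\mathrm{TPI} - 1.0\,\mathrm{TWI} +
2.0\,\mathrm{PRR}$ °C (spanning roughly the reported 23–33 °C), a
site-independent gravid share $r_{gravid} \cdot 0.5 \cdot
(1 - \bar p_{juv})$ of all individuals, and a juvenile share declining
logistically in temperature (intercept −0.4, slope −1.2 per SD). Stage
frequencies are configurable because the field stage composition of the
487 captures was never reported.

The DEM generator produces a seeded smoothed random field with ridge/ravine
relief; plots are placed by rejection sampling under the spacing
constraint (capped at $10^5$ attempts). The fast path
(`simulate_study(landscape = FALSE)`) draws site covariates directly as
independent standard normals — the model's own generating assumption —
which is what the simulation studies use. What passing tests show:
the estimators recover the parameters of data generated under the model's
assumptions, at the study's design size. What they do not show: robustness
to spatial autocorrelation of abundance beyond covariates, non-random
temporary emigration, count double-counting, or covariate measurement
error — none of which the generator emulates.

## Problem sizes and numerical conventions

Simulation studies in the test suite use the 135 × 7 design for
calibration (50 replicates at desk-scale MCMC: 2 chains × 5,000
iterations), 500 sites for selection consistency (20 replicates), and
135 × 7 for multistate recovery (50 replicates) — sizes chosen so the
whole suite runs on a laptop-class single core. Degenerate inputs are
contracts, not surprises: constant covariate columns, infeasible plot
packings, negative counts, and mismatched site keys all raise immediate,
named errors. Ties in D8 flow routing are broken by a fixed neighbour
order; the priority-flood fill adds an epsilon gradient ($10^{-6}$) so
every cell drains. Missing surveys are first-class: masked cells simply
drop out of every likelihood product.
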