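---
title: "Methods: joint modelling of glucocorticoid trajectories and survival"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint modelling of glucocorticoid trajectories and survival}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gcjoint)
```

This vignette records the modelling choices behind `gcjoint`: the joint
model itself, the synthetic-data generator that stands in for field data,
the numerical machinery, and the places where the design was genuinely
open and a decision had to be made.

## The model

The package couples two submodels through shared parameters.

**Longitudinal submodel.** Log fecal glucocorticoid (fGC) concentration
of female $i$ at age $t$ is

$$y_i(t) = m_i(t) + \varepsilon_i(t) = X_i(t)\beta + b_{0i} + b_{1i}t +
\varepsilon_i(t), \qquad \varepsilon_i(t) \sim N(0, \sigma^2),$$

with $(b_{0i}, b_{1i}) \sim N(0, \Sigma_b)$. The fixed design $X_i(t)$
carries an intercept; age in years; dummies for pregnant and lactating
(reference cycling), wet season (reference dry) and alpha status; and
z-scored continuous covariates (3-month rainfall anomaly, 30-day mean
maximum temperature, group size, group size squared, proportional
dominance rank, and the two storage covariates, time to extraction and
time to assay). `m_i(t)` — the noise-free individual trajectory — is the
quantity the survival submodel sees.

**Survival submodel.** A parametric proportional-hazards model with
delayed entry at adulthood:

$$h_i(t) = h_0(t)\,\exp\{\gamma^\top w_i(t) + f(\alpha, M_i(t))\},$$

where $\log h_0$ is a cubic B-spline with two internal knots, $w_i(t)$
are yearly time-varying covariates (sociality indices DSI-F and DSI-M
and the annual rainfall anomaly, z-scored, stepping at birthdays), and
$f$ is one of the three association structures: current value
$\alpha\,m_i(t)$, current slope $\alpha\,m_i'(t)$, or cumulative
exposure $\alpha \int m_i(u)\,du$. Left truncation is enforced: each
female's likelihood contribution conditions on survival to her entry
age, so the cumulative hazard runs from entry to exit.

**Assumptions worth stating.** Trajectories are linear in age per
female after covariate adjustment; yearly survival covariates are
piecewise constant within years of life; hazards are proportional in
the covariates and the association feature; censoring (end of the
observation window) is independent of the death process.

## The synthetic-data generator

The generator emulates the statistical structure of a two-decade
observational study of wild female baboons, so every downstream stage
can be exercised and calibrated without any field data.

* **Cohort**: 242 adult females by default, observed over a 19.5-year
  window. About a third are already adult when the window opens (entry
  ages drawn uniformly above the adult threshold of 5 years); the rest
  reach adulthood during the window and enter at age 5. Censoring falls
  at the window end; death can truncate it earlier.
* **Sampling intensity**: per female-year sample counts are Poisson
  with mean 7.5, truncated to a minimum of one (drawn by inverse
  transform). This reproduces a median of 7 samples per female-year
  with a range floor of 1. Sample times are uniform within the year —
  the within-year distribution of real collection dates is not
  documented, so the least-informative choice is used.
* **Variance budget**: the total variance of log fGC is set to
  $0.199 = (1/2.24)^2$, so that one unit of log fGC equals 2.24 SD of
  the distribution. It is partitioned as fixed-effect variance 0.0275,
  summed random-effect variance 0.0149 and residual variance 0.1566 —
  the split implied by a marginal variance-explained of 0.138 and a
  conditional one of 0.213. Because a finite simulation never hits
  target variances exactly, the generator *calibrates*: the non-intercept
  fixed predictor is rescaled to its target variance in-sample, and the
  random-effect draws are rotated to their exact target covariance and
  rescaled so the realised random variance at the realised sample ages
  meets its target. The realised coefficients are returned as the truth
  for recovery tests.
* **Weather**: daily rainfall is a seasonal wet/dry occurrence-intensity
  process (wet season November–May) and daily maximum temperature a
  sinusoid plus noise. The record doubles as the "long-term" reference
  for anomaly covariates.
* **Reproductive states**: a semi-Markov chain cycling →
  pregnant (178 days, a standard baboon gestation) → lactating
  (Normal around 365 days) → cycling, with no infant-death branch. The
  first four days of lactation are recoded as pregnant wherever states
  are looked up, reflecting the lag between circulating hormones and
  their fecal metabolites.
* **Behaviour**: grooming counts follow dyad-specific latent affinities
  scaled by observer effort (so the effort correction in the sociality
  module has a real artifact to remove); decided agonistic outcomes
  follow a latent linear hierarchy with a small upset probability.
* **Mortality**: the simulation baseline is Gompertz,
  $h_0(t) = a e^{b(t-5)}$ with defaults $a = 0.022$, $b = 0.12$ —
  chosen so the median adult age at death is near 18 years — rather
  than a spline, so closed-form oracles exist (constant hazard when
  $b = 0$). Death times are drawn by inverse-transform sampling with
  the same per-year Gauss–Legendre quadrature the fitter uses, and root
  finding on the cumulative hazard.
* **Association centring**: the simulated hazard uses the association
  feature centred at the population-mean trajectory,
  $f_c = \alpha\,(\text{feat}_i(t) - \overline{\text{feat}}(t))$. The
  uncentred common component $\alpha\,\overline{\text{feat}}(t)$ is a
  smooth function of age that the fitted spline baseline absorbs, so
  the fitted model still uses the plain $f(\alpha, M_i(t))$; centring
  in the generator only keeps the Gompertz parameters meaningful.

One global seed drives everything; sub-generators derive child seeds
deterministically, so cohorts, behaviour and death draws are
reproducible bit for bit.

What the generator does *not* emulate: demographic renewal (no births
maturing into the cohort), group fissions, male dispersal, assay batch
effects, or genetic admixture. Passing recovery tests on this generator
shows the estimation machinery is sound under the model's own
assumptions — it does not validate those assumptions against real
baboon data.

## Covariate construction

* **Season** is a pure function of calendar month: June–October dry,
  November–May wet.
* **3-month rainfall anomaly**: total rain over the 90 days ending the
  day *before* sampling, minus the long-term mean of the same calendar
  window over every year of the record. A fixed 90-day window was
  preferred to calendar months for continuity; the long-term mean
  includes the focal year (with a multi-decade record the difference is
  negligible, and the convention is simpler).
* **Annual rainfall anomaly** uses the female's birthday-aligned year
  of life, truncated at death/censoring, compared against the same
  (possibly truncated) calendar span in other years.
* **30-day temperature**: mean of daily maxima over the 30 days ending
  at and including the sample day; up to 5 missing days are tolerated.
* **Dominance ranks** are computed monthly from decided agonistic
  interactions only. The ordering minimises, lexicographically, the
  number and then the strength of dominance relations pointing up the
  hierarchy (the classic I&SI criterion); exhaustive search up to eight
  females, pairwise-swap descent above. Proportional rank is the share
  of adult females dominated; the top female is the alpha. Months
  without interactions inherit the previous month's ranks.
* **Z-scoring** of the continuous covariates uses in-sample moments,
  stored in the design object so predictions and trajectory paths reuse
  the same constants. Age is deliberately *not* z-scored: the random
  slope multiplies age, and keeping it in years keeps the slope
  interpretable per year of life.

## The sociality index

Daily dyadic grooming rates (events in either direction over
co-residence days) are corrected for observer effort — focal samples on
adult females divided by mean adult females present divided by
co-residence days — by taking residuals of a pooled OLS regression of
log rate on log effort. Decisions the source description leaves open:

* Dyads never observed grooming are excluded from the regression and
  from top-partner candidacy (log 0 is undefined, and the index is the
  mean of the *strongest* observed bonds).
* The regression pools all of the population's dyads over each focal
  female-year window (female-female pairs counted once).
* Low-observation periods are supplied as an explicit date mask, not
  auto-detected.

DSI-F (female partners) and DSI-M (male partners) are the mean of the
top three bond strengths, or of however many partners exist; females
with no partners of a sex get a missing value, imputed by the age-class
mean.

## Estimation

`fit_lmm()` fits the longitudinal submodel alone by REML (lme4), for
diagnostics, starting values and the Nakagawa variance-explained
decomposition (random-effect variance taken as the average of
$z^\top \Sigma_b z$ over observations).

`gcjm()` estimates the joint posterior by a blocked adaptive
Metropolis-within-Gibbs sampler:

* per-female random intercepts and slopes as independent vectorised
  blocks, plus an independence refresh of the slopes from their exact
  Gaussian longitudinal conditional (the weak survival dependence
  decides acceptance);
* an exact Gibbs "recentring" move shifting (intercept, age slope)
  against the random effects — the classic fixed-vs-random mean
  confounding otherwise dominates the autocorrelation;
* fixed effects by independence MH from their exact Gaussian
  conditional under the longitudinal likelihood and prior;
* survival coefficients in three adaptive blocks (covariates
  $\gamma$; spline coefficients $\omega$; scalar $\alpha$);
* residual variance on the log scale; $\Sigma_b$ by independence MH
  from its conditional inverse-Wishart; and a non-centred
  (interweaving) rescaling move for the slope scale.

Two reparameterisations matter. First, the association feature is
internally centred, scaled, and its $\beta$-driven component
orthogonalised against the spline basis. Because the basis sums to one
and the projection lands exactly in its span, this is a pure shear of
the parameter space — draws are mapped back to the natural scale on
storage — but it removes an extreme posterior ridge between $\alpha$
and the baseline (the feature has a large smooth common component that
the baseline must absorb). Second, priors: coefficients get
response-scaled normal priors (2.5 SD of the response; the intercept
centred at the response mean), $\gamma$ and $\alpha$ get $N(0, 2.5^2)$,
scales get half-normal priors, the random-effect correlation a uniform.
The spline coefficients get $N(0, 20^2)$ — deliberately wider than a
conventional weakly informative scale, because under the uncentred
association the baseline must absorb $-\alpha\,\bar m(t)$ (of order
$4\alpha$ per coefficient); a tighter prior on the natural coefficients
implicitly penalises $|\alpha|$ and demonstrably attenuates its
recovery by tens of percent.

**Numerics.** The cumulative hazard uses 15-node Gauss–Legendre
quadrature per year-of-life segment: the integrand is smooth within a
year (covariates constant, trajectory linear) and may jump at
birthdays, so per-segment quadrature is accurate to well below the
1e-8 tolerances the oracle tests impose. Internal knots sit at the
33rd/67th percentiles of observed event ages; boundary knots span entry
to the latest exit, and the basis is clamped outside. The AUC
association integrates from the common adult-onset age (5 years), not
each female's observation-entry age: with per-female lower limits the
uncentred AUC carries an entry-age artifact that an age-only baseline
cannot absorb, which empirically forces $\alpha$ toward zero. For
females entering observation late, the first observed year's covariates
are carried back over the unobserved adult span.

**Presets and diagnostics.** The full-analysis preset is 8 chains of
5000 iterations (2500 warmup); the test preset used throughout the test
suite is 2 chains of 700 iterations (350 warmup) — chosen so a
default-size fit (242 females) takes well under a minute and simulation
studies with tens of replicates stay within a desktop budget.
`diagnostics()` reports split-Rhat, effective sample size (Geyer
initial-positive-sequence) and Monte Carlo SE for every scalar
parameter; the fit's `failed` flag watches the identified parameters
($\beta$, $\gamma$, $\alpha$, $\sigma^2$, the intercept SD). The
random-effect correlation is *structurally* weakly identified whenever
individual slopes are tiny — its chains wander over much of $(-1, 1)$
— and boundary spline coefficients wander where exposure is sparse;
both remain visible in `diagnostics()` but do not gate the flag.

## Dynamic prediction

`percentile_trajectory()` pins a hypothetical female at a fixed
empirical percentile of log fGC in every age class (one
pseudo-observation at each age-class midpoint, covariates at
age-specific means, categorical covariates at reference).
`conditional_survival()` then, for each posterior draw, samples her
random effects from their *exact* Gaussian conditional given the
pseudo-observations (using that draw's $\sigma^2$ and $\Sigma_b$; one
pseudo-observation per age class is a choice — the number defining the
hypothetical female is not documented in the study design this
emulates) and evaluates $S(t \mid t_0) = \exp\{-\int_{t_0}^t h\}$ on
the age grid with the same quadrature as the fitter. Reported bands are
pointwise 5th/50th/95th percentiles across draws; $S(t_0 \mid t_0) = 1$
holds exactly by construction. The default conditioning age is 14.
The closed-form constant-hazard case validates the machinery to
Monte Carlo tolerance, and re-conditioning consistency
$S(t \mid t_1) = S(t \mid t_0) / S(t_1 \mid t_0)$ holds draw for draw
when random effects are held fixed.

## Problem sizes used by the test suite

Module tests run on cohorts of 3–30 females; the variance-budget check
uses a 620-female cohort (about 60,000 samples); the death-time
inversion oracle uses 2,000 females under a constant hazard; parameter
recovery runs ten seeded replicates per association structure at the
full design size of 242 females with the test MCMC preset; the
dynamic-prediction checks share one fitted 120-female cumulative-effect
model. These sizes are the package's own trade-off between Monte Carlo
error and a desktop-scale test run.

## Known limitations

* The sampler is a random-walk-based scheme, not gradient-based MCMC;
  mixing of the weakly identified corners (random-effect correlation,
  boundary spline coefficients) is slow, and long chains are advised
  for final analyses (the full preset).
* Trajectories are linear in age; spline trajectories and
  measurement-error models for assay variation are out of scope.
* The pipeline handles single-residency animals and stable groups; no
  group fissions or re-immigration.
* All-cause mortality only; no competing risks; a single biomarker.
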