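---
title: "Modelling temperature effects on toxicokinetic rate constants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling temperature effects on toxicokinetic rate constants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermotk)
library(dplyr)
```

## The scientific problem

Uptake and elimination of organic chemicals by aquatic ectotherms are
dominated by transport processes — diffusion, advection, ventilation —
whose rates depend on temperature. As water temperatures rise,
first-order uptake rate constants $k_u$ (L kg$^{-1}$ d$^{-1}$) and
elimination rate constants $k_e$ (d$^{-1}$) both increase. `thermotk`
quantifies that dependence across species and chemicals with the
Arrhenius model, and asks two follow-up questions: does normalizing for
body mass sharpen the relationship, and does the bioconcentration factor
(BCF) inherit a temperature dependence?

## Model and assumptions

The Arrhenius equation,

$$k = A \exp\!\left(-\frac{E_A}{RT}\right),$$

is fitted in its linearized form

$$\ln k = \ln A - \frac{E_A}{R}\cdot\frac{1}{T},$$

by ordinary least squares of $\ln k$ on $1/T$ (natural logs, $T$ in
Kelvin). The slope estimates $-E_A/R$ and has units Kelvin; the
intercept estimates $\ln A$. `activation_energy()` converts a slope to
$E_A$ using $R = 8.31$ J K$^{-1}$ mol$^{-1}$ (the two-decimal
convention; the 0.05% difference from 8.3145 is negligible against
slope CVs of ~15%). Assumptions worth keeping in mind:

* **Lognormal errors.** Residuals are Gaussian on $\ln k$. This is the
  natural scale for strictly positive rate constants spanning orders of
  magnitude, and it is what the synthetic generator produces.
* **Pooling.** Pooled fits treat records as exchangeable after duplicate
  averaging; no per-study weights or random effects. Mixed-effects or
  phylogenetically corrected variants are out of scope.
* **One-compartment kinetics.** All BCF reasoning uses
  $BCF = k_u/k_e$, the steady state of a one-compartment model with
  aqueous uptake only (no growth dilution, biotransformation submodels
  or dietary routes).

### Mass correction

Whole-organism rate constants scale approximately as $m^{-1/4}$
(quarter-power allometry: rates $F \sim m^{3/4}$, so rate constants
$F/m \sim m^{-1/4}$). `mass_correct()` therefore computes
$k^* = k\,m^{1/4}$ — division by $m^{-1/4}$ — which expresses every
record as the coefficient of the allometric relationship
$k = k^* m^{-1/4}$, i.e. normalized to a 1 kg organism with units
L kg$^{-1}$ kg$^{1/4}$ d$^{-1}$ (uptake) or kg$^{1/4}$ d$^{-1}$
(elimination). The exponent sign follows from unit consistency and
allometric theory; `mass_uncorrect()` is the exact inverse.
`compare_models()` fits both variants on one rate type and reports the
slope-CI overlap and signed CV changes on which "did correction help?"
is judged.

### BCF temperature independence

Since $\ln BCF = (\ln A_u - \ln A_e) + (s_u - s_e)/T$, the BCF is
temperature-independent iff the two slopes are equal.
`assess_bcf_temperature_dependence()` reports
$\Delta s = s_u - s_e$ with $SE = \sqrt{SE_u^2 + SE_e^2}$ and a normal
95% CI. Treating the fits as independent is an approximation justified
by the two record sets being disjoint (uptake and elimination records
come from different measurements, largely different studies); it
ignores any shared-study correlation, which would make the CI
conservative rather than anticonservative in the usual case of positive
correlation. When paired per-organism $(k_u, k_e)$ values exist, the
direct regression of $\ln(k_u/k_e)$ on $1/T$ is also reported.

## Regression statistics

`fit_arrhenius()` solves the normal equations in closed form on
centered $1/T$ (numerically stable despite $1/T \approx 3\times10^{-3}$
with a spread of $3\times10^{-4}$), then back-transforms the intercept.
For each coefficient it reports the standard error from the residual
variance, the coefficient of variation $CV\% = 100\,SE/|\hat\theta|$,
the 95% CI $\hat\theta \pm t_{0.975,\,n-2}\,SE$, and the two-sided
t-test p-value of the slope (equivalent to the regression F-test in
simple regression). Published pooled coefficient tables that print
"estimate ± SD (CV%) [95% CI]" are reproduced by exactly this
arithmetic — the printed CIs equal estimate
$\pm t_{0.975, n-2}\cdot$SD to rounding, which fixes the reading of
"SD" as the coefficient standard error; `cv_pct()` and `coef_ci()`
expose the two pieces, and `reference_pooled_fits()` ships the
published values.

Degenerate inputs fail loudly: fewer than 3 records, zero variance in
$1/T$, mixed rate types, or missing masses under correction are errors
naming the offending records, never silent drops.

## Data treatment for compiled datasets

Compiled literature data need three rules before fitting, implemented in
`dataset_prep` functions and applied in this order by
`prepare_records()`:

1. **Duplicate averaging** (`average_duplicates()`): observations of the
   same (species, chemical, rate type) at the same temperature —
   compared after rounding to the nearest whole °C, ties away from zero —
   are collapsed to their arithmetic mean $k$ at the mean exact
   temperature, preventing overweighting of popular combinations. The
   source literature reports "averaged" without a scale; the arithmetic
   mean on the natural scale is the default and a geometric-mean option
   (`scale = "log"`) exists because averaging $\ln k$ is equally
   defensible under lognormal errors. Rounding happens in °C, the
   reporting unit of source studies. The operation is idempotent.
2. **Mass imputation** (`impute_mass()`): records lacking a body mass
   take the reference mass for their (species, life stage) when one
   exists, else the species mean. Still-massless records are flagged and
   excluded from mass-corrected fits only.
3. **Minimum-temperature filter** (`filter_min_temperatures()`): the
   chemical- and species-specific analyses only use groups spanning at
   least 4 distinct rounded temperatures — a two- or three-point
   Arrhenius line is too fragile. Pooled fits never apply this filter.

## Stratified analyses and the slope-equality test

`stratified_fits()` fits the Arrhenius model per chemical (each
chemical carrying one log $D_{ow}$ value) or per species, applying the
temperature filter per stratum and listing excluded strata rather than
dropping them. `test_slope_equality()` compares the separate-slopes
model against a common-slope/separate-intercepts model with the nested
F-test

$$F = \frac{(RSS_{common} - RSS_{separate})/(G-1)}
           {RSS_{separate}/(N - 2G)},$$

computed from within-stratum sums (and verified in the test suite
against `anova()` on the corresponding `lm` models). The joint test was
chosen over pairwise slope comparisons because the scientific question —
"do slopes differ by hydrophobicity?" — is a single joint hypothesis;
results are reported without multiplicity correction across strata,
with a Holm-adjusted column available from the tidied per-stratum
p-values for transparency.

## The experiment simulator

Rate constants in compilations originate from bioaccumulation
experiments: exposure at constant water concentration $C_w$ until
$t_c$, then depuration in clean water. `simulate_exposure()` evaluates
the closed form

$$C(t) = \frac{k_u}{k_e} C_w\,(1 - e^{-k_e t}) \quad (t \le t_c),
\qquad C(t) = C(t_c)\,e^{-k_e (t - t_c)} \quad (t > t_c),$$

with multiplicative lognormal observation noise.
`estimate_rate_constants()` recovers $(k_u, k_e)$ by nonlinear least
squares in log-concentration space (homoscedastic under the noise
model; natural-scale fitting is available via `ln_scale = FALSE`),
parameterized on $\log k$ so estimates stay positive, initialized from
the log-linear depuration slope and the last accumulation point, with
convergence tolerance $10^{-10}$ and at most 500 iterations.
Non-convergence is returned as a flagged row, never silently.

## The synthetic-data generator

`generator_config()` defaults define the emulated study conditions:

| parameter | default | rationale |
|---|---|---|
| `n_uptake`, `n_elimination` | 530, 958 | sizes of the published pooled compilation |
| `temperature_range_K` | 278–303 K | 5–30 °C, the span of source experiments; the empirical temperature distribution is unreported, so uniform is assumed and exposed in the config |
| `true_params_*` | slope −10000 K / ln A 40.11 (uptake); −7888 K / 25.73 (elimination) | published pooled uncorrected estimates |
| `noise_sigma_ln` | 2.0 | reproduces pooled $R^2 \approx 0.1$, the order observed in multispecies compilations |
| `taxa_weights` | compilation's per-taxon data-point proportions | dominated by fish, crustaceans and bivalves |
| `mass_law` | log-uniform per taxon, e.g. insects/crustaceans $10^{-6}$–$10^{-3}$ kg, fish $10^{-3}$–1 kg | no mass table is published; these are documented, realistic defaults |
| `dow_intercept_coeff_*` | +0.3 (uptake), −0.5 (elimination) per log $D_{ow}$ unit | qualitative pattern that hydrophobic chemicals are taken up faster and eliminated more slowly; magnitudes chosen to make the pattern clearly detectable at the default noise |
| `dow_slope_coeff_*` | 0 | hydrophobicity shifts intercepts, not slopes, by default; the interaction knob exists for power studies of the equality test |
| `duplicate_fraction` | 0.05 | a modest share of re-observed combinations, as compilations contain |

Species labels are synthetic identifiers (`Crustacea_sp03`); no claims
about real species are generated. Same seed means byte-identical
output.

What passing tests on generated data do **not** show about real data:
the generator draws temperatures independently of species and chemical,
gives every record a mass, uses a single noise scale, and makes
hydrophobicity act linearly on intercepts. Real compilations are
unbalanced (a few studies contribute many records), heteroscedastic
across taxa, and gappy. Parameter-recovery results therefore validate
the estimators under the stated model, not robustness to those
real-data features.

## Numerical choices and problem sizes

* OLS is closed-form on centered $1/T$; agreement with the
  normal-equations oracle and with `lm()` is enforced at $10^{-10}$
  relative in the test suite.
* Rounding of temperatures uses ties-away-from-zero (the convention a
  human reader applies to "nearest whole number"), not banker's
  rounding.
* The nested F statistic is clamped at 0 against floating-point
  cancellation when the two models coincide.
* Monte-Carlo suites use 500 replicates for recovery/coverage checks
  (Monte-Carlo SE of a coverage proportion ≈ 1%) and 1000 for the
  type-I-error calibration of the F-test (binomial 99.7% band 3.6–6.4%
  around 5%); recovery runs use the full compilation sizes (530/958
  records per replicate), which completes in seconds with the
  closed-form fit.
* The acceptance script derives independent seed streams per analysis
  from the user seed so analyses never share random numbers.

## Known limitations

* No weighting or random effects across source studies; slopes from
  heavily sampled studies influence pooled fits proportionally to their
  record counts.
* The $\Delta s$ CI treats uptake and elimination fits as independent.
* The one-compartment estimator assumes constant exposure
  concentration; designs with water-concentration decay need a
  different model.
* Ionization-state ($D_{ow}$ vs $K_{ow}$) handling is upstream:
  log $D_{ow}$ is an input column, never computed here.
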