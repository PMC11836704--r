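---
title: "From respirometry traces to comparative seed energetics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From respirometry traces to comparative seed energetics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedmet)
```

This vignette documents the models behind seedmet, the conventions and
numerical choices adopted where the underlying methods admit more than
one reasonable definition, what the synthetic-data generator does and
does not emulate, and the package's known limitations.

## The measurement model

A quiescent, hydrated seed in a sealed chamber consumes oxygen at an
approximately constant rate, so chamber pO₂ declines linearly until
hypoxia sets in. The trace pipeline makes four assumptions explicit:

* **Smoothing.** Fluorescence-based oxygen sensing is noisy relative to
  the per-interval signal, so each trace is smoothed with a centred
  three-measurement moving average before the slope fit. Edges are
  dropped rather than padded: padded endpoints would repeat information
  and bias the slope precisely where leverage is highest. The window is
  a tunable (`window`, odd, default 3 samples = 1.5 h at 30-min
  sampling).
* **Hypoxia truncation.** Only the maximal prefix with
  pO₂ ≥ 0.8 × initial is analysed (`frac = 0.8`); later recoveries are
  never re-admitted, since transient dips already indicate either
  hypoxic physiology or sensor failure. A replicate needs at least 4
  surviving samples to be usable.
* **STP conversion.** The depletion slope s (kPa h⁻¹) becomes a
  per-seed volumetric rate at standard temperature and pressure via the
  ideal-gas mole-fraction relation
  V̇O₂ = (−s / P_dry) · V · 273.15/(273.15 + T) / n, with
  P_dry = P_ambient − e_s(T) − pCO₂, where e_s is the Arden–Buck
  saturation vapour pressure: seeds are measured near 95% relative
  humidity, so the headspace is treated as vapour-saturated. A
  respiratory exchange ratio of 1 is assumed throughout (carbohydrate
  oxidation): evolved CO₂ then replaces consumed O₂ mole-for-mole and
  total pressure is constant over a run; a measured pCO₂ channel, when
  present, is subtracted from the dry pressure instead. A
  user-supplied `correction` function can replace this conversion
  entirely when instrument-specific standardization is available.
* **Replicate screening.** Microbial contamination elevates apparent
  oxygen consumption and is usually invisible on the seed, so species
  means are computed after a single-pass screen: replicates whose slope
  lies 2 or more population standard deviations from the species'
  **median** replicate slope are excluded. The median centre is a
  deliberate choice: with ten replicates and a realistic contamination
  rate, two or more chambers are frequently contaminated at once, and a
  mean-centred rule is dragged toward the contaminants while their
  presence inflates the spread — the screen then masks exactly the
  replicates it exists to remove, and in simulation recovers only about
  a third of contaminated chambers. The median centre keeps its
  breakdown point up to half-contaminated species and removes over 90%
  of contaminated replicates under the generator's default conditions,
  at the cost of falsely excluding roughly 4–5% of clean replicates
  (harmless to the species mean, which averages the kept chambers). The
  classical mean-centred variant remains available
  (`center = "mean"`). The rule is never iterated; iterating a 2-SD
  rule on clean Gaussian replicates would progressively trim the tails.

Temperature standardization uses the Q₁₀ relationship
SMR₂₀ = SMR_t · Q₁₀^((20 − T_t)/10), default Q₁₀ = 2.5 — the standard
coefficient for comparing ectotherm metabolic rates measured at
different temperatures. The transformation is exactly invertible, which
the generator exploits: it stores rates at species-specific measurement
temperatures (18–30 °C, the optimal-germination range) so that the
pipeline must genuinely re-standardize.

## Allometry by OLS and PGLS

The scaling model is `log₁₀ SMR = log₁₀ a + b · log₁₀ M`. OLS is
appropriate for the regression (rather than major-axis methods) because
mass is measured far more precisely than SMR. Isometry (b = 1) is
tested with a one-sample t on n − 2 degrees of freedom.

PGLS replaces the iid error with covariance σ²·V(λ), where V(λ)
multiplies the off-diagonal (shared-path-length) entries of the
Brownian covariance C by λ ∈ [0, 1] while keeping the diagonal: λ = 1
is Brownian motion, λ = 0 a star phylogeny, and intermediate values
attenuate the inherited component of the residual. Numerical choices:

* The GLS solve is Cholesky-based (whitening by back-substitution), and
  the test suite verifies to 10⁻⁸ that PGLS at fixed λ equals OLS on
  the whitened variables — the defining identity of the estimator.
* λ is profiled by bounded scalar optimization on [0, 1] (tolerance
  10⁻⁶) with both endpoints evaluated explicitly, since the optimum is
  frequently at a boundary and interior search alone can miss it.
* **REML for estimation, ML for comparison.** λ and the coefficient
  standard errors use the restricted likelihood, which removes the
  downward bias of the variance profile; the stored log-likelihood and
  AIC are always the full Gaussian likelihood at the fitted parameters
  so that OLS (3 parameters) and PGLS (4 when λ is free) are comparable
  on one footing. AIC includes the ½·n·log 2π constant; absolute AICs
  therefore differ by a constant from software that drops it, and only
  differences are meaningful.
* **Residuals are vertical deviations.** Downstream correlate analysis
  uses response-scale residuals y − Xβ̂ in log₁₀ units — how far a
  species sits above or below the fitted allometric line — not
  whitened residuals, which are a diagnostic quantity
  (`residuals(fit, type = "normalized")`).
* R² conventions differ by method: adjusted R² for OLS, and for PGLS a
  residual R² of 1 − SSE_GLS/SSE₀, with the null being the
  phylogenetic mean-only model under the same V(λ̂).

## Phylogenetic signal

Pagel's λ is estimated by maximizing the multivariate-normal likelihood
with the mean and rate profiled out analytically, leaving a
one-dimensional search. Likelihood-ratio tests against λ = 0 and λ = 1
are both reported: which null is scientifically relevant depends on the
question, and both null values lie on the boundary of the parameter
space, so p-values use the 50:50 mixture of χ²₀ and χ²₁ (halving the
χ²₁ tail), the standard boundary correction.

Blomberg's K compares the observed ratio of the mean squared deviation
from the phylogenetically corrected mean (MSE₀) to the GLS mean squared
error (MSE) against that ratio's Brownian expectation
(tr C − n/Σᵢⱼ(C⁻¹)ᵢⱼ)/(n − 1); K ≈ 1 under Brownian motion, K < 1 when
relatives resemble each other less than Brownian motion predicts.
Significance is one-sided by random tip-label permutation (default 999
permutations, explicit seed) with add-one smoothing, so the smallest
attainable p is 1/(n_perm + 1). Both statistics are invariant to affine
transformation of the trait, which the suite checks, and both are
cross-validated against an independent implementation on random
instances.

## Germination kinetics

Cumulative germination is fitted with the three-parameter log-logistic
f(t) = d / (1 + exp(b(ln t − ln e))): d is the asymptotic germination
percentage, e the inflection time, b the slope. T₅₀ is defined
**relative to the fitted asymptote** — the time at which f reaches d/2,
which for this parameterization is exactly e. The absolute alternative
(time to 50% of sown seeds) is undefined whenever d < 50% and conflates
capacity with speed; the relative convention matches the default ED
behaviour of standard dose-response software. G_max uses the
viable-seed denominator: seeds found dead by cut-test at trial end are
removed before the percentage is formed. Least squares is solved by
Levenberg–Marquardt with starts d₀ = max observed, e₀ = time nearest
half-maximum, b₀ = −2, and d bounded above at 100; time-zero points are
dropped (the curve passes through zero in the limit). Fits are
invariant to the time unit up to rescaling of e.

## Residual correlates

The correlate layer works on PGLS residuals, which are independent of
mass and phylogeny by construction:

* Univariate regressions (G_max, T₅₀, crop-vs-wild indicator) report
  slope ± SE and F = t².
* Group comparisons of germination traits between crops and wild
  species use the Welch unequal-variance t with Satterthwaite degrees
  of freedom — appropriate because ~14 cultivars face ~94 wild species
  with very different spreads.
* Climate analysis is restricted to native species: crops are excluded
  because selective breeding elevates their residuals, weeds because
  provenance is uncertain. Classes with fewer than two species are
  dropped (a singleton contributes no within-group information) and
  reported. The a-priori aridity hypothesis is tested with a single-df
  linear-trend contrast over the ordered classes using the one-way
  ANOVA error term (df₂ = n − k); successive-difference contrasts are
  available behind a flag.
* Backward stepwise regression over the 15 bioclim covariates removes,
  one per refit, the term with the largest type-III p-value above
  α_stay = 0.05 (ties broken alphabetically, so the path is
  deterministic), and summarizes the final model with type-III F per
  term. The p-value criterion was chosen over AIC because the
  procedure's purpose here is significance screening of retained
  climate terms. Co-correlated covariates are retained by design; the
  condition number of the standardized design is reported, and exactly
  aliased columns are an error rather than a silent drop.

## The synthetic-data generator

`simulate_seed_study()` produces every input of the pipeline with known
truth. Its defaults are fixed study conditions, chosen once:

* 108 species — 87 native (60 Csa, 6 BSh, 20 BWh, 1 BSk), 7 weeds, 14
  crops — on a birth–death tree (rphylo, conditioned on the tip count)
  rescaled to 160.5 Myr.
* log₁₀ mass is Brownian with marginal SD 0.8 around 0.7 (≈ 5 mg
  median, four orders of magnitude across species); SMR follows
  a = 0.057, b = 0.75 with residuals of SD 0.5 log₁₀ units carrying
  λ = 0.6 — the regime of a modest-R² seed allometry.
* crops receive +0.5 log₁₀ units of residual SMR (domestication
  priming); native classes receive ordered shifts 0/0.25/0.5
  (Csa/BSh/BWh) so that increasing aridity raises residual SMR.
* traces: 10 chambers per species, 30-min sampling over 48 h, initial
  pO₂ 20.6 kPa, white noise 0.05 kPa; chamber volume 1500 µl with the
  seed count (2–150) chosen to deplete ≈ 3 kPa per run; each replicate
  is contaminated with probability 0.2, multiplying its slope by 5.
* germination: each sown seed (50 per species) germinates with
  probability d/100 at a log-logistic time, scored every 3 days to day
  56 — cumulative counts are monotone by construction; crops draw from
  the fast, high-success end of the parameter ranges.
* bioclim: two blocks (9 temperature-type, 6 precipitation-type
  covariates) with within-block correlation 0.7; block means track the
  class aridity rank (temperatures up, precipitation down), so climate
  covariates correlate with the residual truth through the class
  shifts.

Every stage reseeds deterministically from (seed, stage), so each
generator operation is independently reproducible and whole bundles are
byte-stable.

What the generator does **not** emulate: measurement-temperature error,
drift or autocorrelated sensor noise, respiratory exchange ratios other
than 1, dormancy (all non-germinating seeds are simply non-germinators),
spatial structure in climate, and phylogenetic signal in mass beyond
pure Brownian motion. Passing recovery tests on these data therefore
demonstrates the correctness and calibration of the estimators under
the stated model, not robustness to every artefact of real Q₂ traces.

## Validation scales

The test suite and the acceptance script run at desk scale, chosen to
finish in minutes on one core while keeping Monte-Carlo error well
inside the asserted tolerances: 50 random 20-tip instances for the
PGLS/whitened-OLS identity (10⁻⁸); 100 replicate studies of 108 species
for slope and λ recovery; 100 replicates of 200-tip trees for K and λ
calibration under Brownian and independent traits; 2000 replicates for
the empirical size of the isometry test and the aridity contrast; and
one full study for respirometry recovery (median per-species bias and
the contamination-removal rate).

## Known limitations

* With ten replicates, species in which five or more chambers are
  contaminated (≈ 3% of species at the default rate) defeat any
  single-pass screen — no centring can identify a contaminated
  majority — and their means remain inflated; the median per-species
  bias is unaffected, but a mean bias across species persists. Users
  with higher expected contamination should raise the replicate count
  or inspect the per-replicate table attached to the SMR output.
* λ estimation assumes an ultrametric tree in the sense that the λ
  transformation preserves tip variances; strongly non-ultrametric
  trees change the interpretation of λ and are not specially handled.
* The stepwise layer inherits the usual caveats of significance-based
  selection (post-selection inference is not corrected); it mirrors the
  conventional analysis rather than a model-averaging alternative.
* The germination fit treats percentages as homoscedastic Gaussian
  observations; a binomial GLM would weight the tails differently, but
  the least-squares log-logistic is the field's standard and is what
  T₅₀ conventions reference.
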