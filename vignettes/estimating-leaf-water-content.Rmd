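---
title: "Estimating winter-wheat leaf water content from canopy reflectance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating winter-wheat leaf water content from canopy reflectance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lwcspectra)
```

## The problem

Leaf water content (LWC) — the water mass fraction of fresh leaf mass,
`(m_fresh - m_dry) / m_fresh x 100` percent — is the quantity an
irrigation manager wants to know and the quantity a field
spectroradiometer never measures directly. Canopy reflectance between
350 and 2500 nm carries the signal indirectly: liquid water absorbs
near 970, 1200, 1450 and 1940 nm, so wetter canopies show deeper
absorption dips, while better-irrigated plots also accumulate more
biomass and therefore reflect more in the near infrared (NIR,
roughly 750–1350 nm). `lwcspectra` implements the full chain from
reflectance spectra to LWC estimates:

1. **Preprocessing** — atmospheric band masking and first-derivative
   spectra (`apply_atmospheric_mask()`, `first_derivative()`).
2. **Two-band index optimization** — exhaustive R² maps of
   normalized-difference, ratio and difference indices over all band
   pairs (`pair_r2_map()`, `best_pair()`).
3. **Characteristic-band screening** — correlation-extremum selection
   (`select_bands_ca()`) and PLS x-loading-weight extrema
   (`select_bands_xlw()`).
4. **Regression** — PLSR, random forest, extremely randomized trees and
   KNN (`fit_lwc_model()`).
5. **Evaluation** — R², RMSE and RPD on a season-based
   calibration/validation split (`run_comparison()`).

Because no suitable public dataset pairs 1-nm canopy spectra with
plot-level wheat LWC under a factorial irrigation design, the package
ships a synthetic generator (`simulate_dataset()`) that emulates such a
trial with known ground truth. Every stage of the pipeline is validated
against that generator.

## The synthetic irrigation trial

The generator reproduces the *statistical* structure of a two-season
field experiment: 7 cultivars × 3 irrigation treatments × 6 sampling
dates × 2 seasons = 252 samples, 126 per season.

**LWC trajectories.** Mean LWC per treatment × date follows a
rise-then-fall curve: it peaks at the second sampling date (shortly
after the jointing-stage irrigation) and declines as the crop senesces.
Treatments diverge late in the season — the twice-irrigated `w2` stays
wettest, the rain-fed `w0` driest, strictly ordered at the final date.
The default table spans 57–88 %, chosen so that summary statistics are
on the scale typical of winter wheat (field studies report roughly
56–89 % with a mean near 79 %). On top of the table the generator adds
a cultivar-by-season random intercept (SD 1 %) and a per-sample
residual (SD 1 %); both defaults are modest because plot-averaged LWC
in managed trials varies far less than leaf-to-leaf measurements.

**Spectra.** Each spectrum is a phenomenological shape model, not a
radiative-transfer simulation: a low visible baseline with a green
peak at 550 nm, a logistic red-edge rise centred at 720 nm to a NIR
plateau of 0.45 × biomass, a smoothly declining SWIR baseline, minus
Gaussian water-absorption dips at 970/1200/1450/1940 nm whose depths
grow linearly with canopy water (LWC × biomass; depth coefficient 0.20
per unit, with the 1450 and 1940 nm features strongest), plus additive
Gaussian noise (SD 0.005, the magnitude of a well-calibrated field
instrument after plot averaging). The biomass factor grows over the
season at a treatment-dependent rate (`w2 > w1 > w0`), so NIR
reflectance orders with irrigation by construction. All reflectance is
clipped to [0, 1]; a configuration that clips more than half the grid
is rejected as unphysical.

**What the generator does *not* emulate** — and therefore what passing
tests cannot show about real data: soil background and view-geometry
effects, instrument-specific noise spectra, covariance between
neighbouring bands beyond the smooth shape components, cultivar-specific
spectral signatures, and any genuine radiative transfer. Results on
synthetic data demonstrate that the algorithms recover structure they
were pointed at; transfer to field spectra must be established on field
spectra.

## Conventions and numerical choices

**Reflectance units.** Internally always a fraction in [0, 1]; percent
only at CSV boundaries. Ratio-type indices would be scale-invariant
either way, but difference indices and derivatives are not, and a single
convention removes the factor-of-100 failure mode.

**Atmospheric mask.** The default windows 1350–1400, 1800–1950 and
2450–2500 nm are excluded with the half-open convention `(low, high]`
(lower endpoint retained). On the 2151-band grid this retains exactly
1901 bands. The endpoint convention is a deliberate package choice:
among the nearby alternatives (inclusive–inclusive gives 1898) only the
half-open rule reproduces the 1901-band accounting used in comparable
full-band analyses, and it composes idempotently.

**Derivatives.** Central differences with one-sided endpoints, computed
independently per contiguous grid segment so no difference ever spans a
mask gap. The grid's native step is inferred as the smallest spacing, so
thinned (coarse-stride) grids segment correctly too.

**Two-band R².** The map cell for (λ1, λ2) is the squared Pearson
correlation between the per-sample index and LWC — identical to the R²
of a univariate linear fit of LWC on the index. The difference form is
computed in closed form from the band covariance matrix; the normalized
and ratio forms stream one reference band against all others. Symmetric
kinds compute one triangle and mirror it. Undefined samples
(zero denominators) are flagged and excluded pairwise with counts
reported; cells with fewer than 3 valid samples or zero index variance
are missing, never zero.

**Extremum detection.** A band is a peak (trough) if it strictly
dominates every band within a ±10-band window inside its contiguous
segment; plateaus report their leftmost band. 10 bands ≈ 10 nm, wide
enough to suppress noise-level wiggles at a 3–10 nm instrument
resolution while keeping adjacent water features separable. The window
is a parameter everywhere it is used.

**CA selection count.** Correlation-extremum screening seeds from the
extrema of |r| and then adjusts deterministically to an explicit
`n_target` (default 100): excess seeds are pruned by |r|, shortfalls are
topped up from the remaining bands by |r| subject to a minimum
2-band separation. No published rule fixes the count, so the package
makes it a parameter with a reproducible tie-break (smaller wavelength
wins).

**PLS.** PLS1 via NIPALS with mean-centring only — unit-variance
scaling is deliberately off, since reflectance bands share units and
scaling would inflate noisy SWIR bands. Loading-weight vectors are
sign-oriented so the largest-magnitude element is positive, making
peak/trough positions reproducible. Component counts for prediction are
chosen by minimum leave-one-out RMSEP, capped at `min(20, n - 2)`;
the x-Lw screen defaults to the first 3 components, selectable by the
RMSEP curve that `fit_pls_loadings()` reports. With all components on
full-rank data the fit reproduces ordinary least squares, which the test
suite uses as an oracle.

**Tree ensembles and KNN.** Random forest: 500 trees, `sqrt(p)` features
per split, bootstrap resampling. Extremely randomized trees: same size,
but *no* bootstrap (every tree sees the whole training set) and a single
random split threshold per candidate feature. Both run through `ranger`
with a fixed seed and one thread, so fits are bit-reproducible. KNN uses
Euclidean distance with fixed k = 3 by default; a seeded 5-fold CV
selector over k = 1..15 is available. Predictors are never standardized
for tree/KNN models — all bands share the reflectance scale.

**Evaluation.** Validation R² is `1 - SS_res/SS_tot` on out-of-sample
predictions (not squared correlation; the two differ out of sample).
RPD uses the sample (n − 1) SD by default, the convention of the
spectroscopy literature that introduced the 1.4 adequacy threshold; a
population-SD variant is exposed. Band screening inside
`run_comparison()` sees calibration-season data only — the leakage-free
default — with an explicitly labelled `pooled_selection` escape hatch.

## Problem sizes

The shipped tests and the acceptance script exercise the pipeline on the
default 252-sample design with the retained grid thinned to a 4 nm
stride (476 bands) — the grain at which every stage (exhaustive pair
search, LOO-validated PLS, 500-tree ensembles) runs comfortably on a
single CPU while preserving all the structure the assertions probe.
Oracle-equivalence checks run exhaustively on 5–10 band instances, where
a naive per-pair loop is feasible. Nothing in the implementation is
specific to these sizes; `pair_r2_map()` on the full 1901-band grid is a
closed-form covariance computation for the difference kind and a ~30 s
streamed loop for the other two.

## Known limitations

* The generator's absorption dips are additive Gaussians on a smooth
  baseline; real water features are asymmetric and sit on
  structure-dependent continua. Band positions recovered on synthetic
  data validate the *search*, not wheat physiology.
* `INDEX_SLR` and the pair search assume a linear index–LWC relation;
  saturating relations (common at high canopy cover) would need a
  nonlinear link.
* The year-based split assumes seasons are exchangeable; systematic
  inter-season instrument drift is not modelled.
* PLS component selection by LOO RMSEP is conservative at small n and
  can underfit when fewer than ~15 samples are available.

## A complete run

```{r pipeline, eval = FALSE}
cfg <- synthetic_config(seed = 20180101)
sim <- simulate_dataset(cfg)
spectra <- thin_bands(apply_atmospheric_mask(sim$spectra), 4L)

split <- year_split(spectra)
dvi <- pair_r2_map(split$calibration, kind = "difference")
best_pair(dvi, top_k = 3)

tab <- run_comparison(spectra)
tab
```
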