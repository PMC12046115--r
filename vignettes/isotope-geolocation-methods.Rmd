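---
title: "Methods: tissue isoscapes, residual bias correction, and assignment quality"
author: "isogeoloc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tissue isoscapes, residual bias correction, and assignment quality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isogeoloc)
```

## The problem

Stable isotope ratios in human tissues record the environment in which the
tissue grew: oxygen in hair keratin and tooth-enamel bioapatite derives
largely from local drinking water, and strontium in enamel from local
bioavailable sources. Because both δ¹⁸O in water and ⁸⁷Sr/⁸⁶Sr in substrate
vary geographically in predictable ways, a measured tissue value carries
information about where a person lived while the tissue formed — the basis
of isotope-assisted forensic geolocation.

Reference compilations assembled from many published studies are noisy in
specific, diagnosable ways: studies use different laboratory pretreatments
and calibration materials, sample different dental elements (which
mineralize at different childhood ages, under changing diet and
physiology), and differ in whether the origin of a sample is documented
("known") or inferred from the collection location ("assumed"). This
package implements the full chain needed to compile such data, relate them
to environmental isoscapes, diagnose and remove systematic biases, and
quantify what the data can actually deliver for geographic assignment.

## The model

### Tissue–environment calibration

For records with tissue value $y_i$ at origin $x_i$, and an environmental
isoscape $e(\cdot)$, we fit the weighted linear model

$$y_i = \alpha + \beta\, e(x_i) + r_i, \qquad
\hat{(\alpha,\beta)} = \arg\min \sum_i w_i r_i^2 .$$

Two weighting policies are exposed. The default, `"site_density"`, weights
each record by the inverse of the number of records at its site, so a
single heavily sampled city cannot dominate a continental fit; `"unit"`
weights recover ordinary least squares. Reported summaries are the weighted
$R^2 = 1 - \mathrm{SSE}_w/\mathrm{SST}_w$ and the residual standard error
$\mathrm{RSE} = \sqrt{\mathrm{SSE}_w/(n-2)}$.

The OLS slope of such regressions is attenuated whenever the predictor
carries error (isoscape prediction error, origin error), so we also provide
the reduced-major-axis slope, $\mathrm{sign}(\rho)\,s_y/s_x$, appropriate
when the two error magnitudes are comparable.

### The tap-water isoscape

Human drinking water is tap water, which deviates from precipitation in
ways that are smooth in space (reservoir mixing, groundwater lags,
inter-basin transfers). The tap-water δ¹⁸O surface is therefore built by
*difference kriging*: compute $d_j = \text{tap}_j - \text{base}(x_j)$ at
each tap observation site, interpolate $d$ over the grid by ordinary
kriging, and add the interpolated difference back to the base
precipitation surface. Where the difference field is well sampled the
surface honors local tap observations; far from data it relaxes to the
base surface plus the fitted mean offset.

Ordinary kriging uses an isotropic semivariogram (exponential by default;
spherical and Gaussian available) fitted to the binned empirical
semivariances by weighted least squares with the customary
$n_\text{pairs}/h^2$ weights. The fit is profiled — for fixed range the
model is linear in (nugget, partial sill) and solved in closed form with
non-negativity clamping; the range is found by a log-spaced grid search
plus golden-section refinement — which is considerably more robust than a
joint nonlinear optimization on this poorly scaled objective. Optimizer
failure falls back to a pure-nugget model with a warning.

Two deliberate simplifications: distances are great-circle kilometres but
the kriging system treats them as planar (adequate at continental scale,
increasingly wrong near the poles or for global grids), and observation
coordinates are snapped to the centers of the grid cells containing them
(duplicates averaged). Snapping makes the zero-nugget exact-interpolation
property hold exactly at each observation's cell — the natural resolution
of statements about a gridded product — at the cost of sub-cell positional
information, which a raster cannot represent anyway.

### Residual diagnostics and bias correction

Residuals $r_i = y_i - \hat\alpha - \hat\beta e(x_i)$ isolate the
non-geographic structure. Three hypotheses each reduce to one test:

1. *Origin quality*: assumed-origin records should show wider residual
   dispersion than known-origin records — Levene's test
   (Brown–Forsythe median centering by default) over `origin_status`.
2. *Laboratory methods*: studies with different pretreatment/calibration
   should show offset mean residuals — one-way ANOVA over `study_id`.
3. *Tooth mineralization age*: teeth formed at different childhood stages
   should show offset mean residuals — ANOVA over `tooth_group`, with the
   heterogeneous `"Unknown"` group excluded by default.

The bias correction subtracts each group's mean residual from its records.
Note what is identifiable: because the regression fits an intercept, the
record-weighted mean of the group biases is absorbed into $\hat\alpha$, and
the corrections estimate each group's offset *relative to that mean*, not
the absolute injected offsets. Recomputing residuals under the same
coefficients after correction yields group means of exactly zero; a refit
changes the coefficients slightly, so refit group means are only
approximately zero. Corrections are estimated and applied on the same
dataset by default, matching common compilation practice; this is an
in-sample correction and the split-sample QA is the honest measure of
whether it helps out-of-sample.

Keratin δ¹⁸O data calibrated against different in-house reference
materials are made comparable by linear reference-scale transforms
(`common = gain × value + offset`) supplied by the user; scales without
coefficients raise an error rather than guessing, so unidentifiable
samples are excluded explicitly.

### Geographic assignment and its quality

For one observation $y$ and a tissue isoscape with cell means $\mu_i$ and
standard deviations $\sigma_i$, the posterior surface is the normal
likelihood $f_i = \phi((y-\mu_i)/\sigma_i)/\sigma_i$ normalized by the
area-weighted sum, $\sum_i p_i a_i = 1$, with $a_i \propto \cos(\text{lat}_i)$
because lon/lat cells shrink poleward and "10% of the area" is a statement
about surface area, not cell count. The tissue-isoscape sd is the fit RSE,
spatially constant; a hook exists to add environmental-surface uncertainty
in quadrature, but no per-cell combination rule is imposed by default. A
small floor (`min_sd = 1e-6`) keeps posteriors defined for degenerate
perfect fits.

The assignment region at area quantile $q$ is the smallest
highest-density prefix of cells whose cumulative area reaches $q$; ties in
density are broken deterministically by row-major cell index.

The quality assessment (`qa()`) is an iterated split-sample experiment:
per iteration, records are split at random (record-level by default;
site-level splitting is available to probe spatial leakage), the
calibration subset fits the regression and tissue isoscape, and each
validation sample is scored by the smallest $q$ at which the cell
containing its reported origin enters the assignment region. The accuracy
curve $A(q)$ — the fraction of validation samples captured at each $q$ —
is then an empirical CDF: monotone, $A(1) = 1$, and for data with no
geographic information $A(q) \approx q$ (the random-assignment diagonal).
"Correct" means the origin *cell* is inside the region; no distance buffer
is applied.

## The synthetic-data generator

All tests and the shipped acceptance experiment run on synthetic data whose
structure mirrors what the analysis assumes: a smooth spatially
autocorrelated environmental field (a seeded superposition of low-frequency
cosine components, rescaled to a target range — light-weight, fully
deterministic per seed, with lag-1 autocorrelation verified rather than
assumed); sites drawn uniformly over cells; tissue values
$y = \alpha + \beta e + \text{bias}_\text{study} +
\text{offset}_\text{tooth} + \varepsilon$; and an optional fraction of
assumed-origin records whose recorded coordinate is displaced by an
exponentially distributed great-circle distance in a uniform direction.

Preset scenarios carry the fitted relationships reported for the North
American compilation: transformed hair δ¹⁸O (slope 0.35 — the body-water
model expectation that hair expresses about 35% of regional tap-water
variation — RSE 1.5‰), enamel carbonate δ¹⁸O (slope 0.43, RSE 1.6‰), and
enamel ⁸⁷Sr/⁸⁶Sr (slope 0.53, residual sd 0.0014). Where a quantity is not
reported (e.g., the Sr residual scale), we chose a value between the
published origin-status dispersions once and did not revisit it. Default
problem sizes — a 40×60 grid over mid-latitude North America, 120–150
sites at 3–4 records each (~360–600 records), 10 QA iterations with a 25%
hold-out over a 0.01-step area-quantile grid — were chosen as the smallest
sizes at which the estimators' sampling error is well below the effects
being measured.

What the generator does *not* emulate — and therefore what passing tests
do not establish about real data: spatially clustered and transect-style
sampling, non-Gaussian residuals, spatially correlated isoscape prediction
error, within-individual correlation across tissues, and realistic
migration histories (the displacement kernel creates origin error, it does
not model human mobility). Synthetic results demonstrate the estimators'
correctness and calibration, not the field performance of any particular
compilation.

## Numerical choices and edge cases

- Cells are half-open; points on a shared edge belong to the cell
  east/south of it, and the raster's own north/west edge belongs to the
  first row/column. Extraction is cell-value, never bilinear.
- Nodata cells are `NA` internally, excluded from every statistic, carry
  no posterior mass, and propagate through raster arithmetic.
- Rasters are read and written as ESRI ASCII grids — a plain-text,
  single-band format that round-trips exactly at the stored precision and
  respects the nodata tag. The format requires square cells; rectangular
  grids are supported in memory only.
- Kriging systems are solved densely with a factor-once, solve-all-cells
  path up to 64 observations, and a 64-nearest-neighbor local solve
  beyond; a singular system (after duplicate averaging) gets a tiny
  diagonal jitter.
- Degenerate inputs fail loudly: coincident variogram points, constant
  environmental rasters, all-zero-spread variance tests, < 3 usable tap
  points, out-of-range Shapiro–Wilk sizes. Zero within-group variance
  with unequal means reports an infinite-F sentinel with p = 0 rather
  than an error.
- All randomness (generator, QA splits) is seeded explicitly and restored
  on exit, so every result is a pure function of its inputs and seed.

## Known limitations

- Planar kriging on great-circle distances; no anisotropy, no
  regression-kriging with covariates.
- The constant-RSE tissue-isoscape sd understates uncertainty where the
  environmental surface is itself poorly constrained.
- Single-analyte assignment only; no joint multi-isotope posteriors.
- The bias correction assumes group offsets are additive and constant in
  space; a study whose bias covaries with climate would be only partially
  removed.
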