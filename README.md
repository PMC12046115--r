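# isogeoloc

Isotope-based forensic geolocation from human-tissue reference data.

Compilations of published human-tissue isotope measurements — δ¹⁸O in hair
keratin and tooth-enamel bioapatite, ⁸⁷Sr/⁸⁶Sr in enamel — are the
reference backbone of isotope-assisted geolocation: a measured value from
an unknown individual is compared against the expected tissue value at
every location to map where that individual plausibly lived while the
tissue grew. Such compilations mix studies with different laboratory
pretreatments, calibration materials, dental elements and origin
documentation, and those differences inject systematic, non-geographic
biases that erode assignment accuracy. `isogeoloc` provides the complete,
tested pipeline for working with this kind of data:

- **Data model** — a validating loader for tissue isotope compilations
  (schema remapping, VPDB→VSMOW and phosphate→carbonate normalization,
  dental-element → mineralization-age grouping, row-level rejection
  diagnostics).
- **Isoscapes** — a raster container with ESRI ASCII grid I/O, empirical
  variograms, weighted variogram fitting, ordinary kriging, and tap-water
  isoscape construction by kriging tap-minus-precipitation differences.
- **Calibration** — the tissue–environment weighted regression
  `y = α + β·e(x) + r` behind tissue isoscapes, plus reduced-major-axis
  slopes for error-in-x settings.
- **Diagnostics** — residual hypothesis tests: Levene/Brown–Forsythe
  variance comparisons (origin quality), one-way ANOVA offsets by study
  and by tooth mineralization-age group, Shapiro–Wilk normality.
- **Bias correction** — group-mean residual corrections and linear
  keratin reference-scale transforms onto a common VSMOW frame.
- **Assignment QA** — area-normalized posterior surfaces, highest-density
  assignment regions, and an iterated split-sample quality assessment
  yielding accuracy-versus-area-quantile curves.
- **Synthetic data** — a seeded generator reproducing the assumed
  data-generating structure (smooth autocorrelated field, affine tissue
  response, study/tooth offsets, displaced assumed origins), so the whole
  pipeline is testable offline.

The core statistic throughout is the calibration residual
`r_i = y_i − α̂ − β̂·e(x_i)`: group structure in residual means reveals
laboratory or physiological bias, group structure in residual spread
reveals origin-information quality, and subtracting group-mean residuals
("bias correction") measurably sharpens geographic assignment.

## Worked example

Simulate a three-study tooth-enamel δ¹⁸O compilation with ±1.5‰ laboratory
biases, diagnose and remove them, and measure the effect on assignment:

```r
library(isogeoloc)

sc  <- synthetic_scenario(seed = 42, slope = 0.43, intercept = 29.4,
                          noise_sd = 1, tissue = "tooth_enamel",
                          analyte = "oxygen",
                          study_biases = c(LabA = 1.5, LabB = 0, LabC = -1.5),
                          n_sites = 120, n_per_site = 4)
env <- synth_raster(sc)
d   <- synth_dataset(sc, env)

fit <- calibrate(d, env)
#> <calibration_fit> y = 29.15 + 0.4089 * e  (n = 480, R2 = 0.538, RSE = 0.79)

summarize_residuals(fit, "study_id")
#>   group_id   n mean_residual sd_residual
#> 1     LabA 157    1.57489145   1.0184779
#> 2     LabB 144   -0.02251341   1.0322150
#> 3     LabC 179   -1.36321802   0.9412697

bt <- build_bias_table(fit, "study_id")
d2 <- apply_bias_correction(d, bt, "study_id")

qa(d,  env, n_iterations = 10, seed = 1)
#>   accuracy at 10% area: 20.6%
qa(d2, env, n_iterations = 10, seed = 1)
#>   accuracy at 10% area: 32.5%
```

The recovered regression (slope 0.41 vs. the injected 0.43) and the
per-study mean residuals (+1.57, −0.02, −1.36‰, estimating the injected
offsets relative to their record-weighted mean) feed a bias table whose
application raises the fraction of validation samples correctly assigned
within the most likely 10% of the study area from 20.6% to 32.5% — the
between-study ANOVA drops from F(2, 477) = 365 to ≈ 0 after correction.

Real compilations enter the same pipeline through
`load_dataset("compilation.csv", schema = ...)`, with environmental
surfaces from `read_ascii_grid()` or built by
`build_tapwater_isoscape(base, tap_lon, tap_lat, tap_values)`.

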