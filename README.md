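# attfield

Dynamic estimation of the spatial attentional field from visual cortical
activity.

## The problem

Covert spatial attention acts like a spotlight: it boosts visuocortical
responses at the attended location, and its *size* can adapt to task
demands. `attfield` implements a model-based pipeline that recovers the
location and spread of that spotlight from fMRI responses in early visual
cortex (V1–V3), block by block:

1. Voxels with population receptive fields (pRFs) overlapping an
   iso-eccentric stimulus annulus are selected and sorted by their
   preferred polar angle.
2. Blockwise BOLD responses (percent signal change, high-pass detrended,
   averaged over a hemodynamically lagged 10-TR window) are collapsed into
   a 1D spatial profile: the median response in each of 60 polar-angle
   bins (6° each), recentered on the cue and smoothed with an 18° circular
   moving average.
3. A scaled, offset **generalized Gaussian** is fitted to each profile.

The model, in the field's standard notation, is

    G(x)  = exp{ −( d(x, μ) / σ )^β }          d = wrapped angular distance
    ŷ(x)  = a · NormGG(x) + b                  NormGG = min-max normalized G

with location μ (deg polar angle), scale σ ∈ [6°, 180°], shape
β ∈ [1.8, 50] (Laplace-like tails below 2, boxcar-like above), gain
a ∈ [0, 20] %-signal-change, and free baseline b. Fitting minimizes the
squared error over the 60 bins from a 6 × 6 grid-search initialization
(μ ∈ {0°, …, 300°} × σ ∈ [9°, 162°], β = 4, a = 1, b = 0), with μ wrapped
to [0°, 360°). Each fit is summarized by

* **FWHM** = 2σ(ln 2)^(1/β) — the width of the attentional field,
* **angular error** — wrapped signed difference between μ̂ and the cue
  center, in (−180°, 180°],
* **R²** — explained variance of the spatial profile (may be negative).

Because no fMRI recordings ship with the package, a fully seeded
block-design simulator (`build_cue_schedule()`, `simulate_prf_table()`,
`simulate_timeseries()`) generates voxel tables and raw time series with a
*known* ground-truth field, so every stage is validated by parameter
recovery. Group-level tools (`exclude_low_r2()`, `slope_test()`,
`paired_comparison()`, `accuracy_vs_chance()`) mirror the statistics used
to interpret such fits.

## Worked example

Fit the model to a noisy profile with a known field:

```r
library(attfield)
set.seed(1)
truth <- list(mu = 162, sigma = 75, beta = 4, gain = 1.1, baseline = -0.2)
y <- predict_profile(truth, profile_bin_centers()) + rnorm(60, 0, 0.08)
fit <- attfield_fit(spatial_profile(y), true_center = 162)
fit
#> Attentional-field fit (generalized Gaussian)
#>   location mu        161.88 deg
#>   FWHM               137.79 deg  (sigma 75.02, beta 4.30, closed)
#>   gain                1.075 %sc
#>   baseline           -0.184 %sc
#>   R-squared           0.979
#>   angular error       -0.12 deg (|.| = 0.12)
```

The fitted location lands 0.12° from the true cue center; the FWHM of
137.8° corresponds to the true σ = 75, β = 4 (2·75·(ln 2)^{1/4} ≈ 137.7);
and gain/baseline recover the imposed 1.1 / −0.2 percent signal change.
`coef()`, `predict()`, `residuals()`, `plot()` and `simulate()` behave as
for any fitted R model.

The full simulate → preprocess → profile → fit pipeline, with ground-truth
diagnostics:

```r
rep <- run_pipeline(pipeline_config(n_runs = 2, noise_sd = 3, seed = 1))
rep
#> attfield pipeline report: 120 fits ( 1 subject(s) x 40 blocks x 3 ROIs x 1 TR level(s))
#>   median |angular error| 5.17 deg; median |FWHM error| 15.36 deg; mean R2 0.732
```

At the default single-voxel noise level (3% signal change per TR) the cued
location is recovered to ~5° median error — far below the 90° chance
level — while single-block width estimates scatter by ~15° around the true
FWHM; per-condition medians are much tighter (see the vignette).

## Package layout

* `R/paradigm.R`, `R/simulate.R` — task design and synthetic data with
  ground truth
* `R/preprocess.R` — percent signal change, DCT high-pass detrending,
  baseline referencing, block averaging (with TR subsampling)
* `R/profiles.R` — voxel selection, 1D circular profiles, 2D visual-field
  maps
* `R/fit.R`, `R/gengauss.R` — the generalized Gaussian model and the
  `attfield` fit object
* `R/group-stats.R` — exclusion rule, slope tests, paired tests, accuracy
  vs chance
* `R/pipeline.R`, `R/io.R` — the end-to-end driver and TSV/JSON/YAML
  interchange

See `vignettes/attentional-field-estimation.Rmd` for the methods account:
model assumptions, simulator design, numerical choices, and limitations.
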