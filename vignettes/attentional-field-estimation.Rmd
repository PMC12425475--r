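---
title: "Estimating the spatial attentional field from visual cortical activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the spatial attentional field from visual cortical activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(attfield)
```

## The model

Covert spatial attention modulates visuocortical responses in a spatially
tuned way: responses rise at the attended location and fall off with
distance from it. When the stimulated region is an iso-eccentric annulus,
the modulation can be treated as a function of polar angle alone, which
reduces the attentional field to a one-dimensional profile on the circle.

`attfield` models that profile with a generalized Gaussian (exponential
power) curve,

$$G(x) = \exp\left\{-\left(\frac{d(x,\mu)}{\sigma}\right)^{\beta}\right\},$$

where $d(x,\mu)$ is the *wrapped* angular distance (the domain is
physically circular, so the curve must wrap at 0/360°), $\mu$ is the field
center, $\sigma$ the scale, and $\beta$ the shape. The family spans
heavy-tailed Laplace-like profiles ($\beta < 2$), the Gaussian
($\beta = 2$), and increasingly boxcar-like shapes as
$\beta \to \infty$ — a single parametric family covering a narrow
spotlight through a wide, flat-topped swath. $G$ is min-max normalized
over the 60 evaluated bin centers and affinely mapped onto the data:

$$\hat y(x) = a \cdot \mathrm{NormGG}(x) + b.$$

Under this normalization convention the gain $a$ is the peak-to-trough
modulation depth (percent signal change) and $b$ is the trough level.
The fitted curve is summarized by the full width at half maximum,
$\mathrm{FWHM} = 2\sigma(\ln 2)^{1/\beta}$ (capped at 360°), by the
wrapped signed angular error of $\hat\mu$ against the cue center, and by
the explained variance $R^2 = 1 - \sum(y-\hat y)^2 / \sum(y-\bar y)^2$,
which may be negative for fits worse than the mean.

### Fitting

The five parameters are estimated by bounded least squares over the 60
profile bins. To avoid local minima, a 6 × 6 grid search over
$\mu \in \{0°, 60°, \ldots, 300°\}$ and $\sigma$ equally spaced on
[9°, 162°] (with $\beta = 4$, $a = 1$, $b = 0$) picks the
lowest-SSE starting point; ties go to the earliest candidate in
(location, scale) order. A quasi-Newton box-constrained search
(`optim`, L-BFGS-B; SSE convergence factor `factr = 1e4`, at most 500
iterations) then refines it under $\sigma \in [6°, 180°]$,
$\beta \in [1.8, 50]$, $a \in [0, 20]$, unbounded $b$ and unbounded
$\mu$ — the objective is circular in $\mu$, so there is no 0/360°
discontinuity, and $\hat\mu$ is wrapped to $[0°, 360°)$ afterwards.
Numerical guards: parameters are snapped back into the box if the
optimizer ends a floating-point ulp outside it; a search that fails or
ends above the initialization SSE falls back to the grid candidate and is
flagged (`optim_failure`); a (near-)zero-variance profile short-circuits
to a flagged degenerate fit with zero gain. Exactly antipodal angular
errors are assigned +180° by convention.

Two FWHM conventions are provided. The default (`"closed"`) applies the
closed form to the unnormalized curve. The alternative (`"normalized"`)
measures the half-height width of the min-max normalized curve over the
grid; the two agree whenever the curve's minimum over the grid is near
zero and diverge for very broad fields. The closed form is the default
because it is a function of $(\sigma, \beta)$ alone and does not inherit
the grid.

## The pipeline

`run_pipeline()` chains the stages in a fixed order: block-average →
bin → recenter → smooth → fit.

* **Voxel selection.** Retained voxels need a preferred eccentricity
  within the pRF-mapping stimulus bounds (0.7–9.1°), a pRF size of at
  least 0.01°, a pRF model fit $R^2 \ge 0.10$, and pRF overlap with the
  stimulus annulus (preferred eccentricity inside the annulus, or within
  one pRF size of it).
* **Percent signal change.** $100\,(y - \bar y)/\bar y$ per voxel per
  run. (Detrending is applied after the conversion: a mean-removing
  filter leaves nothing to divide by, and since both operations are
  affine per voxel the order is otherwise immaterial.)
* **High-pass detrending.** Discrete-cosine basis regression up to the
  0.005 Hz cutoff, plus an explicit linear trend term so ramp-like drift
  is removed exactly, per run. Because each block's cue is unique within
  a run, the design's spectrum extends below any practical cutoff; the
  pipeline therefore orthogonalizes the drift basis against the lagged
  block indicators (`protect =` in `highpass_detrend()`) — the standard
  GLM treatment of nuisance regressors — so drift is removed without
  eating block-locked signal.
* **Baseline referencing.** Percent signal change centers each voxel on
  its run mean, which includes the task modulation itself; the
  unmodulated baseline TRs of a run consequently sit below zero by the
  voxel's mean modulation — a spatially structured background.
  `reference_to_baseline()` subtracts the per-voxel mean over task-free
  TRs, cancelling the background exactly.
* **Block averaging.** Mean over the 10-TR block window shifted by 3 TRs
  (4.65 s) to compensate for the hemodynamic delay. For
  temporal-interval analyses, 1/2/3/5 TRs are drawn uniformly without
  replacement from that window (one seeded draw per block). Windows that
  would overrun the run end are truncated with a warning.
* **1D profile.** 60 polar-angle bins with half-open edges
  $[6k°, 6k°+6°)$, median response per bin (robust to a minority of
  outlying voxels). Bins left empty by an undersampled pRF table are
  filled by circular linear interpolation and flagged; more than 20%
  empty bins is an error. The profile is recentered on the cue (an exact
  circular rotation; all cue centers are integer multiples of the bin
  width) and smoothed with an 18° (3-bin) circular moving average, which
  conserves the profile mean exactly. Smoothing can be disabled
  (`smooth = FALSE`); it slightly widens narrow profiles, but its effect
  on recovered FWHM at realistic field widths is below the estimator's
  own sampling variability, so the default keeps it on.
* **2D maps.** `reconstruct_field_2d()` projects block responses to pRF
  positions in the visual field, rotates the cue to the right horizontal
  meridian, interpolates by Gaussian-kernel local averaging, and
  z-scores the defined cells. These maps are for visualization and
  quality control only; all model fitting consumes the 1D profiles.

### Group statistics

Blocks are excluded by pooled fit quality: the unweighted mean $R^2$
across V1, V2, and V3 per block, with the lowest 20% (floor, ties broken
by block id) dropped — per subject, and per TR-count level when several
are analyzed. Metric-on-width effects are tested by per-subject ordinary
least squares over block-level values (maximizing within-subject degrees
of freedom) followed by a two-sided one-sample t-test of the subject
slopes against zero; temporal-interval analyses add the TR count as a
second regressor. No multiple-comparison correction is applied by
default — the per-ROI tests are treated as separate questions — but
`bonferroni_threshold()` reports the 0.05/3 ≈ 0.017 threshold that would
correct across the three ROIs. The chance reference for the absolute
angular error is 90°, verified by Monte Carlo in
`chance_error_reference()`.

## The simulator

The synthetic-data module emulates the block-design attention paradigm:
a 20-bin (18° per bin) annulus, cue widths of 18/54/90/162° (plus 126°
and cardinal-only centers in the contrast variant, with a σ = 15°
Gaussian edge rolloff), 5-trial blocks of 10 TRs (TR = 1.55 s), 100
trials per run, and 15.5 s of baseline at both ends of each 341 s
(220 TR) run. Cued bins carry exact letter/number majority ratios
(1 bin: single item; 3 bins: 2:1; 5 bins: 3:2; 9 bins: 6:3). Cue centers
per width are placed on an evenly spaced lattice (72° apart) with a
random rotation per width per run: this balances stimulation over polar
angle within each run — the standard way block designs are balanced —
and keeps the run-mean modulation flat in angle, so percent-signal-change
conversion does not imprint a spatial background on the block profiles.

Ground truth per block: the field is centered on the cue, and its FWHM
interpolates linearly from 103° at the narrowest cue to 179° at the
widest — the attentional field is substantially broader than the cue
itself, as observed empirically for covert attention. Shape
$\beta = 4$, gain 1 percent signal change (scaled by ROI: 0.8/1.0/1.2
for V1/V2/V3, so modulation strengthens up the visual hierarchy),
baseline 0. Raw signal is $S_0(1 + m/100)$ with $S_0 = 1000$ arbitrary
units, so percent-signal-change conversion is exercised nontrivially.
Noise is i.i.d. Gaussian per voxel-TR with sd 3 (percent-signal-change
units, a typical single-voxel level at 3 T); an optional AR(1)
coefficient adds temporal autocorrelation at the same stationary sd.
The hemodynamic delay is a pure 3-TR shift with no HRF convolution,
matching the shift-and-average analysis. Simulated pRF tables draw
polar angles uniformly (re-drawn until all sixty 6° bins are occupied),
concentrate eccentricities near the annulus with a broad uniform
component over 0.5–9.5°, grow pRF size with eccentricity (steeper up
the hierarchy), and can inject a configurable fraction of voxels
violating each selection rule to exercise the filters.

What the simulator does **not** emulate: the shape of the hemodynamic
response (onset ramps, undershoot), spatially correlated and
physiological noise, pRF estimation error, eccentricity-dependent
modulation, stimulus rendering, and eye movements. Passing recovery
tests therefore demonstrate the estimator's correctness under the stated
generative model, not performance on real recordings — empirical error
levels on real data are governed by noise structure the simulator
deliberately keeps simple.

## Validation by parameter recovery

The test suite validates the pipeline end to end (problem sizes chosen
to keep the default test run light):

* **Noise-free recovery** (2 runs, 600 voxels per ROI): every block's
  estimated location lands within one 6° bin of the cue, and the
  per-condition FWHM estimate — the median across a width's blocks, the
  way parameter distributions are summarized per condition — is within
  2° of the true field width in every ROI. Single-block FWHM at this
  voxel count carries ~1–2.5° of sampling jitter from binning (the
  median of a handful of voxels per bin), which is a property of the
  generator size, not of the estimator.
* **Recovery at the default noise level** (40 runs, 200 blocks per
  width, one ROI): median absolute angular error ~5°, far below the 90°
  chance level, with per-width median FWHM strictly increasing in the
  true width.
* **Analytic oracles**: the closed-form FWHM agrees with a brute-force
  half-maximum search within 0.1° over the full bounds grid; the
  Monte-Carlo chance error converges to 90°.
* **Statistical calibration**: the group slope test holds its nominal
  5% type-I error within the binomial confidence band over 500 null
  simulations.
* **Exact identities**: rotation equivariance of the fit, mean
  conservation under smoothing, invertibility of recentering, and the
  guarantee that the local search never ends above its grid
  initialization.

## Known limitations

* The model is 1D in polar angle; eccentricity-resolved estimation of
  the attentional field is out of scope.
* Point estimates only: no uncertainty intervals on the fitted
  parameters (the `simulate()` method supports parametric-bootstrap
  exploration).
* The pooled-$R^2$ exclusion rule assumes fits exist for all three ROIs
  per block.
* FWHM is capped at 360°, so extremely broad fields saturate; near the
  $\sigma$ upper bound the closed-form and normalized-curve conventions
  diverge, and the choice matters for comparisons across analyses.
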