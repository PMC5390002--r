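---
title: "Modeling fixation durations in scene viewing: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling fixation durations in scene viewing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fixdur)
```

# The scientific problem

During scene viewing the eyes alternate between fixations (a few hundred
milliseconds of stable gaze, when visual information is taken in) and
saccades. The duration of a fixation is a window onto ongoing processing:
it can reflect the difficulty of the *currently* fixated content (an
immediacy effect), leftover processing from the *previous* location (a lag
or spillover effect), and parafoveal preprocessing of the *next* location
(a successor effect). Separating these influences requires (a) local image
statistics around each fixated location, (b) a data structure that aligns
each fixation with its predecessor and successor, and (c) a regression
framework that handles crossed, unbalanced grouping by subject and scene.
`fixdur` implements all three stages plus a synthetic-data generator with
known ground truth.

# Local image features

Five per-scene maps are computed (`computeFeatureMaps()`):

* **Luminance** — sRGB is converted to CIE L\*a\*b\* (IEC 61966-2-1
  assumptions, via `grDevices::convertColor`), the L\* channel is kept and
  min–max rescaled to [0, 1] per image. A constant image has no luminance
  range; it maps to all zeros with a warning rather than NaN.
* **Edges** — 3×3 Sobel kernels (reflect padding) on the luminance map; the
  gradient magnitude is binarised at `sobelThresholdFactor` (default 4)
  times its mean, a standard automatic-threshold heuristic. The factor is
  exposed in `featureConfig()` because published analyses of this kind
  delegate the threshold to toolbox defaults that are rarely printed.
* **Clutter** — a feature-congestion measure: at each of 3 Gaussian-pyramid
  levels, colour clutter (the pooled covariance volume of a\*, b\*),
  contrast clutter (local SD of centre–surround luminance energy) and
  orientation clutter (local SD of oriented-derivative energy at four
  orientations) are computed, upsampled, channel-normalised and combined
  with weights 0.24 / 0.06 / 0.70. Exact parity with any particular
  MATLAB implementation is *not* claimed; the weights and pooling scale
  are documented and configurable, and the map is min–max rescaled to
  [0, 1].
* **Segmentation** — mean-shift filtering in the joint spatial × L\*a\*b\*
  domain (spatial bandwidth 7 px, range bandwidth 6.5 Lab units),
  connected-component labelling, and fusion of regions under 20 px into
  their most similar neighbour. These are the published defaults of the
  classic mean-shift segmenter; the edge-confidence ("synergistic")
  weighting variant is not implemented — plain mean-shift plus region
  fusion preserves the segment-count semantics that the analysis uses
  (segments per patch as an object-density surrogate).

# Patch statistics and the triplet table

Patches are circular, radius 1° of visual angle — 31 px at the reference
display (800 px spanning 25.78°). Pixel-centre geometry is used (a pixel
belongs to the mask iff its centre is within the radius), which makes every
masked statistic verifiable against a brute-force loop. Patches that cross
the image border are clipped to in-bounds pixels and flagged, rather than
discarded; the original treatment of border patches is not documented
anywhere, and clipping keeps the row count stable.

Contrast uses the *population* SD of patch luminance divided by the image
mean (the RMS-contrast convention of using raw second moments). Edge
density is logit-transformed with `0.5·ln(p/(1−p))`; exact zeros are
regularised to the smallest nonzero proportion in the analysis dataset,
computed per task (an override is available).

Triplets (n−1, n, n+1) are built per trial with the standard exclusions:
first/last fixation of a trial, durations outside 50–1000 ms,
blink-adjacent fixations (a blink anywhere in the three-fixation window
invalidates the triplet), and — for visual search — fixations from the
button press onward. Both flanking saccades must exceed 2°, which at the
reference calibration guarantees the three patches are pairwise disjoint
(two 1° circles one radius apart would overlap by 39%); the disjointness
is additionally enforced as an explicit centre-distance filter so that the
guarantee survives coarser pixel grids, where the rounded patch radius can
exceed one degree by a fraction of a pixel. The control table keeps one
row per valid fixation with saccades of *any* amplitude; the duration,
blink and boundary filters are retained for the focal fixation — a
deliberate, conservative reading of "all individual fixations", documented
here because the alternative (dropping the duration filter too) changes
the row count.

# The mixed model

The response is the natural log of fixation duration in ms. All 20 input
variables (5 features × 3 positions, plus incoming/outgoing saccade
amplitude, ΔAngle, viewing time, central distance) are z-standardised per
task — models are fit separately per task, so per-task scaling is the
consistent choice. Quadratic terms (incoming saccade, viewing time) are
squares of the standardized variable and are *not* re-standardised, so the
linear and quadratic coefficients of a centred input stay interpretable
independently of each other. With the intercept this yields 23 fixed
effects.

Random effects are zero-correlation ("zcpLMM"): every random intercept and
slope is an independent variance component. The full structure has 48
components (23 by subject, 23 by scene item, plus scene-list and
subject-group intercepts); the standard reduction — dropping the 15
by-subject image-feature slopes and both quadratic incoming-saccade
slopes — leaves 31. For orientation: a *maximal* correlated structure over
23 terms would need n(n+1)/2 = 276 parameters per factor (253 of them
correlations), 554 in total, which is far beyond what such data can
identify and is the reason the zero-correlation form is used.

Fitting is delegated to `lme4::lmer`, with each random term entered as its
own `(0 + term | factor)` block — exactly the zero-correlation constraint.
`lme4` is the de-facto standard fitter for crossed random effects in this
field; correctness of the wrapper is pinned by known-answer tests rather
than by trusting any backend: the noiseless limit must reproduce ordinary
least squares to 1e-6, balanced one-way variance components must equal the
closed-form ANOVA (method-of-moments) estimators, and a Monte-Carlo
recovery experiment must produce calibrated interval coverage. Singular
fits (variance components estimated at zero) are expected and are not
errors. Standard errors come from the fixed-effect covariance at
convergence; significance uses the two-tailed normal criterion
(|t| > 1.96, marginal above 1.645), appropriate for the large-n regime
this analysis targets, and no Satterthwaite/Kenward–Roger correction is
attempted. Model comparison refits by maximum likelihood; the LRT uses the
χ² reference with df equal to the parameter-count difference, and
BIC = deviance + k·ln(n).

Marginal and conditional R² use the variance-decomposition definition with
the random-slope extension: the variance credited to a grouping factor is
the mean over observations of the random-effect covariance projected
through the design, which for a zero-correlation model reduces to
Σ σ²_t · mean(x_t²) over its terms.

# The synthetic-data generator

The generator reproduces the study design: 72 subjects in nine groups of
eight, 135 scenes in three lists of 45, and a dual Latin square crossing
three list rotations with the three task orders
(search–memorization–preference, preference–search–memorization,
memorization–preference–search), so that 24 subjects share any list×task
cell and 8 share list×task×order. Scenes are synthesised from a smooth
gradient background, solid rectangles and band-limited noise patches,
giving controllable variation in all five features; trials last 8 s.

Scanpaths are a reflected random walk: gamma-distributed saccade
amplitudes (shape 2, median 5.1°, matching the reported median saccade
amplitudes of 5.1–5.3°), wrapped-normal direction persistence whose
concentration is set by a momentum parameter in [0, 1), and a
Metropolis-style Gaussian central bias; the start position is drawn from
the same positional prior. Blinks are independent per-fixation events at
rate 0.02. Two simulator-versus-reality caveats are worth stating
plainly. First, boundary reflection folds long saccades back into the
image, so the *realised* displacement median (≈3.6° at default settings)
is smaller than the drawn amplitude median; the drawn distribution is the
documented parameter. Second, the covariate structure of real scanpaths
is richer than this walk; recovery results are internal-validity checks
of the pipeline, not claims about any real corpus.

Durations are generated **conditionally on the realised covariates**:
locations and a provisional log-normal timeline come first (they determine
onsets, viewing times and all filters), then the response
log d = Xβ + Zu + ε is drawn from the generative model on the final
triplet design. The causal structure of real duration control is unknown;
this two-stage choice makes the true coefficients recoverable by
construction, which is the property the validation suite needs. The
default β vector uses the memorization-task reference estimates (intercept
5.534 log-ms ≈ 253 ms; ΔAngle 0.065; viewing time 0.040; feature effects
of order ±0.01–0.02). Variance components default to subject-intercept SD
0.13, item-intercept SD 0.09, small slope SDs (0.01–0.02) and residual SD
0.415 — chosen once so that the conditional-minus-marginal R² gap lands in
the 10–15-percentage-point range that full-scale analyses of this kind
report, with marginal R² around 5%.

# Problem sizes and numerical choices

The validation experiments run at a deliberately scaled-down size chosen
as a realistic desk-scale replicate: 24 subjects × 45 scenes, scenes of
150 × 200 px spanning the full 25.78° field (so 1° ≈ 7.8 px and the patch
radius is 8 px), 200 recovery replicates (150 for the null/type-I run).
At this size the triplet table has ≈ 14,000 rows, a REML fit of the
23-fixed-effect model with the compact recovery random structure
(by-subject intercept + ΔAngle and viewing-time slopes; by-item intercept
+ foveal-clutter slope) takes a few seconds, and replicate refits reuse
the factored model object. Other defaults: quantile bins default to
deciles (the bin count behind published binned-means figures is not
documented; 10 is the conventional choice and it is configurable);
partial-effect bands use the normal approximation, consistent with the
|t| criterion; convolution borders are reflect-padded; tie-breaking in
quantile binning is stable first-come ranking, which makes the
sort-and-slice oracle exact.

# Known limitations

* The feature-congestion clutter and mean-shift segmentation are faithful
  to their published algorithm families but not bit-identical to any
  specific MATLAB/EDISON build; segment counts and clutter values should
  be compared across conditions, not across implementations.
* Passing recovery tests on synthetic scanpaths demonstrates that the
  pipeline estimates what it claims to estimate under its own generative
  assumptions; real eye-movement data add measurement error, saccade
  detection artefacts, and covariate dependencies the simulator does not
  model.
* Correlated random effects, predictor interactions, and a task factor
  inside a single model are intentionally out of scope; tasks are fitted
  separately.
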