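# fixdur

Tools for analysing **fixation durations during real-world scene viewing**.
When people inspect a photograph, their eyes rest on one location for a few
hundred milliseconds before jumping (saccading) to the next. How long the
eyes stay put reflects both *what* is being processed at and around the
current gaze position and *how* the eyes got there. `fixdur` implements an
analysis pipeline that quantifies these influences at the level of single
fixations:

1. **Feature maps** — for every scene, five per-pixel maps: normalised
   CIELab luminance, binary Sobel edges, a multi-scale feature-congestion
   visual-clutter map, and a mean-shift segmentation whose region count
   serves as a local object-density surrogate.
2. **Patch statistics** — local image statistics inside circular patches of
   1° of visual angle (31 px at the reference display geometry of 800 px /
   25.78°) centred on each fixation: mean luminance, RMS contrast
   (patch SD / image mean), edge density (logit-transformed,
   `0.5·ln(p/(1−p))`), mean clutter, and the number of segments.
3. **Fixation triplets** — sliding windows (n−1, n, n+1) over each trial's
   fixation sequence, filtered by the standard rules: first/last fixations
   excluded, durations outside 50–1000 ms excluded, blink-adjacent windows
   removed, and both flanking saccades must exceed 2° so the three patches
   never overlap (two 1° patches one degree apart would overlap by 39%).
4. **Mixed models** — zero-correlation-parameter linear mixed models
   (zcpLMMs) of log fixation duration with crossed subject and scene-item
   random effects, fit per viewing task via `lme4`. The full fixed-effects
   structure has 23 terms: the intercept, the 5 features × 3 patch
   positions (testing *immediacy*, *lag*, and *successor* effects), and the
   oculomotor/spatiotemporal covariates — incoming and outgoing saccade
   amplitude (quadratic for the incoming), the direction change ΔAngle
   between them, viewing time (quadratic), and distance from image centre.
   Inference uses the normal-theory |t| > 1.96 criterion; goodness of fit
   is summarised by marginal and conditional R² (random-slope-aware).
5. **Reporting** — quantile-binned means with Cousineau within-subject
   standard errors, and partial-effect curves with 95% bands.
6. **Synthetic data** — a first-class generator that reproduces the study
   design (72 subjects in 9 groups, 135 scenes in 3 lists, a dual Latin
   square over 3 viewing tasks), synthesises scenes with controllable
   feature structure, simulates scanpaths with saccadic momentum and
   central bias, and draws log-normal durations from a known generative
   LMM so that the entire pipeline can be validated by parameter recovery.

The model, in standard notation, for fixation *n* of subject *s* on scene
*i*:

    log d_nsi = Xβ + Z_s u_s + Z_i w_i + u_list + u_group + ε,
    u ~ N(0, diag(σ²)),  ε ~ N(0, σ²_e)

with all predictors z-standardised per task and all random effects mutually
independent (the zero-correlation constraint).

## Worked example

```r
library(fixdur)

## one synthetic scene and its feature maps
scene <- makeScene(7, size = c(150L, 200L), pxPerDeg = 200 / 25.78)
maps  <- computeFeatureMaps(scene)
maps
#> FeatureMapSet 'scene7': 150 x 200 px; edge density 0.076; 398 segments

## a full synthetic dataset: scanpaths -> patches -> triplets -> model data
sim <- simulateTripletData(nSubjects = 8, nScenes = 10, seed = 401,
                           sceneSize = c(120L, 160L))
nrow(sim$data)
#> [1] 1105

## fit the duration model and inspect the fixed effects
fit <- fitDurationLMM(sim$data, sim$spec)
head(fixedEffectTests(fit), 4)
#>          term           b         se          t          label
#>   (Intercept)  5.49714822 0.03987473 137.860458    significant
#>    luminanceN  0.02394734 0.01781290   1.344382 nonsignificant
#>     contrastN -0.03603352 0.02536213  -1.420761 nonsignificant
#>  edgeDensityN  0.02811954 0.02526034   1.113189 nonsignificant

r2LMM(fit)
#> $marginal    [1] 0.074
#> $conditional [1] 0.137
```

The intercept sits within two standard errors of the generative mean log
duration (5.534 log-ms, about 253 ms); at this deliberately tiny problem
size the individual feature coefficients are noisy, which is exactly what
the full recovery experiment (below) quantifies.

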