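---
title: "From repeat quadrat photographs to weed emergence models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From repeat quadrat photographs to weed emergence models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Emergence models describe the fraction of a weed population that has
emerged by day $x$ of the season with a cumulative sigmoid $y(x) \in [0,1]$.
The conventional data are *true counts*: seedlings identified, counted and
removed at each visit to fixed quadrats. `weedemerge` implements the
image-based substitute: the same quadrats are photographed at each visit,
weed pixels are segmented from the soil background, and the accumulated
weed pixel area plays the role of the count. The substitution works because
relative cumulative emergence is invariant to multiplying a quadrat's
per-date values by any positive constant — if every seedling contributes a
roughly similar pixel area, pixels and counts produce the same normalized
curve. That invariance is implemented and tested directly
(`build_relative_cumulative()`), and the whole claim is testable end to end
on synthetic scenes where the true schedule is known.

## Pixel classification

Two segmentation routes are provided, deliberately mirroring an
image-editor workflow and a GIS workflow.

**Thresholding.** Channel-wise contrast exaggeration (`contrast_stretch()`,
a linear min–max map to $[0,255]$, idempotent by construction) followed by a
cutoff on the excess-green index $2G - R - B$. The index is the package's
concrete reading of a "spectral value" separating green tissue from
background; the default cutoff of 30 sits where healthy green tissue passes
easily but warm soil tones do not. Its known failure mode is deliberate:
slightly green-tinged features (sand, lichened rocks) also pass, producing
the over-detection that motivates the supervised route.

**Supervised maximum likelihood.** Each class is modelled as a Gaussian in
RGB space, estimated from labeled training samples (mean, sample covariance
with denominator $n-1$). A pixel $x$ is assigned to
$\arg\max_k \left[\log \pi_k - \tfrac12 \log |\Sigma_k| - \tfrac12 (x-\mu_k)^\top \Sigma_k^{-1} (x-\mu_k)\right]$,
the full quadratic discriminant with per-class covariance. Choices made
where the procedure is genuinely open:

- **Priors** $\pi_k$ are equal by default. Class prevalences differ wildly
  (soil dominates), but prevalence-weighted priors would bias the rare weed
  class downward; practitioners of this workflow typically leave priors
  uninformative.
- **Ridge** of $10^{-6}$ (intensity-squared units) is added to each
  covariance diagonal. Training regions highlighted on near-uniform
  features can be numerically degenerate; the ridge is far below any real
  color variance and only guards invertibility. A covariance that is still
  singular fails at classification time with an explicit error.
- **Ties** go to the lowest label index — deterministic and testable.
- **Dual reference files.** Lighting shifts all class colors between sunny
  and overcast days, so one reference file is kept per condition, the sunny
  one carrying a sixth `shadows` class. No radiometric calibration step is
  provided: per-condition references replace it.

The classifier is verified against a brute-force per-pixel evaluation of
the discriminant on random images, exactly, not approximately.

## Postclassification

The cleanup stage assumes the weed of interest produces seedling-scale
blobs rather than isolated pixels.

- **Majority filter** (`majority_filter()`): each pixel takes the most
  frequent label in the circular neighborhood of radius 15 px (the field
  protocol's value). Neighborhoods are *truncated* at image borders — no
  padding, so no invented labels. Tie rule: if the maximal count is shared,
  the pixel keeps its original label (plurality with center retention);
  single pass by default. The per-label counts are computed by FFT
  convolution with a disc kernel and rounded back to exact integers; tests
  verify exact agreement with explicit disc-offset voting.
- **Components and area filtering**: weed pixels are grouped under
  8-connectivity (the raster-to-polygon convention of common GIS tools;
  4-connectivity available) and components outside $[50, 20000]$ px are
  discarded at the default 512 × 512 synthetic scale. The bounds express
  intent — drop isolated noise and shapes too large to be one seedling —
  and must be rescaled with image resolution.

## Emergence series

Weed pixel counts are divided by the classified pixel total and re-expressed
for a standard 12,500,000-pixel frame, so images with different classified
areas are comparable. Per quadrat, values are accumulated over days and
normalized by the season total; day 0 is the first imaging date. Quadrats
with a zero season total are flagged degenerate and excluded from pooling
with a warning. Pooling stacks each quadrat's points without averaging —
the fit sees within- and between-quadrat variation. A single aggregated
series can be obtained by summing observations beforehand, but pooling is
the default because it weights quadrats by their actual observations.

## Model families and fitting

Four families cover the emergence shapes encountered in practice: logistic
(symmetric single flush), Gompertz (asymmetric, early inflection), Weibull
(flexible onset/shape, parameterized so `x0` is the half-rise day and the
curve is clamped to zero below its onset), and a logistic + Weibull mixture
for biphasic, two-flush seasons, with weight $w \in [0,1]$ and unit
asymptote. All are non-decreasing and bounded by their asymptote; both
properties are tested on dense grids over random parameter draws.

Fitting minimizes pooled SSE with bounded Levenberg–Marquardt. Starting
values are data-driven — `x0` from the day the mean series crosses half its
maximum, `b` from the central-rise span — and the remaining starts
(default 12) are seeded log-normal/normal jitters of that point, clamped to
the box. Box bounds: $a \in [0.05, 1.05]$ (slight overshoot of 1 allowed,
as normalized data can end below their asymptote), locations within one
span of the observed days, scales in $(0, 3\,\text{span}]$, Weibull shape
in $[0.2, 10]$. The biphasic surface is multi-modal; multi-start plus
bounds is what makes its fits reproducible. The best-SSE converged start
wins; everything is deterministic given the seed.

**Metrics.** RMSE $=\sqrt{SSE/n}$, $R^2 = 1 - SSE/TSS$ (undefined and
flagged when the observations are constant), and AIC in the least-squares
convention $n\ln(SSE/n) + 2(k+1)$, counting the error variance as a
parameter. Different software uses different additive AIC constants; any
fixed convention preserves the *ranking*, which is the only use AIC has
here. Absolute AIC values are therefore not comparable across conventions.

**Validation.** The fitted curve is evaluated at the count series' days and
scored against count-derived relative emergence. By construction no count
datum influences the fit (permuting the count series leaves parameters
bit-identical — tested). Days outside the fitted span are extrapolated with
a warning rather than rejected, since counting and imaging dates can
differ.

## The synthetic scene generator

`generate_series()` emulates the field protocol: a known cumulative curve
is inverted into a per-date schedule by drawing the per-quadrat seedling
total from a multinomial over the curve's increments between imaging dates
(first increment measured from zero); each date's image then contains *only
that date's new seedlings*, because counted seedlings are removed in the
field. Scenes are soil-textured backgrounds with sand patches, rocks,
sticks, and (sunny condition) multiplicatively darkened shadow regions;
seedlings are paired ellipse cotyledons with a configurable area range and
random orientation, placed by rejection sampling that avoids overlap until
the scene gets crowded — reproducing the leaf-overlap under-count regime of
dense stands. Colors are per-class Gaussians clipped and quantized to
$[0,255]$ (quantization also makes PNG round trips lossless). Defaults:
512 × 512 scenes (18 MP remains configurable), seedling areas of
600–1400 px so that seedling extent relative to the 15 px majority-filter
disc mirrors the field-scale relationship, rock color given a slight green
tinge so the thresholding baseline over-detects as it does on real soil.
The default season is a Gompertz curve ($x_0 = 60$, $b = 18$ days) with 600
seedlings across 6 quadrats and 12 biweekly dates.

What the generator does **not** emulate: photorealistic texture, raking
illumination, soil moisture changes, wind blur, multiple weed species,
perspective distortion, or growth of seedlings between emergence and
imaging. Passing tests therefore demonstrate the *pipeline's* correctness
and the soundness of pixels-for-counts substitution under controlled
conditions — not field-level classification accuracy, which depends on how
separable real class colors are.

## Problem sizes and numerical checks

The test suite fixes its own scales for speed and determinism: oracle
equivalence for the classifier on 50 random 16 × 16 images (3–6 classes),
for the majority filter on 30 random 32 × 32 rasters at radii 1, 2 and 15,
and for components on 100 random 32 × 32 masks; parameter recovery over 100
noisy replicates (15 days, noise SD 0.02); the end-to-end pipeline at the
full default conditions (6 × 12 images at 512 × 512); and workflow ordering
over 10 replicate seasons at 256 × 256. Smaller pipeline tests scale the
postclassification radius and area bounds down with the scene, as a user
must at any resolution.

## Known limitations

- Pixel-for-count substitution assumes per-seedling area is roughly
  stationary across the season; strong growth between visits or heavy
  overlap biases the pixel curve (the removal protocol limits both).
- The Gaussian color model ignores texture and shape; classes separable
  only by those features need a different front end.
- AIC values are convention-specific (see above); compare rankings, not
  magnitudes.
- The biphasic family with six free parameters needs data spanning both
  flushes; on single-flush data it collapses toward a degenerate mixture
  and is selected against by AIC, which is the intended behavior.
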