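---
title: "Methods: scoring 2D renders of photogrammetric specimen models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring 2D renders of photogrammetric specimen models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rendereval)
```

## The problem

Structure-from-motion photogrammetry turns a turntable series of macro
photographs of a pinned specimen into a textured 3D model, from which 2D
views can be rendered at any pose. If those renders are to stand in for
photographs — most ambitiously as labelled training data for species
classifiers — their fidelity must be measured, and it must be measured as a
function of the acquisition parameters that dominate digitization cost:
horizontal step between turntable positions, the number of vertical tilt
rings, and whether each view is focus-stacked. `rendereval` implements that
measurement pipeline: acquisition-plan enumeration, masked image comparison,
morphometric error scoring, and per-scenario aggregation, together with a
synthetic data generator so the whole pipeline is exercisable without
photogrammetry software or physical specimens.

## Acquisition geometry

The base capture is 32 images per ring, the turntable advancing 11.25°
between stations, repeated on tilt rings at −40°, −20°, 0°, +20°, +40° (160
stations at full density). Sparser horizontal densities are modelled as
*decimation* of the captured full ring — stations with base index
`k mod m == 0` are retained, `m = step / 11.25` — rather than as re-spaced
capture, because that is how sparse series are produced in practice (images
are removed from a full series). Two consequences are embraced rather than
hidden:

* 33.75° does not divide 360°, so the `m = 3` ring keeps
  `ceiling(32 / 3) = 11` stations with a single wrap-around gap of 22.5°.
* Decimated rings are phase-aligned with the center ring (same `k` indices).
  Whether real rigs offset alternate rings is unknowable from a shot count;
  alignment is the fixed, reproducible choice.

Focus stacking is carried as scenario metadata only: it changes how many raw
frames produce each station image, not where stations are. The full grid is
2 styles × 3 steps × 3 tilt sets = 18 scenarios.

## Texture accuracy

Original and rendered images are compared only where both masks agree.
The *intersection* of the masks is used (not the union): every compared
location is then specimen in both images, so neither background pixels nor
mask disagreements bias the score. Both rasters are cropped to the tight
bounding box of the common mask and the outside zeroed; because every metric
is restricted to the common mask, the background fill value is
score-neutral by construction.

Per channel `C`, the difference map is `Δ_C(i,j) = |A_C(i,j) − B_C(i,j)|`
(computed in doubles — no 8-bit wraparound), and

```
Similarity_C  = (1 − Σ Δ_C / (255 · n_pixels)) · 100
Similarity_RGB = mean over C of Similarity_C
Overall        = mean over {top, center, bottom} views of Similarity_RGB
```

`n_pixels` counts common-mask pixels, not frame pixels. Counting the full
clipped frame would dilute the sum with guaranteed-zero background
differences and inflate every score; since masking exists precisely to
remove background bias, the masked denominator is the defensible reading.

**SSIM.** The structural similarity index is computed with the standard
constants of the Wang et al. formulation, which the source material leaves
unstated: dynamic range `L = 255`, stabilizers `k1 = 0.01`, `k2 = 0.03`
(`C1 = (k1·L)²`, `C2 = (k2·L)²`), an 11 × 11 Gaussian window with σ = 1.5,
computed on Rec. 601 luminance (0.299 R + 0.587 G + 0.114 B). Local moments
come from windowed convolution with replicated edges; the reported value is
the mean of the per-window SSIM over windows whose *center* lies in the
common mask, so near-boundary windows contribute but pure background does
not. Per-channel SSIM (averaged over R, G, B) is available via
`ssim_params(per_channel = TRUE)`; on gray images it coincides with the
luminance form. Local variances are clamped at zero before use — windowed
second moments can go fractionally negative in floating point.

**Difference highlights.** The per-pixel maximum over the three channel
maps is thresholded at strict exceedance (`> 30` by default): "exceeds a
threshold of 30" is read literally, so a delta of exactly 30 is suppressed.
Maximum is the most sensitive channel combination; mean is available.

Reported percents and SSIM are rounded to two decimals *only* in the report
files; every in-memory value keeps full precision.

## Geometric accuracy

Six morphometric features are scored: elytra length, elytra width, second
and third antenna segments, first and second tibia — standard carabid
measurements spanning coarse and fine structures. A feature whose body
segment was not reconstructed is *absent* (`NA` / empty CSV cell), never
zero; zero-length measurements are rejected as invalid. Each feature reports
`MAE (n_success / n_total)`, printing `N/A (0/n)` when nothing succeeded.

The overall score **pools records**: it is the mean of
`|modeled − reference|` over all present measurements, not the mean of
per-feature MAEs. The two differ whenever success counts are uneven (pooled
weights each measurement equally; mean-of-means up-weights sparse features),
and "MAE across all measurements" is the literal pooled form. The
mean-of-feature-means alternative remains available via
`geometric_score(..., aggregate = "feature_means")`.

## Aggregation and best-model selection

`summarize_scenarios()` emits one row per scenario in grid order; means are
taken over successfully created models only, and a scenario with zero
successes carries `NA` metrics, rendered as an em dash (—) in `summary.csv`.
Model-creation success is an *input* flag: in real studies it is a visual
judgement (minimal distortion, no missing segments) that no desk metric can
reproduce, so the pipeline treats it as data; the synthetic generator
samples it.

How texture and geometry combine into "the best model" is genuinely open;
the package's convention is mean rank: rank successful models by RGB
similarity (descending), SSIM (descending) and MAE (ascending), average the
three ranks, lowest wins, ties returned as a set. The rule is
scale-free — it never trades percentage points against millimetres — and it
returns a Pareto-optimal model whenever one exists (a dominated model cannot
have the minimal mean rank, since the dominating model beats it in every
ranking). A weighted variant is exposed through `select_best(weights =)`.
Formal statistical testing across scenarios is deliberately out of scope:
with success counts varying from 0 to 10 per scenario the comparisons would
be unbalanced in uninterpretable ways.

## The synthetic generator

`generate_specimen()` draws a beetle-like figure — elliptical body with
longitudinal striae and seeded speckle, head, two-segment antennae, six
legs — on a plain background, at a center view and two tilted views
(foreshortened by the cosine of the tilt). The mask is the figure support.
The six reference measurements are fixed proportions of body length
(elytra 0.58 and 0.34, antenna segments 0.055 and 0.065, tibiae 0.17 and
0.19) with seeded 3% multiplicative jitter, so measurements scale exactly
with body length before jitter.

`degrade()` produces the "render": Gaussian blur → per-channel intensity
shift → additive Gaussian noise → clamp to [0, 255], in that fixed order
(order matters: blurring after clamping or shifting after noise changes
scores). Clamping means the closed-form similarity drop under a pure shift
(`shift / 255 · 100` points on a flat specimen) holds only away from
saturation — verification fixtures therefore use mid-gray bodies. Modeled
measurements are references × `scale_error` × seeded relative jitter
(default SD 0.02), with dropout features returned absent.

`generate_study()` lays out the default design: **10 specimens** with body
lengths 2.75–23.96 mm (the published range for the ten-beetle panel the
generator emulates) × **18 scenarios** = 180 planned models. Per-scenario
degradation severity is `0.3·(m−1) + 0.25·(5 − rings)/2 + 0.3·[FS]`,
i.e. it grows with horizontal decimation, with the loss of tilt rings, and
with focus stacking (emulating stacking's texture artifacts); severity
scales blur (base 1.2 px), channel shifts (base ±8), noise (base SD 5),
scale error (base 3%) and fine-feature dropout (base rate 12%).
Model-creation success is `plogis(3.2 − 2.0·severity − 2.2·|log(L/median)|)`
— sparse imaging and extreme body sizes fail more often. These constants
were chosen once as a plausible severity ladder for a desk-scale emulation
and are not fitted to any published table.

One root seed drives everything through `derive_seed(root, tag)`, so each
stage (specimen appearance, per-model noise, dropout, success) has its own
reproducible stream, and `evaluate_study()` regenerates images on demand
from the manifest instead of holding 180 × 3 rasters in memory.

**What the generator does and does not emulate.** It reproduces the
*structure* of the study (paired masked views, graded degradations, missing
features, uneven success) — not the physics. Real SfM failures produce
bowing, surface doubling and hole-filled meshes, not Gaussian blur; real
texture error is spatially structured (seam lines, defocus halos), not
i.i.d.; specimen masks in real pipelines are hand-drawn and disagree between
original and render. Passing tests therefore demonstrate that the *metrics
and accounting* behave correctly under controlled corruption, not that any
particular acquisition recipe is superior on real beetles.

## Numerical and degenerate-input choices

* Masks binarize at the 8-bit midpoint (≥ 128 is specimen).
* Empty masks, empty mask intersections, and unprepared pairs are hard
  errors, as are dimension mismatches unless bilinear resizing is explicitly
  requested (`resize = TRUE`) — silent resampling changes scores.
* One-pixel-wide crops keep matrix shape throughout.
* SSIM requires the window to fit inside the cropped extent; smaller crops
  are an error rather than a silently shrunken window.
* Crop windows are tight bounding boxes; cropping is idempotent.
* CSV round-trips preserve absent measurements as genuinely empty cells.

## Problem sizes used by the test suite

The suite exercises exact oracles on fixtures up to 3 × 3 (a double-loop
similarity implementation must agree *exactly*), closed-form SSIM on
constant images to 1e-9, monotonicity of mean RGB similarity and SSIM over
20 seeded replicates per level of blur (σ = 0–2.4 px) and noise (SD 0–16) on
100 × 80 px specimens, scale-error recovery by regression over 100 seeded
specimens, and a full 10 × 18 identity-degradation study, which must come
back as 100.00 / 1.00 / 0.00 in every summary row. These sizes are the
package's chosen verification scale; the generator's defaults (160 × 120 px,
10 × 18 design) define the emulated study itself.

## Known limitations

* No geometric registration: comparison assumes the render was produced at
  the original's pose, so any residual misalignment is charged to texture
  error, exactly as in mask-and-compare workflows.
* No perceptual color metrics (ΔE) or multiscale SSIM.
* Success of model creation cannot be computed, only recorded.
* The severity ladder is a modelling convenience; its constants shape the
  synthetic success pattern and should not be read as predictions for any
  real rig.
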