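# rendereval

Quantitative evaluation of how photogrammetric imaging parameters affect the
fidelity of 2D images rendered from 3D specimen models.

Museum digitization pipelines increasingly build 3D models of pinned insect
specimens by structure-from-motion (SfM) photogrammetry and then render 2D
views from those models — for outreach, proxy access, or as synthetic
training data for machine-learning classifiers. Whether a rendered view is a
faithful stand-in for a photograph depends on acquisition choices: how finely
the turntable is stepped, how many tilt rings are captured, and whether each
view is focus-stacked. `rendereval` implements the evaluation pipeline for
that question, for digitization teams and morphologists who need numbers
rather than visual impressions.

## What it computes

**Acquisition plans.** A full ring is 32 camera stations at azimuths
k · 11.25°, k = 0…31; coarser horizontal steps (22.5°, 33.75°) retain the
stations with k mod m = 0, where m is the decimation factor, and tilt sets
C±20–40 = (−40°, −20°, 0°, 20°, 40°), C±20, C±40 choose the rings. The full
grid of 2 styles × 3 steps × 3 tilt sets gives 18 scenarios; the
full-density five-ring plan has 160 stations.

**Texture accuracy.** For a masked original/rendered pair clipped to the
intersection of the two specimen masks, the per-channel difference is
Δ_C(i,j) = |A_C(i,j) − B_C(i,j)| and the channel similarity is

    Similarity_C = (1 − Σ Δ_C / (255 · n_pixels)) · 100

with Similarity_RGB the mean over C ∈ {R, G, B} and the overall model score
the mean over the top/center/bottom views. SSIM is computed on Rec. 601
luminance with the standard Wang et al. constants (11×11 Gaussian window,
σ = 1.5, k₁ = 0.01, k₂ = 0.03, L = 255), averaged over windows centered in
the mask. Difference maps keep the per-pixel max-channel Δ where it strictly
exceeds a threshold (default 30).

**Geometric accuracy.** Mean absolute error (mm) between reference and
modeled values of six morphometric features (elytra length and width, second
and third antenna segments, first and second tibia), pooling all present
measurements; features whose body segment was not modeled are absent and are
reported as success fractions, e.g. `0.15 (9/10)` or `N/A (0/3)`.

**Reporting.** Per-scenario summary tables (success counts, mean RGB
similarity, SSIM, MAE; em-dash cells for scenarios with no successful model),
per-feature MAE tables, and mean-rank best-model selection per specimen.

**Synthetic data.** Because real inputs require photogrammetry software and
physical specimens, a generator draws beetle-like masked specimens at three
view angles, applies controlled degradations (Gaussian blur, per-channel
intensity shift, additive noise, measurement scale error, feature dropout)
and samples model-creation success, reproducing the structure of a
10-specimen × 18-scenario study from a single seed.

## Worked example

```r
library(rendereval)

plan <- plan_stations(imaging_scenario("NFS", 11.25, "C20-40"))
plan
#> <acquisition_plan> NFS (C20-40, 11.25) - 160 stations on 5 rings

specimen <- generate_specimen(seed = 42, body_length_mm = 13.5)
model <- degrade(specimen, degradation_spec(
  blur_sigma = 1, channel_shift = c(R = 8, G = -4, B = 6),
  noise_sd = 4, scale_error = 1.03, seed = 7))

pair <- to_common_extent(specimen$views$center, model$views$center)
texture_score(pair)
#> <texture_score> view center: RGB 91.74% (R 91.79, G 91.87, B 91.55), SSIM 0.67

ev <- evaluate_model(specimen, model)
ev$texture
#> <model_texture_score> overall RGB 91.62%, overall SSIM 0.66
ev$geometry
#> <geometric_score> overall MAE 0.08 mm (6/6 measurements)

hl <- difference_highlight(pair, threshold = 30)
sum(hl$highlight > 0)
#> [1] 775
```

The degraded render keeps 91.6% of the original's RGB content and an SSIM of
0.66 (blur destroys local structure faster than it moves mean intensities);
the injected 3% measurement scale error plus jitter shows up as a 0.08 mm
MAE across the six features; 775 of the 3146 compared specimen pixels differ
by more than 30 intensity levels in at least one channel.

A full study runs as `simulate → compare → geometry → summarize`:

```r
study <- generate_study(study_config(seed = 1))           # 180 planned models
res   <- evaluate_study(study)
summ  <- summarize_scenarios(res$evaluations)
write_report(summ, res$evaluations, "report", measurements = res$measurements)
```

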