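---
title: "Automated hemocytometer counting: model, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated hemocytometer counting: model, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(algaecount)
```

## The counting model

A hemocytometer is a microscope slide with an etched grid of squares of
known side length $l$ (mm) under a cover slip at a fixed depth $h$ (mm).
Classical counting tallies cells inside grid squares of area $S$ and uses

$$N = \frac{a \cdot 10^3}{h \cdot S},$$

where $a$ is the mean count per square and $10^3$ converts mm$^3$ to mL
(`manual_concentration()`). The automated path avoids any per-image grid
cropping by computing, once per equipment setup, the volume of suspension
that one full camera frame covers. From operator-cropped images of grid
squares we obtain measurements $p$ of the square side in pixels; the
conversion factor is $s = l / \bar p$ (mm/px) and the image volume is

$$V_{img} = (s \cdot PH)(s \cdot PW) \cdot h \quad [\text{mm}^3],$$

for a $PW \times PH$ px frame. A frame with $a_{img}$ detected cells in a
sample diluted by factor $D \ge 1$ then estimates

$$N = \frac{a_{img} \cdot D \cdot 10^3}{V_{img}} \quad [\text{cells/mL}].$$

Several frames from different slide zones are averaged per sample; we report
mean, median and population (divide-by-$n$) SD, with the mean as the
headline estimate since all chamber regions are equivalent. Per-image values
are carried unrounded; only sample-level reports round to integer cells/mL.

Two conventions worth making explicit:

* **Both edges of each cropped square are measured** (width and height),
  giving two $p$ measurements per crop. This doubles the sample and makes
  the calibration robust to slight grid tilt. At least five squares from
  different chamber regions are recommended; fewer produces a warning.
* **Population SD throughout.** All spread statistics divide by $n$, the
  convention that reproduces the published benchmark tables this package
  ships (`validation_table()`).

The chamber depth is always an explicit user input rather than being looked
up from the chamber name: published catalogues are not internally consistent
about, e.g., the Goryaev chamber's working depth (0.02 mm in catalogues,
0.1 mm in common practice with standard cover slips), and the wrong depth
silently scales every concentration.

## The detection pipeline

Cells of *Chlorella vulgaris* are near-spherical (2–10 µm diameter) and
chlorophyll-rich, which motivates each stage of `count_cells()`:

1. **Green-channel CLAHE** (`enhance_green()`): contrast-limited adaptive
   histogram equalization applied to the green channel only, amplifying the
   chlorophyll signal while leaving red and blue planes untouched. The clip
   limit (default 2.0) and tile grid (default 8×8) are conventional CLAHE
   defaults and configurable.
2. **Luminance grayscale** (`to_grayscale()`): $Y = 0.299R + 0.587G +
   0.114B$, rounded to 8-bit.
3. **Median filtering** (`denoise_median()`, default 3×3): suppresses
   salt-and-pepper sensor noise without degrading cell edges. Implemented as
   a direct small-kernel median with reflected borders.
4. **Hough circle detection** (`detect_circles()`): Sobel edge pixels above
   a gradient-magnitude threshold (default 100) vote along ± their gradient
   direction for circle centers at all radii in `[min_radius_px,
   max_radius_px]` (defaults 15 and 100 px for the reference 4032×3024
   setup). Accumulator local maxima with at least `sensitivity` votes
   (default 30) become candidates; lower sensitivity admits more circles
   (recall), higher less (precision), and by construction the detections at
   a higher threshold are a subset of those at a lower one. Greedy
   non-maximum suppression enforces `min_dist_px` between centers
   (default 100 px), ordered by votes with exact ties broken by (row,
   column) — this makes results fully deterministic. Radii are estimated
   from radially aligned edge pixels: the modal integer distance, refined by
   the mean distance within ±1 px of the mode. Because voting uses gradient
   magnitude in both directions, no assumption is made about cells being
   darker or lighter than the background.

A geometric advisory holds that `min_dist_px` ≥ 2·`max_radius_px` so that
detected neighbours cannot overlap; the reference defaults themselves
violate it, so the package logs a message rather than failing. A detection
is kept whenever its center is inside the frame, so cells truncated by the
frame border still count. Radius bounds are specified in pixels; when
working in microns, convert via the calibration's $s$.

Two pipeline internals the reference configuration leaves open — the
accumulator resolution and the edge threshold — are fixed here at full image
resolution and gradient threshold 100, both exposed in
`detection_params()`.

## The synthetic scene generator

`generate_scene()` renders what the detector assumes about a hemocytometer
frame: a light background, dark etched grid lines, and green-dominant
anti-aliased disks with radii from a truncated normal, placed by rejection
sampling. Defaults emulate the reference high-magnification setup
(4032×3024 px, one grid square ≈ 1222 px, radii in 15–100 px, 10–60 cells
per frame). `clump_fraction` places that share of cells in touching chains
(centers ≈ 1.8 radii apart, a simple stand-in for acid-induced
agglomeration whose real geometry is irregular); `degrade()` adds defocus
blur, multiplicative illumination ramps, overexposure clipping,
salt-and-pepper noise, and irregular non-green foreign blobs. Ground truth
— centers, radii, count, and a mask rasterized identically to
`detections_to_mask()` — is frozen before any degradation.

`generate_sample()` draws per-frame counts from a Poisson law with mean
`expected_count(C, V_img, D)`, the canonical model for a well-mixed
suspension, then renders one scene per frame with seeds derived from the
base seed and frame index; identical parameters give bit-identical scenes.

What the generator does *not* emulate: optics (point-spread functions,
chromatic effects), cell texture and ellipticity, debris beyond generic
blobs, and grid-line interactions with cells other than simple occlusion
by drawing order. Tests passing on these scenes therefore demonstrate the
geometry and arithmetic of the pipeline — count recovery, mask accuracy,
concentration round-trips — not photorealistic robustness, which only real
slides can show.

## Validation metrics

`count_mae()` is the mean absolute per-image count error $\frac 1N \sum
|x_i - y_i|$ (the mean, as the name says). `mask_iou()` is the Jaccard
index; two empty masks score 1 (perfect agreement), exactly one empty
scores 0 — degenerate cases a benchmark never meets but a test suite does.
`mean_area_error()` is the relative error of the mean cell area (areas
$\pi r^2$ for circles, component pixel counts for masks); the definition is
a reconstruction, as segmentation benchmarks rarely state it.
`percentage_difference()` uses the expert value as denominator.
`agglomeration_trend()` fits error on clump rate by OLS.

The shipped `validation_table()` data are the published per-sample expert
vs. automated benchmarks for two setups; the percentage-difference columns
summarize (via `column_summary()`) to mean 15.24% / SD 10.31% (median-based
estimates) and 17.96% / 9.94% (mean-based), which the acceptance tests
reproduce. Two expert entries in the high-magnification table (samples 8
and 18) are inconsistent with their printed percentage differences, so
summary statistics are validated against the percentage columns as printed,
not recomputed from the concentration columns.

## Study sizes used by the test suite

The heavy validation suites run at reduced frame sizes so the whole suite
stays comfortably interactive, with geometry scaled coherently (cell radii,
separations and detector bounds shrink together):

* **Clean-scene detection suite**: 100 scenes at 1024×768, radii
  truncnorm(22, 4) clipped to [15, 30] px, 10–60 cells, separation
  66 px = 2.2·r\_max; detector bounds [15, 30], min-dist 60, sensitivity
  30. Acceptance: exact count in ≥ 95%, |error| ≤ 1 otherwise, truth-mask
  IoU ≥ 0.9 per scene.
* **Concentration round trip**: 50 replicates of 10 frames at 640×480
  (one grid square = 160 px, so $V_{img} = 0.003$ mm³), Poisson counts at
  expected 30. Note that even a perfect detector passes a ±10% band in only
  ≈ 92% of replicates under Poisson sampling, so this criterion
  genuinely exercises sampling noise, not just the detector. A further 200
  replicates check estimator bias from truth counts alone (≤ 5%).
* **Clumping trend**: clump fractions {0, 0.1, 0.2, 0.4}, 30 scenes each at
  1024×768 and 30 cells; mean absolute count error must be non-decreasing
  with a positive OLS slope. Clumped neighbours fall inside the detector's
  min-dist suppression radius, so undercounting grows with clumping — the
  same qualitative failure mode as on real agglomerated samples.

## Numerical choices and degenerate inputs

* Coordinates are 0-based with x = column, y = row; centers and radii are
  reals (sub-pixel, via accumulator vote centroids).
* The conversion factor and image volume are never rounded internally;
  reports display $s$ at 2 significant figures and $V_{img}$ at 1.
* A blank image yields an empty detection set (count 0, concentration 0),
  not an error; an unreadable image in a batch warns and is skipped; an
  empty batch errors.
* Infeasible cell packings (too many cells for the requested separation)
  fail with an explicit error rather than silently under-filling.
* `detection_params()` validates radius ordering, odd median kernels and
  positive thresholds at construction time.

## Limitations

Clump splitting is out of scope: touching cells within the suppression
distance are counted as one, which is exactly the degradation the clumping
trend quantifies. Non-circular debris can be falsely detected when its
edges are circular at the searched radii; the overlay output
(`annotate_image()`) exists so an operator can audit such cases. The
mapping of the sensitivity threshold onto any other Hough implementation's
scale is not 1:1; it is validated here against synthetic ground truth
rather than against another implementation's parameter values.
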