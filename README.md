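# algaecount

Automated estimation of microalgae cell concentration (cells/mL) from
microscope images of a hemocytometer counting chamber, for wet-lab teams
monitoring cultures of near-spherical cells such as *Chlorella vulgaris*
without commercial cell counters or labelled training data.

## The method

Manual hemocytometer counting uses squares of known area *S* and chamber
depth *h*:

```
N = a · 10³ / (h · S)        [cells/mL]
```

with *a* the mean count per square. This package automates the whole
measurement instead of the bookkeeping: a one-off **calibration** converts
the camera frame itself into a known volume, and a classical computer-vision
pipeline counts the cells in each frame.

1. **Calibration.** Crop a few chamber grid squares (side length *l* mm,
   from the manufacturer) out of microscope frames; each crop's pixel width
   and height measure the side in pixels. With mean measurement *p̄*, the
   conversion factor is `s = l / p̄` (mm/px) and a `PW × PH` px frame covers
   `V_img = (s·PH)·(s·PW)·h` mm³ of suspension.
2. **Detection.** Green-channel CLAHE (chlorophyll signal) → luminance
   grayscale `Y = 0.299R + 0.587G + 0.114B` → 3×3 median filter → a
   gradient-voting Hough circle transform with radius bounds, a minimum
   center distance, and an accumulator-evidence threshold ("sensitivity").
3. **Quantification.** Each frame with `a_img` detections in a sample
   diluted `D`-fold estimates `N = a_img · D · 10³ / V_img`; several frames
   per sample are aggregated (mean, median, population SD).
4. **Validation & simulation.** Count MAE, mask IoU, cell-area error,
   percentage difference vs expert counts, Pearson correlation, clumping
   trend — plus a synthetic hemocytometer-scene generator with exact ground
   truth, so the full pipeline is testable with no microscope at all.

## Worked example

Calibrating the reference setup — a Goryaev chamber (square side 0.05 mm,
depth 0.1 mm used with standard cover slips) photographed at 4032×3024 px,
with grid squares measuring about 1222 px:

```r
library(algaecount)

chamber <- chamber_spec("Goryaev", square_side_mm = 0.05, depth_mm = 0.1,
                        side_tolerance_mm = 0.004)
stats <- summarize_etalon(c(1222, 1218, 1230, 1210, 1225, 1219))
cal <- calibrate(stats, chamber, image_height_px = 3024, image_width_px = 4032)
cal
#> Equipment calibration report
#> ============================
#> Chamber:            Goryaev (square side 0.05 +/- 0.004 mm, depth 0.1 mm)
#> Etalon squares:     6 measurements, 1221 +/- 6 px
#> Conversion factor:  s = 4.1e-05 mm/px (unrounded 4.09612e-05)
#> Frame size:         4032 x 3024 px (W x H)
#> Image volume:       V_img = 0.002 mm^3 (unrounded 0.00204573)
```

So each full frame images ≈ 0.002 mm³ of suspension: a frame with 10
detected cells in an undiluted sample is ≈ 10·10³/0.002 = 5×10⁶ cells/mL.
Counting a simulated sample end to end:

```r
scenes <- lapply(1:3, function(i)
  generate_scene(scene_params(n_cells = 30, seed = i)))
imgs <- setNames(lapply(scenes, `[[`, "image"), paste0("img_", 1:3))
sample_est <- run_count(imgs, cal, dilution = 1, out_dir = "out")
sample_est
#> <sample_concentration> sample (D = 1, 3 images)
#>   mean   14,664,697 cells/mL
#>   median 14,664,697 cells/mL
#>   SD     0 cells/mL
```

The detector recovered all 30 cells in each of the three frames, hence the
zero spread (30 cells per 0.002 mm³ frame ≈ 1.5×10⁷ cells/mL; a real sample
varies frame to frame by Poisson sampling). `out/` gains per-image
detections, a per-image CSV and a one-row sample summary CSV, plus
`--overlays`-style annotated PNGs on request.) A command-line front end
(`exec/algaecount`) exposes the same four verbs: `calibrate`, `count`,
`simulate`, `validate`.

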