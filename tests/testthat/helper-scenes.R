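# Shared study configurations for the synthetic-scene tests.
#
# clean_scene: 1024 x 768 frames, radii ~ truncnorm(22, 4) in [15, 30] px,
# non-clumped separation 66 px (2.2 * r_max); detection radius bounds match
# the scene and min_dist = 2 * r_max. small_scene: a 640 x 480 variant for
# the many-replicate round-trip simulations, with one grid square = 160 px
# so that s = 0.05 / 160 mm/px and V_img = 0.003 mm^3.

clean_scene <- function(seed, n_cells = 30, clump_fraction = 0) {
  scene_params(height_px = 768, width_px = 1024, grid_spacing_px = 256,
               grid_line_width_px = 3, n_cells = n_cells,
               radius_mean_px = 22, radius_std_px = 4,
               radius_min_px = 15, radius_max_px = 30,
               min_separation_px = 66, clump_fraction = clump_fraction,
               clump_size = 3, seed = seed)
}

clean_det_params <- function(sensitivity = 30) {
  detection_params(min_radius_px = 15, max_radius_px = 30, min_dist_px = 60,
                   sensitivity = sensitivity)
}

small_scene <- function(seed, n_cells = 30) {
  scene_params(height_px = 480, width_px = 640, grid_spacing_px = 160,
               grid_line_width_px = 2, n_cells = n_cells,
               radius_mean_px = 14, radius_std_px = 2.5,
               radius_min_px = 10, radius_max_px = 20,
               min_separation_px = 44, seed = seed)
}

small_det_params <- function() {
  suppressMessages(
    detection_params(min_radius_px = 9, max_radius_px = 22, min_dist_px = 40))
}

small_calibration <- function() {
  calibrate(suppressWarnings(summarize_etalon(c(160, 160))),
            chamber_spec("synthetic", square_side_mm = 0.05, depth_mm = 0.1),
            image_height_px = 480, image_width_px = 640)
}

default_det_params <- function(...) {
  suppressMessages(detection_params(...))
}

# light background with one anti-aliased dark disk, for detector unit tests
disk_image <- function(H, W, centers_xy, r, bg = 220, fg = 60) {
  img <- matrix(bg, H, W)
  for (k in seq_len(nrow(centers_xy))) {
    cx <- centers_xy[k, 1]; cy <- centers_xy[k, 2]
    d <- sqrt(outer(((1:H) - 1 - cy)^2, ((1:W) - 1 - cx)^2, `+`))
    cov <- pmin(pmax(r + 0.5 - d, 0), 1)
    img <- img * (1 - cov) + fg * cov
  }
  round(img)
}
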