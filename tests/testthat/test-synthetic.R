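test_that("a cell-free scene is grid-only with empty truth", {
  sc <- generate_scene(clean_scene(seed = 2, n_cells = 0))
  expect_equal(sc$true_count, 0L)
  expect_equal(nrow(sc$true_centers), 0L)
  expect_equal(sum(sc$truth_mask), 0L)
  # grid lines present: some pixels darker than the background
  expect_lt(min(sc$image[, , 1]), sc$params$background_rgb[1])
})

test_that("scenes are bit-identical for a fixed seed", {
  a <- generate_scene(clean_scene(seed = 31, n_cells = 15))
  b <- generate_scene(clean_scene(seed = 31, n_cells = 15))
  expect_identical(a$image, b$image)
  expect_identical(a$true_centers, b$true_centers)
  expect_identical(a$true_radii, b$true_radii)
  c2 <- generate_scene(clean_scene(seed = 32, n_cells = 15))
  expect_false(identical(a$image, c2$image))
})

test_that("non-clumped placement honours the minimum separation exhaustively", {
  sc <- generate_scene(clean_scene(seed = 6, n_cells = 30))
  d <- as.matrix(dist(sc$true_centers))
  expect_true(all(d[upper.tri(d)] >= sc$params$min_separation_px))
  expect_equal(sum(upper.tri(d)), choose(30, 2))  # all 435 pairs checked
})

test_that("radii come from the truncated normal and cells stay in frame", {
  p <- clean_scene(seed = 8, n_cells = 40)
  sc <- generate_scene(p)
  expect_true(all(sc$true_radii >= p$radius_min_px))
  expect_true(all(sc$true_radii <= p$radius_max_px))
  expect_true(all(sc$true_centers$x >= sc$true_radii &
                    sc$true_centers$x <= p$width_px - 1 - sc$true_radii))
  expect_true(all(sc$true_centers$y >= sc$true_radii &
                    sc$true_centers$y <= p$height_px - 1 - sc$true_radii))
})

test_that("the truth mask equals the rasterized truth detections exactly", {
  sc <- generate_scene(clean_scene(seed = 12, n_cells = 18))
  oracle <- detections_to_mask(
    detection_set(sc$true_centers$x, sc$true_centers$y, sc$true_radii,
                  image_height_px = sc$params$height_px,
                  image_width_px = sc$params$width_px))
  expect_identical(mask_iou(sc$truth_mask, oracle), 1)
})

test_that("infeasible packings fail loudly, naming the constraint", {
  p <- scene_params(height_px = 200, width_px = 200, grid_spacing_px = 100,
                    n_cells = 50, radius_mean_px = 20, radius_std_px = 0,
                    radius_min_px = 20, radius_max_px = 20,
                    min_separation_px = 80, seed = 1)
  expect_error(generate_scene(p), "min_separation_px")
})

test_that("degradations change the image but never the truth", {
  sc <- generate_scene(small_scene(seed = 17, n_cells = 10))
  same <- degrade(sc, list())
  expect_identical(same$image, sc$image)

  lap_var <- function(img) {
    g <- to_grayscale(img)
    l <- g[2:(nrow(g) - 1), 2:(ncol(g) - 1)] * 4 -
      g[1:(nrow(g) - 2), 2:(ncol(g) - 1)] - g[3:nrow(g), 2:(ncol(g) - 1)] -
      g[2:(nrow(g) - 1), 1:(ncol(g) - 2)] - g[2:(nrow(g) - 1), 3:ncol(g)]
    stats::var(as.numeric(l))
  }
  blurred <- degrade(sc, list(blur_sigma_px = 3))
  expect_lt(lap_var(blurred$image), lap_var(sc$image))  # sharpness drops

  foreign <- degrade(sc, list(n_foreign_objects = 3))
  expect_identical(foreign$true_count, sc$true_count)
  expect_identical(foreign$truth_mask, sc$truth_mask)
  expect_false(identical(foreign$image, sc$image))

  ramp <- degrade(sc, list(illumination_gradient_amplitude = 0.3))
  # left edge darkened, right edge brightened
  expect_lt(mean(ramp$image[, 1:40, ]), mean(sc$image[, 1:40, ]))
  expect_gt(mean(ramp$image[, 601:640, ]) + 1, mean(sc$image[, 601:640, ]))

  expect_error(degrade(sc, list(vignette_strength = 1)), "unknown degradation")
})

test_that("per-image sample counts follow the Poisson law of the concentration", {
  # tiny frames so 200 draws stay cheap; lambda = C V / 10^3 = 30
  p <- scene_params(height_px = 120, width_px = 160, grid_spacing_px = 80,
                    grid_line_width_px = 1, n_cells = 1, radius_mean_px = 6,
                    radius_std_px = 1, radius_min_px = 4, radius_max_px = 8,
                    min_separation_px = 13, seed = 50)
  cal <- small_calibration()
  C <- 30 * 1e3 / cal$image_volume_mm3
  scenes <- generate_sample(C, 200, cal, dilution = 1, base_params = p)
  counts <- vapply(scenes, function(s) s$true_count, integer(1))
  expect_lt(abs(mean(counts) - 30), 3 * sqrt(30 / 200))  # within 3 SE

  empty <- generate_sample(0, 5, cal, base_params = p)
  expect_true(all(vapply(empty, function(s) s$true_count, integer(1)) == 0L))
})
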