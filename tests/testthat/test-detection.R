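test_that("green-channel CLAHE leaves red and blue planes bit-identical", {
  sc <- generate_scene(clean_scene(seed = 3, n_cells = 12))
  out <- enhance_green(sc$image)
  expect_identical(out[, , 1], sc$image[, , 1])
  expect_identical(out[, , 3], sc$image[, , 3])

  flat <- array(128, dim = c(64, 64, 3))
  ef <- enhance_green(flat)
  expect_length(unique(as.numeric(ef[, , 2])), 1L)  # flat stays flat

  # low-contrast green ramp gains dynamic range
  ramp <- array(0, dim = c(64, 64, 3))
  ramp[, , 2] <- matrix(rep(round(seq(100, 120, length.out = 64)), each = 64),
                        64, 64, byrow = TRUE)
  er <- enhance_green(ramp)
  expect_gt(diff(range(er[, , 2])), diff(range(ramp[, , 2])))

  expect_error(enhance_green(matrix(1, 5, 5)), "RGB")
})

test_that("grayscale conversion uses the 0.299/0.587/0.114 luminance weights", {
  px <- function(r, g, b) {
    img <- array(0, dim = c(1, 1, 3))
    img[1, 1, ] <- c(r, g, b)
    as.numeric(to_grayscale(img))
  }
  expect_equal(px(255, 255, 255), 255)
  expect_equal(px(0, 255, 0), 150)   # 149.685 rounds up
  expect_equal(px(255, 0, 0), 76)    # 76.245 rounds down
  expect_equal(px(0, 0, 255), 29)
})

test_that("median denoising removes salt pixels and respects its contract", {
  g <- matrix(round(runif(400, 0, 255)), 20, 20)
  expect_identical(denoise_median(g, 1), g)          # kernel 1 = identity
  const <- matrix(77, 15, 15)
  expect_equal(denoise_median(const, 3), const)      # median of constants
  salt <- matrix(0, 5, 5)
  salt[3, 3] <- 255
  expect_equal(denoise_median(salt, 3), matrix(0, 5, 5))
  expect_error(denoise_median(g, 2), "odd")
})

test_that("circle detection finds isolated disks with sub-pixel accuracy", {
  blank <- matrix(200, 300, 300)
  expect_equal(detect_circles(blank, default_det_params())$count, 0L)

  one <- disk_image(400, 400, cbind(200, 200), r = 30)
  d1 <- detect_circles(one, default_det_params())
  expect_equal(d1$count, 1L)
  expect_lt(abs(d1$detections$center_x_px - 200), 2)
  expect_lt(abs(d1$detections$center_y_px - 200), 2)
  expect_lt(abs(d1$detections$radius_px - 30), 3)

  two <- disk_image(400, 700, cbind(c(180, 480), c(200, 200)), r = 30)
  d2 <- detect_circles(two, default_det_params())
  expect_equal(d2$count, 2L)
})

test_that("all detections respect the radius bounds and minimum distance", {
  sc <- generate_scene(clean_scene(seed = 21, n_cells = 40))
  p <- clean_det_params()
  d <- detect_circles(to_grayscale(sc$image), p)$detections
  expect_true(all(d$radius_px >= p$min_radius_px))
  expect_true(all(d$radius_px <= p$max_radius_px))
  if (nrow(d) > 1) {
    dm <- as.matrix(dist(d[, c("center_x_px", "center_y_px")]))
    expect_true(all(dm[upper.tri(dm)] >= p$min_dist_px))
  }
})

test_that("raising the sensitivity threshold only removes detections", {
  gray <- to_grayscale(generate_scene(clean_scene(seed = 9, n_cells = 25))$image)
  key <- function(d) sprintf("%.3f_%.3f", d$center_x_px, d$center_y_px)
  lo <- detect_circles(gray, clean_det_params(sensitivity = 20))
  mid <- detect_circles(gray, clean_det_params(sensitivity = 30))
  hi <- detect_circles(gray, clean_det_params(sensitivity = 60))
  expect_true(all(key(hi$detections) %in% key(mid$detections)))
  expect_true(all(key(mid$detections) %in% key(lo$detections)))
})

test_that("masks rasterize filled disks with near-exact area and union semantics", {
  empty <- detection_set(image_height_px = 50, image_width_px = 60)
  expect_equal(sum(detections_to_mask(empty)), 0L)

  one <- detection_set(25, 25, 10, image_height_px = 51, image_width_px = 51)
  area <- sum(detections_to_mask(one))
  # brute-force oracle: lattice points within the disk
  brute <- sum(outer((0:50 - 25)^2, (0:50 - 25)^2, `+`) <= 100)
  expect_identical(area, brute)
  expect_lt(abs(area - pi * 100) / (pi * 100), 0.05)

  twoover <- detection_set(c(25, 31), c(25, 25), c(10, 10),
                           image_height_px = 51, image_width_px = 61)
  a2 <- sum(detections_to_mask(twoover))
  expect_lt(a2, 2 * brute)               # overlap merges
  expect_gt(a2, brute)
})

test_that("mask connected components match the count for separated cells", {
  sc <- generate_scene(clean_scene(seed = 5, n_cells = 20))
  ds <- count_cells(sc$image, clean_det_params())
  mask <- detections_to_mask(ds)
  ncomp <- max(EBImage::bwlabel(t(mask)))
  expect_lte(ncomp, ds$count)
  expect_equal(ncomp, ds$count)  # separation 66 > 2 * max radius 30
})

test_that("the full pipeline is deterministic and recovers clean-scene counts", {
  sc <- generate_scene(clean_scene(seed = 14, n_cells = 30))
  a <- count_cells(sc$image, clean_det_params())
  b <- count_cells(sc$image, clean_det_params())
  expect_identical(a, b)
  expect_equal(a$count, 30L)

  grid_only <- generate_scene(clean_scene(seed = 15, n_cells = 0))
  expect_equal(count_cells(grid_only$image, clean_det_params())$count, 0L)
})

test_that("parameter validation catches inconsistent detector settings", {
  expect_error(detection_params(min_radius_px = 0), "min_radius")
  expect_error(detection_params(min_radius_px = 50, max_radius_px = 40),
               "min_radius")
  expect_error(detection_params(median_kernel = 4), "odd")
  expect_error(detection_params(sensitivity = 0), "sensitivity")
  # the distance >= 2 * max radius advisory is a message, not an error
  expect_message(detection_params(), "advisory")
  expect_no_message(detection_params(min_dist_px = 200))
})
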