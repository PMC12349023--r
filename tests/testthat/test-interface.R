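test_that("run_calibrate reproduces a known scale from cropped squares on disk", {
  dir <- file.path(tempdir(), "crops")
  dir.create(dir, showWarnings = FALSE)
  # squares rendered at ~122 px for a 0.05 mm side: s = 0.05/122 scaled setup
  for (k in c(121, 122, 122, 122, 123)) {
    img <- array(180, dim = c(k, k, 3))
    write_image_rgb(img, file.path(dir, sprintf("sq_%d_%d.png", k,
                                                sample.int(1e6, 1))))
  }
  ch <- chamber_spec("Goryaev", 0.05, 0.1)
  out <- file.path(tempdir(), "cal.json")
  rpt <- file.path(tempdir(), "cal.txt")
  cal <- suppressMessages(run_calibrate(dir, ch, image_height_px = 302,
                                        image_width_px = 403,
                                        out_json = out, out_report = rpt))
  expect_equal(cal$etalon$mean_px, 122)
  expect_equal(cal$conversion_factor_mm_per_px, 0.05 / 122)
  expect_true(file.exists(out) && file.exists(rpt))

  # rerunning yields a byte-identical artifact
  out2 <- file.path(tempdir(), "cal2.json")
  suppressMessages(run_calibrate(dir, ch, 302, 403, out_json = out2))
  expect_identical(readLines(out), readLines(out2))

  empty <- file.path(tempdir(), "no_crops")
  dir.create(empty, showWarnings = FALSE)
  expect_error(suppressMessages(run_calibrate(empty, ch, 302, 403,
                                              out_json = out)), "no etalon")
})

test_that("run_count writes per-image and summary CSVs with rounded summaries", {
  scenes <- lapply(1:3, function(i) {
    generate_scene(small_scene(seed = 60 + i, n_cells = 8 + i))
  })
  imgs <- lapply(scenes, function(s) s$image)
  names(imgs) <- sprintf("img_%d", 1:3)
  cal <- small_calibration()
  out <- file.path(tempdir(), "countrun")
  sc <- run_count(imgs, cal, dilution = 2, out_dir = out,
                  params = small_det_params(), overlays = TRUE)
  expect_equal(sc$n_images, 3L)
  expect_equal(sc$per_image$count, c(9L, 10L, 11L))

  per <- read.csv(file.path(out, "per_image.csv"))
  expect_equal(per$count, c(9, 10, 11))
  expect_equal(per$concentration_cells_per_ml,
               concentration_from_count(c(9, 10, 11), cal, 2))
  summ <- read.csv(file.path(out, "sample_summary.csv"))
  expect_equal(summ$mean_cells_per_ml, round(sc$mean_cells_per_ml))
  expect_equal(summ$n_images, 3)
  expect_true(file.exists(file.path(out, "img_1_overlay.png")))

  # determinism: identical CSV bytes on a rerun
  out2 <- file.path(tempdir(), "countrun2")
  run_count(imgs, cal, dilution = 2, out_dir = out2,
            params = small_det_params())
  expect_identical(readLines(file.path(out, "per_image.csv")),
                   readLines(file.path(out2, "per_image.csv")))

  # blank image: zero cells, zero concentration
  blank <- list(blank = array(200, dim = c(120, 160, 3)))
  sb <- run_count(blank, cal, params = small_det_params())
  expect_equal(sb$per_image$count, 0L)
  expect_equal(sb$per_image$concentration_cells_per_ml, 0)

  expect_error(run_count(imgs, "/nonexistent/cal.json"), "not found")
  expect_error(run_count(list(), cal), "no input images")
})

test_that("run_validate computes MAE, summaries and flags id mismatches", {
  truth <- data.frame(image_id = c("a", "b", "c"), count = c(10, 20, 30))
  perfect <- run_validate(truth, truth)
  expect_equal(perfect$value[perfect$metric == "mae"], 0)
  expect_equal(perfect$value[perfect$metric == "pearson_r"], 1)

  pred <- data.frame(image_id = c("a", "b", "c"), count = c(12, 18, 33))
  m <- run_validate(pred, truth)
  expect_equal(m$value[m$metric == "mae"], 7 / 3)

  bad <- data.frame(image_id = c("a", "x"), count = c(1, 2))
  expect_error(run_validate(bad, truth), "x")
  expect_error(run_validate("/nope.csv", truth), "not found")
})

test_that("run_simulate emits a corpus whose truth matches the counted masks", {
  out <- file.path(tempdir(), "corpus")
  counts <- run_simulate(out, n_images = 2,
                         base_params = small_scene(seed = 80, n_cells = 6))
  files <- list.files(file.path(out, "images"))
  expect_length(files, 2L)
  expect_true(file.exists(file.path(out, "truth_cells.csv")))
  truth <- read.csv(file.path(out, "truth_cells.csv"))
  expect_equal(nrow(truth), 12L)  # 6 cells x 2 scenes
  # masks round-trip through PNG
  mask <- to_grayscale(read_image_rgb(file.path(out, "masks",
                                                "scene_001.png"))) > 0
  sc <- generate_scene(small_scene(seed = 80, n_cells = 6))
  expect_identical(mask_iou(mask, sc$truth_mask), 1)
})

test_that("annotation draws strokes without touching other pixels", {
  sc <- generate_scene(small_scene(seed = 90, n_cells = 5))
  ds <- count_cells(sc$image, small_det_params())
  empty <- detection_set(image_height_px = 480, image_width_px = 640)
  expect_identical(annotate_image(sc$image, empty), sc$image)

  ann <- annotate_image(sc$image, ds)
  changed <- which(ann != sc$image, arr.ind = TRUE)
  expect_gt(nrow(changed), 0)
  d <- ds$detections
  for (i in seq_len(nrow(changed))) {
    dx <- changed[i, 2] - 1 - d$center_x_px
    dy <- changed[i, 1] - 1 - d$center_y_px
    on_ring <- abs(sqrt(dx^2 + dy^2) - d$radius_px) <= 1.01
    expect_true(any(on_ring))
  }
})
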