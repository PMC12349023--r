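# Workflow runners tying calibration -> detection -> quantification ->
# metrics -> simulation together, with the CSV/JSON/PNG plumbing that makes
# every step auditable: calibration reports, per-image detection CSVs,
# annotated overlays for visual verification, and validation metrics.

.image_files <- function(dir) {
  list.files(dir, pattern = "\\.(png|jpe?g|tiff?)$", ignore.case = TRUE,
             full.names = TRUE)
}

#' Calibrate from a folder of cropped etalon squares
#'
#' Reads every image in `squares_dir` (each cropped to one chamber grid
#' square), measures its width and height in pixels, summarizes the
#' measurements, and builds the calibration for the given chamber and camera
#' frame size. Writes the JSON artifact and a plain-text report.
#'
#' @param squares_dir Directory of cropped square images (PNG/JPEG/TIFF).
#' @param chamber A [chamber_spec()].
#' @param image_height_px,image_width_px Full camera frame size, px.
#' @param out_json Path for the calibration artifact (JSON).
#' @param out_report Optional path for the text report.
#' @return The `calibration`, invisibly.
#' @export
run_calibrate <- function(squares_dir, chamber, image_height_px,
                          image_width_px, out_json,
                          out_report = NULL) {
  if (!dir.exists(squares_dir))
    stop("squares directory not found: ", squares_dir, call. = FALSE)
  files <- .image_files(squares_dir)
  if (length(files) == 0L)
    stop("no etalon crops found in ", squares_dir, call. = FALSE)
  lengths <- edge_lengths_from_crops(files)
  cal <- calibrate(summarize_etalon(lengths), chamber,
                   image_height_px, image_width_px)
  build_calibration_report(cal, report_path = out_report,
                           artifact_path = out_json)
  message(sprintf("image volume V_img = %.6g mm^3", cal$image_volume_mm3))
  invisible(cal)
}

#' Count cells and estimate concentration for a sample
#'
#' Runs the detection pipeline on every image, converts counts to cells/mL
#' with the calibration and dilution, and writes a per-image CSV plus a
#' one-row sample summary CSV. Per-image concentrations are written at full
#' precision; summary concentrations are integer-rounded (standard
#' biological reporting). Unreadable images produce a warning and are
#' skipped; an empty image set is an error.
#'
#' @param images Directory of images, or a character vector of image paths,
#'   or a list of H x W x 3 arrays (named for image ids).
#' @param calibration A `calibration` object or path to its JSON artifact.
#' @param dilution Dilution factor D (>= 1).
#' @param out_dir Output directory (created if missing); `NULL` writes
#'   nothing.
#' @param params [detection_params()] to use.
#' @param overlays If `TRUE`, write an annotated overlay PNG per image.
#' @param sample_id Label used in the summary.
#' @return A `sample_concentration`, invisibly when `out_dir` is given.
#' @export
run_count <- function(images, calibration, dilution = 1, out_dir = NULL,
                      params = detection_params(), overlays = FALSE,
                      sample_id = "sample") {
  if (is.character(calibration)) calibration <- read_calibration(calibration)
  if (!inherits(calibration, "calibration"))
    stop("`calibration` must be a calibration object or artifact path",
         call. = FALSE)
  if (is.character(images) && length(images) == 1L && dir.exists(images))
    images <- .image_files(images)
  if (length(images) == 0L) stop("no input images", call. = FALSE)
  ids <- if (is.list(images) && !is.null(names(images))) names(images)
         else if (is.character(images)) tools::file_path_sans_ext(basename(images))
         else sprintf("image_%03d", seq_along(images))
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  rows <- list()
  for (i in seq_along(images)) {
    img <- tryCatch(
      if (is.character(images)) read_image_rgb(images[[i]]) else images[[i]],
      error = function(e) {
        warning(sprintf("skipping unreadable image %s: %s", ids[i],
                        conditionMessage(e)), call. = FALSE)
        NULL
      })
    if (is.null(img)) next
    dset <- count_cells(img, params)
    conc <- concentration_from_count(dset$count, calibration, dilution)
    rows[[length(rows) + 1L]] <- data.frame(
      image_id = ids[i], count = dset$count,
      concentration_cells_per_ml = conc)
    if (!is.null(out_dir) && overlays)
      write_image_rgb(annotate_image(img, dset),
                      file.path(out_dir, paste0(ids[i], "_overlay.png")))
    if (!is.null(out_dir)) {
      det <- dset$detections
      det$image_id <- ids[i]
      utils::write.csv(det[, c("image_id", "center_x_px", "center_y_px",
                               "radius_px")],
                       file.path(out_dir, paste0(ids[i], "_detections.csv")),
                       row.names = FALSE)
    }
  }
  if (length(rows) == 0L) stop("no readable images", call. = FALSE)
  per_image <- do.call(rbind, rows)
  sc <- aggregate_sample(per_image, sample_id = sample_id, dilution = dilution)
  if (!is.null(out_dir)) {
    utils::write.csv(per_image, file.path(out_dir, "per_image.csv"),
                     row.names = FALSE)
    summary_df <- data.frame(
      sample_id = sc$sample_id, dilution = sc$dilution, n_images = sc$n_images,
      mean_cells_per_ml = round(sc$mean_cells_per_ml),
      median_cells_per_ml = round(sc$median_cells_per_ml),
      std_cells_per_ml = round(sc$std_cells_per_ml))
    utils::write.csv(summary_df, file.path(out_dir, "sample_summary.csv"),
                     row.names = FALSE)
    return(invisible(sc))
  }
  sc
}

#' Validate predicted counts (and masks) against ground truth
#'
#' Joins prediction and truth tables on `image_id` (an error lists any
#' offending ids), then computes the count MAE, per-image percentage
#' differences with their column summary, the Pearson correlation between
#' truth and prediction, and -- when mask directories are supplied --
#' per-image IoU. Results go to a metrics CSV.
#'
#' @param pred,truth Data frames (or CSV paths) with columns `image_id`,
#'   `count`.
#' @param out_csv Optional output CSV path for the metric table.
#' @param pred_masks,truth_masks Optional directories of same-named mask
#'   PNGs (non-zero = foreground).
#' @return Data frame of metrics (`metric`, `value`), one row per metric,
#'   plus per-image IoU rows when masks are given.
#' @export
run_validate <- function(pred, truth, out_csv = NULL, pred_masks = NULL,
                         truth_masks = NULL) {
  if (is.character(pred)) {
    if (!file.exists(pred)) stop("prediction file not found: ", pred, call. = FALSE)
    pred <- utils::read.csv(pred)
  }
  if (is.character(truth)) {
    if (!file.exists(truth)) stop("truth file not found: ", truth, call. = FALSE)
    truth <- utils::read.csv(truth)
  }
  only_p <- setdiff(pred$image_id, truth$image_id)
  only_t <- setdiff(truth$image_id, pred$image_id)
  if (length(only_p) || length(only_t))
    stop("image ids do not match; prediction-only: [",
         paste(only_p, collapse = ", "), "], truth-only: [",
         paste(only_t, collapse = ", "), "]", call. = FALSE)
  m <- merge(truth, pred, by = "image_id", suffixes = c("_true", "_pred"))
  out <- data.frame(metric = "mae",
                    value = count_mae(m$count_true, m$count_pred))
  if (all(m$count_true > 0)) {
    pd <- percentage_difference(m$count_true, m$count_pred)
    cs <- column_summary(pd)
    out <- rbind(out, data.frame(
      metric = c("pct_diff_mean", "pct_diff_median", "pct_diff_sd"),
      value = c(cs$mean, cs$median, cs$sd_pop)))
  }
  if (stats::sd(m$count_true) > 0 && stats::sd(m$count_pred) > 0)
    out <- rbind(out, data.frame(
      metric = "pearson_r",
      value = pearson_correlation(m$count_true, m$count_pred)))
  if (!is.null(pred_masks) && !is.null(truth_masks)) {
    for (id in m$image_id) {
      pm <- file.path(pred_masks, paste0(id, ".png"))
      tm <- file.path(truth_masks, paste0(id, ".png"))
      if (!file.exists(pm) || !file.exists(tm)) next
      a <- to_grayscale(read_image_rgb(pm)) > 0
      b <- to_grayscale(read_image_rgb(tm)) > 0
      out <- rbind(out, data.frame(metric = paste0("iou_", id),
                                   value = mask_iou(a, b)))
    }
  }
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  out
}

#' Write a deterministic synthetic test corpus
#'
#' Generates `n_images` scenes from `base_params` (seed varied per image),
#' writing each frame as PNG, its truth mask as PNG, one truth CSV
#' (`image_id`, `center_x`, `center_y`, `radius`), a counts CSV
#' (`image_id`, `count`) and the scene parameters as JSON.
#'
#' @param out_dir Output directory.
#' @param n_images Number of scenes.
#' @param base_params [scene_params()] template.
#' @return The truth counts data frame, invisibly.
#' @export
run_simulate <- function(out_dir, n_images = 10L,
                         base_params = scene_params()) {
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  truth <- list(); counts <- list()
  for (i in seq_len(n_images)) {
    p <- base_params
    p$seed <- base_params$seed + i - 1L
    sc <- generate_scene(p)
    id <- sprintf("scene_%03d", i)
    write_image_rgb(sc$image, file.path(out_dir, "images", paste0(id, ".png")))
    mask <- array(rep(255 * (sc$truth_mask * 1), 3L),
                  dim = c(dim(sc$truth_mask), 3L))
    write_image_rgb(mask, file.path(out_dir, "masks", paste0(id, ".png")))
    if (sc$true_count > 0)
      truth[[i]] <- data.frame(image_id = id,
                               center_x = sc$true_centers$x,
                               center_y = sc$true_centers$y,
                               radius = sc$true_radii)
    counts[[i]] <- data.frame(image_id = id, count = sc$true_count)
  }
  truth_df <- do.call(rbind, truth)
  counts_df <- do.call(rbind, counts)
  utils::write.csv(truth_df, file.path(out_dir, "truth_cells.csv"),
                   row.names = FALSE)
  utils::write.csv(counts_df, file.path(out_dir, "truth_counts.csv"),
                   row.names = FALSE)
  jsonlite::write_json(unclass(base_params),
                       file.path(out_dir, "scene_params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(counts_df)
}

#' Draw detection circles onto an image
#'
#' Overlays each detection as a circle outline for visual verification.
#' Pixels outside the drawn strokes are unchanged.
#'
#' @param image H x W x 3 RGB array, 0..255.
#' @param dset A `detection_set` with matching dimensions.
#' @param color RGB triple for the stroke.
#' @param thickness Stroke width, px.
#' @return The annotated RGB array.
#' @export
annotate_image <- function(image, dset, color = c(255, 40, 40),
                           thickness = 2) {
  .assert_rgb(image)
  if (!inherits(dset, "detection_set"))
    stop("`dset` must be a detection_set", call. = FALSE)
  if (dset$image_height_px != dim(image)[1L] ||
      dset$image_width_px != dim(image)[2L])
    stop("image and detection set dimensions differ", call. = FALSE)
  H <- dim(image)[1L]; W <- dim(image)[2L]
  d <- dset$detections
  for (i in seq_len(nrow(d))) {
    cx <- d$center_x_px[i]; cy <- d$center_y_px[i]; r <- d$radius_px[i]
    ext <- r + thickness
    rows <- max(1L, floor(cy - ext) + 1L):min(H, ceiling(cy + ext) + 1L)
    cols <- max(1L, floor(cx - ext) + 1L):min(W, ceiling(cx + ext) + 1L)
    dist <- sqrt(outer(((rows - 1L) - cy)^2, ((cols - 1L) - cx)^2, `+`))
    ring <- abs(dist - r) <= thickness / 2
    for (ch in 1:3) {
      sub <- image[rows, cols, ch]
      sub[ring] <- color[ch]
      image[rows, cols, ch] <- sub
    }
  }
  image
}
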