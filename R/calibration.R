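# Calibration of microscope + counting-chamber geometry.
#
# The chamber's etched grid squares have a manufacturer-stated side length l
# (mm). The operator crops a handful of squares out of microscope frames so
# that each crop's borders coincide with one square's edges; the crops' pixel
# dimensions are then measurements p of l in pixels. Their mean gives the
# conversion factor s = l / p (mm per pixel), and with the camera frame size
# (PH x PW pixels) and chamber depth h (mm) the suspension volume under one
# full frame is V_img = (s * PH) * (s * PW) * h, in mm^3.

#' Counting-chamber specification
#'
#' Manufacturer geometry of a hemocytometer: the etalon grid-square side
#' length, its stated tolerance, and the chamber depth. The small-square area
#' `small_square_area_mm2` is only needed for the manual counting formula
#' ([manual_concentration()]).
#'
#' @param name Chamber label, e.g. `"Goryaev"`.
#' @param square_side_mm Side length l of the etalon grid square, mm (> 0).
#' @param depth_mm Chamber depth h, mm (> 0).
#' @param side_tolerance_mm Manufacturer tolerance on the side length, mm.
#' @param small_square_area_mm2 Optional area S of one counting square, mm^2.
#' @return A `chamber_spec` object.
#' @examples
#' chamber_spec("Goryaev", square_side_mm = 0.05, depth_mm = 0.1)
#' @export
chamber_spec <- function(name, square_side_mm, depth_mm,
                         side_tolerance_mm = 0,
                         small_square_area_mm2 = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(square_side_mm) || length(square_side_mm) != 1L ||
      !is.finite(square_side_mm) || square_side_mm <= 0)
    stop("`square_side_mm` must be a single positive number", call. = FALSE)
  if (!is.numeric(depth_mm) || length(depth_mm) != 1L ||
      !is.finite(depth_mm) || depth_mm <= 0)
    stop("`depth_mm` must be a single positive number", call. = FALSE)
  if (!is.numeric(side_tolerance_mm) || side_tolerance_mm < 0)
    stop("`side_tolerance_mm` must be >= 0", call. = FALSE)
  if (!is.null(small_square_area_mm2) &&
      (!is.numeric(small_square_area_mm2) || small_square_area_mm2 <= 0))
    stop("`small_square_area_mm2` must be > 0 when given", call. = FALSE)
  structure(
    list(name = name,
         square_side_mm = square_side_mm,
         depth_mm = depth_mm,
         side_tolerance_mm = side_tolerance_mm,
         small_square_area_mm2 = small_square_area_mm2),
    class = "chamber_spec")
}

#' @export
print.chamber_spec <- function(x, ...) {
  cat(sprintf("<chamber_spec> %s: square side %g +/- %g mm, depth %g mm\n",
              x$name, x$square_side_mm, x$side_tolerance_mm, x$depth_mm))
  invisible(x)
}

#' Edge lengths from cropped etalon squares
#'
#' Each crop is an image whose borders coincide with one chamber square's
#' edges, so the crop's own width and height in pixels are two measurements
#' of the square side. Both are returned (order-stable: width then height per
#' crop), which also tolerates slight grid tilt.
#'
#' @param crops A list of images (H x W or H x W x 3 arrays) or a character
#'   vector of image file paths.
#' @return Numeric vector of pixel lengths, `2 * length(crops)` long.
#' @export
edge_lengths_from_crops <- function(crops) {
  if (is.character(crops)) crops <- lapply(crops, read_image_rgb)
  if (!is.list(crops) || length(crops) == 0L)
    stop("no etalon crops supplied; cannot calibrate", call. = FALSE)
  out <- numeric(0)
  for (i in seq_along(crops)) {
    d <- dim(crops[[i]])
    if (is.null(d) || length(d) < 2L || d[1L] < 1L || d[2L] < 1L)
      stop(sprintf("crop %d is not a valid 2-D image", i), call. = FALSE)
    out <- c(out, d[2L], d[1L])  # width, height
  }
  out
}

#' Summarize etalon square measurements
#'
#' Mean and population (divide-by-n) standard deviation of the pixel lengths
#' measured for the chamber's etalon squares. Good practice is to measure at
#' least five squares from different parts of the chamber; fewer triggers a
#' warning, not an error.
#'
#' @param lengths_px Positive numeric vector of measured square sides, px.
#' @return An `etalon_stats` object with `lengths_px`, `n_measurements`,
#'   `mean_px`, `std_px`.
#' @examples
#' summarize_etalon(c(1200, 1244))
#' @export
summarize_etalon <- function(lengths_px) {
  if (length(lengths_px) == 0L)
    stop("no etalon measurements supplied", call. = FALSE)
  if (!is.numeric(lengths_px) || anyNA(lengths_px) || any(lengths_px <= 0))
    stop("etalon measurements must all be positive numbers", call. = FALSE)
  if (length(lengths_px) < 5)
    warning(sprintf(
      "only %d etalon measurement(s); measuring at least 5 squares from different chamber regions is recommended",
      length(lengths_px)), call. = FALSE)
  m <- mean(lengths_px)
  s <- sqrt(mean((lengths_px - m)^2))
  structure(
    list(lengths_px = as.numeric(lengths_px),
         n_measurements = length(lengths_px),
         mean_px = m, std_px = s),
    class = "etalon_stats")
}

#' @export
print.etalon_stats <- function(x, ...) {
  cat(sprintf("<etalon_stats> n = %d, %0.0f +/- %0.0f px\n",
              x$n_measurements, x$mean_px, x$std_px))
  invisible(x)
}

#' Pixel-to-millimetre conversion factor
#'
#' `s = l / p`: the chamber square's stated side length divided by its mean
#' measured pixel length. Carried unrounded; round only for display.
#'
#' @param stats An `etalon_stats` object (or a bare positive mean in px).
#' @param chamber A [chamber_spec()].
#' @return Conversion factor s in mm per pixel.
#' @examples
#' conversion_factor(summarize_etalon(c(1222, 1222)),
#'                   chamber_spec("Goryaev", 0.05, 0.1))
#' @export
conversion_factor <- function(stats, chamber) {
  p <- if (inherits(stats, "etalon_stats")) stats$mean_px else stats
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p <= 0)
    stop("mean etalon length must be a positive number", call. = FALSE)
  if (!inherits(chamber, "chamber_spec"))
    stop("`chamber` must be a chamber_spec", call. = FALSE)
  chamber$square_side_mm / p
}

#' Suspension volume covered by one full image
#'
#' `V_img = (s * PH) * (s * PW) * h` in mm^3: the image footprint converted
#' to mm via the conversion factor, times the chamber depth. Unrounded.
#'
#' @param s Conversion factor, mm per pixel (> 0).
#' @param image_height_px,image_width_px Camera frame size in pixels (>= 1).
#' @param depth_mm Chamber depth h, mm (> 0).
#' @return Image volume in mm^3.
#' @examples
#' image_volume(4.1e-5, 3024, 4032, 0.1)
#' @export
image_volume <- function(s, image_height_px, image_width_px, depth_mm) {
  vals <- c(s = s, PH = image_height_px, PW = image_width_px, h = depth_mm)
  if (!is.numeric(vals) || anyNA(vals) || any(vals <= 0))
    stop("all of s, image dimensions and depth must be positive", call. = FALSE)
  (s * image_height_px) * (s * image_width_px) * depth_mm
}

#' Assemble a calibration for one equipment setup
#'
#' Binds the etalon statistics, chamber geometry and camera frame size into a
#' calibration object holding the conversion factor and image volume. One
#' calibration is valid for a fixed combination of chamber type, microscope
#' magnification and camera resolution.
#'
#' @param etalon An `etalon_stats` object.
#' @param chamber A [chamber_spec()].
#' @param image_height_px,image_width_px Camera frame size in pixels.
#' @return A `calibration` object.
#' @export
calibrate <- function(etalon, chamber, image_height_px, image_width_px) {
  if (!inherits(etalon, "etalon_stats"))
    stop("`etalon` must be an etalon_stats object", call. = FALSE)
  if (!inherits(chamber, "chamber_spec"))
    stop("`chamber` must be a chamber_spec", call. = FALSE)
  if (image_height_px < 1 || image_width_px < 1)
    stop("image dimensions must be >= 1 px", call. = FALSE)
  s <- conversion_factor(etalon, chamber)
  structure(
    list(conversion_factor_mm_per_px = s,
         image_height_px = as.integer(image_height_px),
         image_width_px = as.integer(image_width_px),
         image_volume_mm3 = image_volume(s, image_height_px, image_width_px,
                                         chamber$depth_mm),
         chamber = chamber,
         etalon = etalon),
    class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat(.calibration_report_text(x), sep = "\n")
  invisible(x)
}

.calibration_report_text <- function(cal) {
  c("Equipment calibration report",
    "============================",
    sprintf("Chamber:            %s (square side %g +/- %g mm, depth %g mm)",
            cal$chamber$name, cal$chamber$square_side_mm,
            cal$chamber$side_tolerance_mm, cal$chamber$depth_mm),
    sprintf("Etalon squares:     %d measurements, %0.0f +/- %0.0f px",
            cal$etalon$n_measurements, cal$etalon$mean_px, cal$etalon$std_px),
    sprintf("Conversion factor:  s = %.2g mm/px (unrounded %.6g)",
            cal$conversion_factor_mm_per_px, cal$conversion_factor_mm_per_px),
    sprintf("Frame size:         %d x %d px (W x H)",
            cal$image_width_px, cal$image_height_px),
    sprintf("Image volume:       V_img = %.1g mm^3 (unrounded %.6g)",
            cal$image_volume_mm3, cal$image_volume_mm3))
}

#' Build a human-readable calibration report and machine artifact
#'
#' The report echoes the etalon statistics (mean +/- SD), the conversion
#' factor (displayed at 2 significant figures, carried unrounded), frame
#' size, chamber depth and the resulting image volume. The JSON artifact
#' round-trips losslessly through [read_calibration()].
#'
#' @param calibration A `calibration` object.
#' @param report_path Optional path for the plain-text report.
#' @param artifact_path Optional path for the JSON calibration artifact.
#' @return A list with `text` (character vector of report lines) and
#'   `calibration`, invisibly if any path was written.
#' @export
build_calibration_report <- function(calibration, report_path = NULL,
                                     artifact_path = NULL) {
  if (!inherits(calibration, "calibration"))
    stop("`calibration` must be a calibration object", call. = FALSE)
  if (!inherits(calibration$chamber, "chamber_spec"))
    stop("calibration is missing its chamber specification", call. = FALSE)
  txt <- .calibration_report_text(calibration)
  if (!is.null(report_path)) writeLines(txt, report_path)
  if (!is.null(artifact_path)) write_calibration(calibration, artifact_path)
  out <- list(text = txt, calibration = calibration)
  if (is.null(report_path) && is.null(artifact_path)) out else invisible(out)
}

#' Serialize a calibration to JSON
#'
#' @param calibration A `calibration` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(calibration, path) {
  if (!inherits(calibration, "calibration"))
    stop("`calibration` must be a calibration object", call. = FALSE)
  ch <- unclass(calibration$chamber)
  x <- list(
    chamber = ch[!vapply(ch, is.null, TRUE)],
    etalon = unclass(calibration$etalon),
    image_height_px = calibration$image_height_px,
    image_width_px = calibration$image_width_px,
    conversion_factor_mm_per_px = calibration$conversion_factor_mm_per_px,
    image_volume_mm3 = calibration$image_volume_mm3)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a calibration artifact written by [write_calibration()]
#'
#' @param path JSON path.
#' @return A `calibration` object.
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) stop("calibration artifact not found: ", path, call. = FALSE)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  chamber <- chamber_spec(
    name = x$chamber$name,
    square_side_mm = x$chamber$square_side_mm,
    depth_mm = x$chamber$depth_mm,
    side_tolerance_mm = x$chamber$side_tolerance_mm %||% 0,
    small_square_area_mm2 = x$chamber$small_square_area_mm2)
  etalon <- summarize_etalon(x$etalon$lengths_px)
  calibrate(etalon, chamber, x$image_height_px, x$image_width_px)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
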