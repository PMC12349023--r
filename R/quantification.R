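# Counts -> cells/mL.
#
# Manual hemocytometer counting uses N = a * 10^3 / (h * S): mean cells per
# grid square over the square's volume, with 10^3 converting mm^3 to mL. The
# automated path replaces the square volume with the calibrated image volume
# V_img and scales by the dilution factor D, so one microscope frame yields
# one concentration estimate; several frames per sample are aggregated.

#' Manual hemocytometer concentration
#'
#' `N = a * 10^3 / (h * S)` cells/mL, where `a` is the mean number of cells
#' counted per grid square, `h` the chamber depth (mm) and `S` the square
#' area (mm^2).
#'
#' @param mean_cells_per_square Mean count per chamber square (>= 0).
#' @param depth_mm Chamber depth, mm (> 0).
#' @param square_area_mm2 Area of one counting square, mm^2 (> 0).
#' @return Concentration in cells/mL.
#' @examples
#' manual_concentration(5, depth_mm = 0.1, square_area_mm2 = 0.04)
#' @export
manual_concentration <- function(mean_cells_per_square, depth_mm,
                                 square_area_mm2) {
  if (mean_cells_per_square < 0)
    stop("cell count must be >= 0", call. = FALSE)
  if (!is.finite(depth_mm) || depth_mm <= 0 ||
      !is.finite(square_area_mm2) || square_area_mm2 <= 0)
    stop("chamber depth and square area must be positive", call. = FALSE)
  mean_cells_per_square * 1e3 / (depth_mm * square_area_mm2)
}

#' Automated per-image concentration
#'
#' `N = a_img * D * 10^3 / V_img` cells/mL: the per-image cell count over the
#' calibrated image volume (mm^3), multiplied by the dilution factor D to
#' recover the undiluted sample's concentration. Values are kept unrounded
#' here; integer rounding is applied only to final per-sample reports.
#'
#' @param count Cells detected in the image (>= 0).
#' @param image_volume_mm3 Calibrated image volume, mm^3 (> 0), or a
#'   `calibration` object.
#' @param dilution Dilution factor D (>= 1).
#' @return Concentration in cells/mL.
#' @examples
#' concentration_from_count(10, 0.002, dilution = 1)
#' @export
concentration_from_count <- function(count, image_volume_mm3, dilution = 1) {
  if (inherits(image_volume_mm3, "calibration"))
    image_volume_mm3 <- image_volume_mm3$image_volume_mm3
  if (any(count < 0)) stop("`count` must be >= 0", call. = FALSE)
  if (!is.finite(image_volume_mm3) || image_volume_mm3 <= 0)
    stop("`image_volume_mm3` must be positive", call. = FALSE)
  if (any(dilution < 1)) stop("`dilution` must be >= 1", call. = FALSE)
  count * dilution * 1e3 / image_volume_mm3
}

#' Expected per-image count at a known concentration
#'
#' Inverse of [concentration_from_count()]:
#' `a = C * V_img / (10^3 * D)`. Used by the scene simulator and by
#' [recommend_dilution()].
#'
#' @param true_concentration Cells/mL (>= 0).
#' @param image_volume_mm3 Image volume, mm^3 (> 0), or a `calibration`.
#' @param dilution Dilution factor D (>= 1).
#' @return Expected number of cells per image (real, not rounded).
#' @export
expected_count <- function(true_concentration, image_volume_mm3, dilution = 1) {
  if (inherits(image_volume_mm3, "calibration"))
    image_volume_mm3 <- image_volume_mm3$image_volume_mm3
  if (any(true_concentration < 0))
    stop("`true_concentration` must be >= 0", call. = FALSE)
  if (!is.finite(image_volume_mm3) || image_volume_mm3 <= 0)
    stop("`image_volume_mm3` must be positive", call. = FALSE)
  if (any(dilution < 1)) stop("`dilution` must be >= 1", call. = FALSE)
  true_concentration * image_volume_mm3 / (1e3 * dilution)
}

#' Aggregate per-image concentrations into a sample estimate
#'
#' Mean, median and population (divide-by-n) standard deviation over the
#' per-image cells/mL values. The mean is the headline estimate: all chamber
#' regions are technically equivalent, and the mean does not differ
#' materially in quality from the median.
#'
#' @param per_image Data frame with columns `image_id`, `count`,
#'   `concentration_cells_per_ml` (as produced by [run_count()]), or a bare
#'   numeric vector of concentrations.
#' @param sample_id Sample label.
#' @param dilution Dilution factor used for the sample.
#' @return A `sample_concentration` object.
#' @export
aggregate_sample <- function(per_image, sample_id = "sample", dilution = 1) {
  if (is.numeric(per_image))
    per_image <- data.frame(image_id = as.character(seq_along(per_image)),
                            count = NA_integer_,
                            concentration_cells_per_ml = per_image)
  if (!is.data.frame(per_image) || nrow(per_image) == 0L)
    stop("`per_image` must contain at least one image", call. = FALSE)
  if (!"concentration_cells_per_ml" %in% names(per_image))
    stop("`per_image` needs a `concentration_cells_per_ml` column", call. = FALSE)
  v <- per_image$concentration_cells_per_ml
  structure(
    list(sample_id = sample_id,
         dilution = dilution,
         per_image = per_image,
         n_images = nrow(per_image),
         mean_cells_per_ml = mean(v),
         median_cells_per_ml = stats::median(v),
         std_cells_per_ml = sqrt(mean((v - mean(v))^2))),
    class = "sample_concentration")
}

#' @export
print.sample_concentration <- function(x, ...) {
  cat(sprintf("<sample_concentration> %s (D = %g, %d images)\n",
              x$sample_id, x$dilution, x$n_images))
  # final reporting convention: integer cells/mL at sample level
  cat(sprintf("  mean   %s cells/mL\n  median %s cells/mL\n  SD     %s cells/mL\n",
              format(round(x$mean_cells_per_ml), big.mark = ","),
              format(round(x$median_cells_per_ml), big.mark = ","),
              format(round(x$std_cells_per_ml), big.mark = ",")))
  invisible(x)
}

#' Recommend a dilution factor for a target counting density
#'
#' Counting is most reliable at roughly 10-60 cells per field of view: more
#' and cells overlap, fewer and the estimate becomes noisy. Given a rough
#' concentration estimate, returns the smallest dilution from the 1-2-5
#' series (1, 2, 5, 10, 20, 50, 100, ...) whose expected per-image count is
#' at most 60. Warns when even undiluted imaging is expected to yield fewer
#' than 10 cells per frame.
#'
#' @param estimated_concentration Rough cells/mL estimate (> 0).
#' @param image_volume_mm3 Image volume, mm^3 (> 0), or a `calibration`.
#' @return Recommended dilution factor (>= 1).
#' @export
recommend_dilution <- function(estimated_concentration, image_volume_mm3) {
  if (!is.finite(estimated_concentration) || estimated_concentration <= 0)
    stop("`estimated_concentration` must be positive", call. = FALSE)
  series <- as.vector(outer(c(1, 2, 5), 10^(0:9)))
  for (D in series) {
    a <- expected_count(estimated_concentration, image_volume_mm3, D)
    if (a <= 60) {
      if (D == 1 && a < 10)
        warning(sprintf(
          "expected only %.1f cells per image even undiluted; consider more images per sample",
          a), call. = FALSE)
      return(D)
    }
  }
  utils::tail(series, 1)
}
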