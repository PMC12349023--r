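# Cell detection: the classical image-processing chain.
#
# Chlorella vulgaris absorbs strongly in the green band (chlorophyll), so the
# green channel is contrast-enhanced with CLAHE before the luminance
# grayscale conversion; a small median filter removes salt-and-pepper sensor
# noise; a gradient-voting Hough circle transform then detects the
# near-spherical cells as circles within a biologically grounded radius
# range.

#' Detection parameters
#'
#' Defaults follow the reference configuration for 4032 x 3024 frames of
#' *Chlorella vulgaris* (cell diameter 2-10 um): radii between 15 and 100 px,
#' a minimum distance of 100 px between detected centers, and an
#' accumulator-evidence threshold ("sensitivity") of 30 -- lower values admit
#' more candidate circles (higher recall), higher values fewer (higher
#' precision). A geometric advisory holds that `min_dist_px` should be at
#' least `2 * max_radius_px` so neighbouring detections cannot overlap; the
#' reference defaults themselves violate it, so violations are logged as a
#' message, never an error.
#'
#' @param min_radius_px,max_radius_px Radius search bounds, px.
#' @param min_dist_px Minimum distance between detected centers, px.
#' @param sensitivity Accumulator-evidence threshold (> 0).
#' @param median_kernel Median filter window (odd, >= 1); 1 disables.
#' @param clahe_clip CLAHE clip limit for the green channel.
#' @param clahe_tiles Integer pair: CLAHE tile grid (columns, rows).
#' @param gradient_threshold Sobel gradient magnitude above which a pixel is
#'   treated as edge evidence.
#' @return A `detection_params` object.
#' @export
detection_params <- function(min_radius_px = 15L, max_radius_px = 100L,
                             min_dist_px = 100L, sensitivity = 30,
                             median_kernel = 3L, clahe_clip = 2.0,
                             clahe_tiles = c(8L, 8L),
                             gradient_threshold = 100) {
  if (min_radius_px <= 0 || max_radius_px <= min_radius_px)
    stop("need 0 < min_radius_px < max_radius_px", call. = FALSE)
  if (min_dist_px <= 0) stop("`min_dist_px` must be > 0", call. = FALSE)
  if (sensitivity <= 0) stop("`sensitivity` must be > 0", call. = FALSE)
  if (median_kernel < 1 || median_kernel %% 2 == 0)
    stop("`median_kernel` must be odd and >= 1", call. = FALSE)
  if (length(clahe_tiles) != 2L || any(clahe_tiles < 1))
    stop("`clahe_tiles` must be two positive integers", call. = FALSE)
  if (gradient_threshold <= 0)
    stop("`gradient_threshold` must be > 0", call. = FALSE)
  if (min_dist_px < 2 * max_radius_px)
    message(sprintf(
      "advisory: min_dist_px (%g) < 2 * max_radius_px (%g); neighbouring detections may overlap",
      min_dist_px, 2 * max_radius_px))
  structure(
    list(min_radius_px = as.integer(min_radius_px),
         max_radius_px = as.integer(max_radius_px),
         min_dist_px = as.numeric(min_dist_px),
         sensitivity = as.numeric(sensitivity),
         median_kernel = as.integer(median_kernel),
         clahe_clip = as.numeric(clahe_clip),
         clahe_tiles = as.integer(clahe_tiles),
         gradient_threshold = as.numeric(gradient_threshold)),
    class = "detection_params")
}

#' Enhance the green channel with CLAHE
#'
#' Contrast-limited adaptive histogram equalization applied to the green
#' channel only; red and blue planes pass through bit-identical. This
#' amplifies the chlorophyll-specific signal of green microalgae while
#' bounding noise amplification via the clip limit.
#'
#' @param image H x W x 3 RGB array, values 0..255.
#' @param clahe_clip Clip limit (multiples of the uniform histogram height).
#' @param clahe_tiles Integer pair, tile grid (columns, rows).
#' @return RGB array of the same shape.
#' @export
enhance_green <- function(image, clahe_clip = 2.0, clahe_tiles = c(8L, 8L)) {
  .assert_rgb(image)
  g <- EBImage::Image(t(image[, , 2L]) / 255, colormode = "Grayscale")
  ge <- EBImage::clahe(g, nx = clahe_tiles[1L], ny = clahe_tiles[2L],
                       limit = clahe_clip, keep.range = FALSE)
  out <- image
  out[, , 2L] <- .clamp8(round(t(as.array(ge)) * 255))
  out
}

#' Luminance grayscale conversion
#'
#' `Y = 0.299 R + 0.587 G + 0.114 B`, rounded to the nearest integer and
#' clipped to 0..255.
#'
#' @param image H x W x 3 RGB array, values 0..255.
#' @return H x W matrix of 8-bit luminances.
#' @export
to_grayscale <- function(image) {
  .assert_rgb(image)
  .clamp8(round(0.299 * image[, , 1L] + 0.587 * image[, , 2L] +
                  0.114 * image[, , 3L]))
}

#' Median denoising
#'
#' Square median filter that removes salt-and-pepper noise from microscope
#' optics while preserving cell boundaries. `kernel = 1` is the identity.
#'
#' @param image H x W grayscale matrix, values 0..255.
#' @param kernel Odd window size >= 1.
#' @return Filtered matrix of the same shape.
#' @export
denoise_median <- function(image, kernel = 3L) {
  .assert_gray(image)
  if (kernel < 1 || kernel %% 2 == 0)
    stop("`kernel` must be odd and >= 1", call. = FALSE)
  if (kernel == 1L) return(image)
  median_filter_cpp(image, as.integer(kernel))
}

#' Detect circular cells in a grayscale image
#'
#' Gradient-voting (Hough) circle transform: Sobel edge pixels vote along
#' their gradient direction for centers at all radii in
#' `[min_radius_px, max_radius_px]`; accumulator maxima with at least
#' `sensitivity` votes become detections after non-maximum suppression at
#' `min_dist_px`. Radii are estimated from the radially aligned edge pixels
#' around each kept center. Detection uses gradient magnitude only, so cells
#' darker or lighter than the background are found alike. A blank image
#' yields an empty detection set, not an error.
#'
#' @param image H x W grayscale matrix, values 0..255.
#' @param params A [detection_params()] object.
#' @return A `detection_set` object.
#' @export
detect_circles <- function(image, params = detection_params()) {
  .assert_gray(image)
  if (!inherits(params, "detection_params"))
    stop("`params` must come from detection_params()", call. = FALSE)
  df <- hough_circles_cpp(image, params$min_radius_px, params$max_radius_px,
                          params$min_dist_px, params$sensitivity,
                          params$gradient_threshold)
  detection_set(df$center_x_px, df$center_y_px, df$radius_px,
                image_height_px = nrow(image), image_width_px = ncol(image),
                votes = df$votes)
}

#' Construct a detection set
#'
#' Coordinates are 0-based: `center_x_px` is the column offset, `center_y_px`
#' the row offset; both may be fractional (sub-pixel).
#'
#' @param center_x_px,center_y_px,radius_px Equal-length numeric vectors.
#' @param image_height_px,image_width_px Dimensions of the source image.
#' @param votes Optional accumulator evidence per detection.
#' @return A `detection_set` with a `detections` data frame and `count`.
#' @export
detection_set <- function(center_x_px = numeric(), center_y_px = numeric(),
                          radius_px = numeric(), image_height_px,
                          image_width_px, votes = NULL) {
  n <- length(center_x_px)
  if (length(center_y_px) != n || length(radius_px) != n)
    stop("center and radius vectors must have equal length", call. = FALSE)
  if (image_height_px < 1 || image_width_px < 1)
    stop("image dimensions must be >= 1", call. = FALSE)
  if (n > 0 && (any(center_x_px < 0) || any(center_x_px > image_width_px - 1) ||
                any(center_y_px < 0) || any(center_y_px > image_height_px - 1)))
    stop("detection centers must lie inside the image", call. = FALSE)
  if (n > 0 && any(radius_px <= 0))
    stop("radii must be positive", call. = FALSE)
  det <- data.frame(center_x_px = as.numeric(center_x_px),
                    center_y_px = as.numeric(center_y_px),
                    radius_px = as.numeric(radius_px))
  if (!is.null(votes)) det$votes <- as.numeric(votes)
  structure(
    list(detections = det,
         image_height_px = as.integer(image_height_px),
         image_width_px = as.integer(image_width_px),
         count = n),
    class = "detection_set")
}

#' @export
print.detection_set <- function(x, ...) {
  cat(sprintf("<detection_set> %d cell(s) in a %d x %d px image\n",
              x$count, x$image_width_px, x$image_height_px))
  if (x$count > 0) print(utils::head(x$detections, 10))
  invisible(x)
}

#' Rasterize detections into a binary mask
#'
#' The union of filled disks at each detection's center and radius. A pixel
#' at 0-based coordinates (x, y) is foreground when
#' `(x - cx)^2 + (y - cy)^2 <= r^2` for some detection.
#'
#' @param dset A `detection_set`.
#' @return Logical H x W matrix.
#' @export
detections_to_mask <- function(dset) {
  if (!inherits(dset, "detection_set"))
    stop("`dset` must be a detection_set", call. = FALSE)
  H <- dset$image_height_px
  W <- dset$image_width_px
  mask <- matrix(FALSE, H, W)
  d <- dset$detections
  for (i in seq_len(nrow(d))) {
    cx <- d$center_x_px[i]; cy <- d$center_y_px[i]; r <- d$radius_px[i]
    rows <- max(1L, floor(cy - r) + 1L):min(H, ceiling(cy + r) + 1L)
    cols <- max(1L, floor(cx - r) + 1L):min(W, ceiling(cx + r) + 1L)
    dy2 <- ((rows - 1L) - cy)^2
    dx2 <- ((cols - 1L) - cx)^2
    mask[rows, cols] <- mask[rows, cols] | (outer(dy2, dx2, `+`) <= r^2)
  }
  mask
}

#' Full detection pipeline: RGB image to counted cells
#'
#' Composition of [enhance_green()], [to_grayscale()], [denoise_median()] and
#' [detect_circles()]. Deterministic for a fixed input and parameters.
#'
#' @param image H x W x 3 RGB array, values 0..255.
#' @param params A [detection_params()] object.
#' @return A `detection_set`; its `count` is the per-image cell count.
#' @export
count_cells <- function(image, params = detection_params()) {
  .assert_rgb(image)
  if (!inherits(params, "detection_params"))
    stop("`params` must come from detection_params()", call. = FALSE)
  img <- enhance_green(image, params$clahe_clip, params$clahe_tiles)
  gray <- to_grayscale(img)
  gray <- denoise_median(gray, params$median_kernel)
  detect_circles(gray, params)
}
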