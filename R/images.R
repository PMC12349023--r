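# Image containers and IO.
#
# Internally an RGB image is a plain H x W x 3 array of 8-bit intensities
# (0..255), rows = image y (top to bottom), columns = image x, channel order
# red-green-blue. A grayscale image is an H x W matrix on the same scale.
# EBImage stores images transposed (x, y[, c]) on [0, 1]; the two helpers
# below convert at the boundary so all arithmetic in this package happens on
# the 8-bit row-major representation.

.assert_rgb <- function(img, arg = "image") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3L] != 3L)
    stop(sprintf("`%s` must be an H x W x 3 RGB array", arg), call. = FALSE)
  if (dim(img)[1L] < 1L || dim(img)[2L] < 1L)
    stop(sprintf("`%s` has a zero dimension", arg), call. = FALSE)
  rng <- range(img)
  if (anyNA(rng) || rng[1L] < 0 || rng[2L] > 255)
    stop(sprintf("`%s` must hold intensities in [0, 255]", arg), call. = FALSE)
  invisible(img)
}

.assert_gray <- function(img, arg = "image") {
  if (!is.matrix(img) || nrow(img) < 1L || ncol(img) < 1L)
    stop(sprintf("`%s` must be a non-empty H x W matrix", arg), call. = FALSE)
  rng <- range(img)
  if (anyNA(rng) || rng[1L] < 0 || rng[2L] > 255)
    stop(sprintf("`%s` must hold intensities in [0, 255]", arg), call. = FALSE)
  invisible(img)
}

.clamp8 <- function(x) pmin(pmax(x, 0), 255)

# H x W [x 3] 8-bit array -> EBImage Image on [0, 1]
.to_eb <- function(arr) {
  if (length(dim(arr)) == 3L)
    EBImage::Image(aperm(arr, c(2L, 1L, 3L)) / 255, colormode = "Color")
  else
    EBImage::Image(t(arr) / 255, colormode = "Grayscale")
}

# EBImage Image -> H x W [x 3] 8-bit array
.from_eb <- function(img) {
  a <- as.array(img)
  a <- if (length(dim(a)) == 3L) aperm(a, c(2L, 1L, 3L)) else t(a)
  .clamp8(round(a * 255))
}

#' Read a microscope image as an 8-bit RGB array
#'
#' Reads PNG/JPEG/TIFF via EBImage. Grayscale images are promoted to RGB by
#' channel replication; an alpha channel, if present, is dropped.
#'
#' @param path Path to an image file.
#' @return An H x W x 3 numeric array with values in 0..255.
#' @export
read_image_rgb <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path, call. = FALSE)
  img <- EBImage::readImage(path)
  a <- as.array(img)
  if (length(dim(a)) == 2L) {
    a <- array(rep(a, 3L), dim = c(dim(a), 3L))
  } else if (dim(a)[3L] > 3L) {
    a <- a[, , 1:3, drop = FALSE]
  } else if (dim(a)[3L] < 3L) {
    a <- array(rep(a[, , 1L], 3L), dim = c(dim(a)[1:2], 3L))
  }
  .clamp8(round(aperm(a, c(2L, 1L, 3L)) * 255))
}

#' Write an 8-bit RGB array to an image file
#'
#' @param img H x W x 3 array, values in 0..255.
#' @param path Output path; format from the extension (png/jpeg/tiff).
#' @return `path`, invisibly.
#' @export
write_image_rgb <- function(img, path) {
  .assert_rgb(img)
  EBImage::writeImage(.to_eb(img), path)
  invisible(path)
}
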