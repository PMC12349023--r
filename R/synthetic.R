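# Synthetic hemocytometer scenes with exact ground truth.
#
# A scene emulates one microscope frame of a counting chamber: a light
# background, the chamber's dark etched grid lines, and green-dominant
# near-circular cells rendered as anti-aliased disks (radii from a truncated
# normal). Optional degradations reproduce the failure modes seen on real
# slides -- clumping, defocus blur, uneven illumination, overexposure,
# salt-and-pepper noise and non-green foreign particles. Ground truth
# (centers, radii, count, mask) is recorded before any degradation, so
# detector behaviour under degradation can be measured against exact truth.

.with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else suppressWarnings(rm(".Random.seed", envir = genv))
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

.rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (n == 0L) return(numeric(0))
  if (sd == 0) return(rep(mean, n))
  out <- numeric(0)
  for (it in 1:100) {
    need <- n - length(out)
    if (need <= 0L) break
    x <- stats::rnorm(need, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  if (length(out) < n)  # pathological mean/sd: fall back to clamping
    out <- c(out, pmin(pmax(stats::rnorm(n - length(out), mean, sd), lo), hi))
  out[seq_len(n)]
}

#' Parameters of a synthetic hemocytometer scene
#'
#' Defaults emulate a high-magnification setup: 4032 x 3024 px frames in
#' which one chamber grid square spans about 1222 px and cell radii fall in
#' 15-100 px. `clump_fraction` assigns that share of cells to touching
#' clusters of `clump_size` (cluster-mate centers about 1.8 radii apart),
#' emulating agglomeration; the remaining degradation fields feed
#' [degrade()] at generation time.
#'
#' @param height_px,width_px Frame size, px.
#' @param background_rgb,grid_rgb,cell_rgb_mean RGB triples, 0..255.
#' @param grid_spacing_px,grid_line_width_px Chamber grid geometry, px.
#' @param n_cells Number of cells to place (>= 0).
#' @param radius_mean_px,radius_std_px,radius_min_px,radius_max_px Truncated
#'   normal radius distribution, px.
#' @param min_separation_px Minimum center distance between non-clumped
#'   cells, px.
#' @param cell_rgb_jitter Half-width of the uniform per-cell colour jitter.
#' @param clump_fraction Share of cells placed in clumps, in `[0, 1]`.
#' @param clump_size Cells per clump (>= 2).
#' @param illumination_gradient_amplitude Multiplicative horizontal ramp
#'   amplitude in `[0, 1)`; 0 disables.
#' @param blur_sigma_px Gaussian defocus blur sigma, px; 0 disables.
#' @param salt_pepper_prob Per-pixel salt-and-pepper probability in `[0, 1)`.
#' @param n_foreign_objects Number of irregular non-green blobs (>= 0).
#' @param seed Integer seed; scenes are bit-reproducible given the seed.
#' @return A `scene_params` object.
#' @export
scene_params <- function(height_px = 3024L, width_px = 4032L,
                         background_rgb = c(210, 210, 205),
                         grid_spacing_px = 1222L, grid_line_width_px = 8L,
                         grid_rgb = c(110, 110, 110),
                         n_cells = 30L,
                         radius_mean_px = 35, radius_std_px = 8,
                         radius_min_px = 15, radius_max_px = 100,
                         min_separation_px = 220,
                         cell_rgb_mean = c(70, 150, 80),
                         cell_rgb_jitter = 15,
                         clump_fraction = 0, clump_size = 3L,
                         illumination_gradient_amplitude = 0,
                         blur_sigma_px = 0, salt_pepper_prob = 0,
                         n_foreign_objects = 0L, seed = 1L) {
  stopifnot(height_px >= 1, width_px >= 1, n_cells >= 0,
            grid_spacing_px > 0, grid_line_width_px >= 1,
            radius_min_px > 0, min_separation_px >= 0,
            clump_size >= 2, n_foreign_objects >= 0)
  if (!(radius_min_px <= radius_mean_px && radius_mean_px <= radius_max_px))
    stop("need radius_min_px <= radius_mean_px <= radius_max_px", call. = FALSE)
  if (radius_std_px < 0) stop("`radius_std_px` must be >= 0", call. = FALSE)
  if (clump_fraction < 0 || clump_fraction > 1)
    stop("`clump_fraction` must be in [0, 1]", call. = FALSE)
  if (illumination_gradient_amplitude < 0 || illumination_gradient_amplitude >= 1)
    stop("`illumination_gradient_amplitude` must be in [0, 1)", call. = FALSE)
  if (salt_pepper_prob < 0 || salt_pepper_prob >= 1)
    stop("`salt_pepper_prob` must be in [0, 1)", call. = FALSE)
  if (blur_sigma_px < 0) stop("`blur_sigma_px` must be >= 0", call. = FALSE)
  for (nm in c("background_rgb", "grid_rgb", "cell_rgb_mean")) {
    v <- get(nm)
    if (length(v) != 3L || any(v < 0) || any(v > 255))
      stop(sprintf("`%s` must be an RGB triple in 0..255", nm), call. = FALSE)
  }
  structure(
    list(height_px = as.integer(height_px), width_px = as.integer(width_px),
         background_rgb = as.numeric(background_rgb),
         grid_spacing_px = as.numeric(grid_spacing_px),
         grid_line_width_px = as.numeric(grid_line_width_px),
         grid_rgb = as.numeric(grid_rgb),
         n_cells = as.integer(n_cells),
         radius_mean_px = radius_mean_px, radius_std_px = radius_std_px,
         radius_min_px = radius_min_px, radius_max_px = radius_max_px,
         min_separation_px = min_separation_px,
         cell_rgb_mean = as.numeric(cell_rgb_mean),
         cell_rgb_jitter = cell_rgb_jitter,
         clump_fraction = clump_fraction, clump_size = as.integer(clump_size),
         illumination_gradient_amplitude = illumination_gradient_amplitude,
         blur_sigma_px = blur_sigma_px, salt_pepper_prob = salt_pepper_prob,
         n_foreign_objects = as.integer(n_foreign_objects),
         seed = as.integer(seed)),
    class = "scene_params")
}

# blend an anti-aliased filled disk into an H x W x 3 image
.draw_disk <- function(img, cx, cy, r, col) {
  H <- dim(img)[1L]; W <- dim(img)[2L]
  rows <- max(1L, floor(cy - r) ):min(H, ceiling(cy + r) + 2L)
  cols <- max(1L, floor(cx - r) ):min(W, ceiling(cx + r) + 2L)
  d <- sqrt(outer(((rows - 1L) - cy)^2, ((cols - 1L) - cx)^2, `+`))
  cov <- pmin(pmax(r + 0.5 - d, 0), 1)
  for (ch in 1:3)
    img[rows, cols, ch] <- img[rows, cols, ch] * (1 - cov) + col[ch] * cov
  img
}

.render_grid <- function(img, p) {
  H <- dim(img)[1L]; W <- dim(img)[2L]
  half <- p$grid_line_width_px / 2
  for (x in seq(p$grid_spacing_px, W - 1, by = p$grid_spacing_px)) {
    cols <- max(1L, round(x - half) + 1L):min(W, round(x + half))
    for (ch in 1:3) img[, cols, ch] <- p$grid_rgb[ch]
  }
  for (y in seq(p$grid_spacing_px, H - 1, by = p$grid_spacing_px)) {
    rows <- max(1L, round(y - half) + 1L):min(H, round(y + half))
    for (ch in 1:3) img[rows, , ch] <- p$grid_rgb[ch]
  }
  img
}

# place n_cells centers: free cells pairwise >= min_separation_px apart,
# clumped cells chained ~1.8 radii from their cluster-mates
.place_cells <- function(p, radii) {
  n <- p$n_cells
  H <- p$height_px; W <- p$width_px
  xs <- numeric(0); ys <- numeric(0)
  cluster_of <- integer(0)  # 0 = free cell
  n_clumped <- round(p$clump_fraction * n)
  n_clusters <- if (n_clumped > 0) ceiling(n_clumped / p$clump_size) else 0L
  # membership plan: first n_clumped cells belong to clusters, rest free
  plan <- c(if (n_clumped > 0) rep(seq_len(n_clusters), each = p$clump_size)[seq_len(n_clumped)],
            rep(0L, n - n_clumped))
  budget <- 400L * max(n, 1L)
  tries <- 0L
  for (i in seq_len(n)) {
    r <- radii[i]
    if (W - 1 - 2 * r < 0 || H - 1 - 2 * r < 0)
      stop("cell radius exceeds frame size; infeasible packing", call. = FALSE)
    cl <- plan[i]
    anchor <- cl > 0L && !(cl %in% cluster_of)
    repeat {
      tries <- tries + 1L
      if (tries > budget)
        stop(sprintf(
          "could not place %d cells at min_separation_px = %g within the frame; infeasible packing",
          n, p$min_separation_px), call. = FALSE)
      if (cl > 0L && !anchor) {
        # chain from a random already-placed cluster-mate
        mates <- which(cluster_of == cl)
        j <- mates[sample.int(length(mates), 1L)]
        ang <- stats::runif(1, 0, 2 * pi)
        gap <- 0.9 * (radii[j] + r)   # ~1.8 radii for equal-sized cells
        x <- xs[j] + gap * cos(ang)
        y <- ys[j] + gap * sin(ang)
        if (x < r || x > W - 1 - r || y < r || y > H - 1 - r) next
        others <- which(cluster_of != cl)
      } else {
        x <- stats::runif(1, r, W - 1 - r)
        y <- stats::runif(1, r, H - 1 - r)
        others <- seq_along(xs)
      }
      if (length(others) > 0) {
        d2 <- (xs[others] - x)^2 + (ys[others] - y)^2
        if (any(d2 < p$min_separation_px^2)) next
      }
      xs <- c(xs, x); ys <- c(ys, y); cluster_of <- c(cluster_of, cl)
      break
    }
  }
  data.frame(x = xs, y = ys, cluster = cluster_of)
}

#' Generate one synthetic hemocytometer scene
#'
#' Deterministic for a fixed seed. Non-clumped cells honour the pairwise
#' minimum separation; clumped cells are placed in touching chains. The
#' truth mask is the rasterized union of the true disks (identical to
#' [detections_to_mask()] applied to the truth), and all ground truth is
#' frozen before the degradations in `params` are applied to the image.
#'
#' @param params A [scene_params()] object.
#' @return A `synthetic_scene`: `image` (H x W x 3, 0..255), `true_centers`
#'   (data frame `x`, `y`, 0-based), `true_radii`, `truth_mask`,
#'   `true_count`, `params`.
#' @export
generate_scene <- function(params = scene_params()) {
  if (!inherits(params, "scene_params"))
    stop("`params` must come from scene_params()", call. = FALSE)
  p <- params
  .with_seed(p$seed, {
    radii <- .rtruncnorm(p$n_cells, p$radius_mean_px, p$radius_std_px,
                         p$radius_min_px, p$radius_max_px)
    pos <- .place_cells(p, radii)
    img <- array(rep(p$background_rgb, each = p$height_px * p$width_px),
                 dim = c(p$height_px, p$width_px, 3L))
    img <- .render_grid(img, p)
    for (i in seq_len(p$n_cells)) {
      col <- .clamp8(p$cell_rgb_mean +
                       stats::runif(3, -p$cell_rgb_jitter, p$cell_rgb_jitter))
      img <- .draw_disk(img, pos$x[i], pos$y[i], radii[i], col)
    }
    truth_set <- detection_set(pos$x, pos$y, radii,
                               image_height_px = p$height_px,
                               image_width_px = p$width_px)
    scene <- structure(
      list(image = .clamp8(round(img)),
           true_centers = pos[, c("x", "y")],
           true_radii = radii,
           truth_mask = detections_to_mask(truth_set),
           true_count = p$n_cells,
           params = p),
      class = "synthetic_scene")
    degrade(scene,
            list(blur_sigma_px = p$blur_sigma_px,
                 illumination_gradient_amplitude = p$illumination_gradient_amplitude,
                 salt_pepper_prob = p$salt_pepper_prob,
                 n_foreign_objects = p$n_foreign_objects))
  })
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %d x %d px, %d cell(s), seed %d\n",
              x$params$width_px, x$params$height_px, x$true_count,
              x$params$seed))
  invisible(x)
}

#' Degrade a scene's image while keeping its ground truth
#'
#' Applies any combination of: Gaussian defocus blur (`blur_sigma_px`), a
#' multiplicative horizontal illumination ramp
#' (`illumination_gradient_amplitude`), overexposure via gain and clipping
#' (`overexposure_gain` > 1), salt-and-pepper noise (`salt_pepper_prob`),
#' and irregular non-green foreign blobs (`n_foreign_objects`). Truth
#' (centers, radii, count, mask) is untouched: degradations affect the image
#' only. Unknown specification names are an error.
#'
#' @param scene A `synthetic_scene`.
#' @param spec Named list of degradation settings; an empty list is the
#'   identity. A `seed` entry controls the stochastic degradations
#'   (default: the scene's seed + 10000).
#' @return The degraded `synthetic_scene`.
#' @export
degrade <- function(scene, spec = list()) {
  if (!inherits(scene, "synthetic_scene"))
    stop("`scene` must be a synthetic_scene", call. = FALSE)
  known <- c("blur_sigma_px", "illumination_gradient_amplitude",
             "overexposure_gain", "salt_pepper_prob", "n_foreign_objects",
             "seed")
  bad <- setdiff(names(spec), known)
  if (length(bad) > 0)
    stop("unknown degradation mode(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  img <- scene$image
  seed <- spec$seed %||% (scene$params$seed + 10000L)
  img <- .with_seed(seed, {
    nf <- spec$n_foreign_objects %||% 0L
    if (nf > 0) {
      H <- dim(img)[1L]; W <- dim(img)[2L]
      base_r <- 0.05 * min(H, W)
      for (k in seq_len(nf)) {
        cx <- stats::runif(1, base_r, W - 1 - base_r)
        cy <- stats::runif(1, base_r, H - 1 - base_r)
        col <- .clamp8(c(125, 100, 70) + stats::runif(3, -20, 20))
        for (b in 1:6) {  # irregular blob: union of offset disks
          ox <- cx + stats::runif(1, -base_r, base_r) * 0.6
          oy <- cy + stats::runif(1, -base_r, base_r) * 0.6
          img <- .draw_disk(img, ox, oy, stats::runif(1, 0.3, 0.7) * base_r, col)
        }
      }
    }
    amp <- spec$illumination_gradient_amplitude %||% 0
    if (amp > 0) {
      W <- dim(img)[2L]
      ramp <- 1 + amp * (2 * (seq_len(W) - 1) / (W - 1) - 1)
      img <- img * rep(ramp, each = dim(img)[1L])
    }
    gain <- spec$overexposure_gain %||% 1
    if (gain != 1) img <- img * gain
    sigma <- spec$blur_sigma_px %||% 0
    if (sigma > 0)
      img <- 255 * aperm(as.array(EBImage::gblur(.to_eb(.clamp8(img)), sigma = sigma)),
                         c(2L, 1L, 3L))
    spp <- spec$salt_pepper_prob %||% 0
    if (spp > 0) {
      H <- dim(img)[1L]; W <- dim(img)[2L]
      npx <- H * W
      hit <- which(stats::runif(npx) < spp)
      val <- ifelse(stats::runif(length(hit)) < 0.5, 0, 255)
      for (ch in 1:3) img[hit + (ch - 1L) * npx] <- val
    }
    img
  })
  scene$image <- .clamp8(round(img))
  scene
}

#' Simulate a sample: several frames at a known true concentration
#'
#' Per-image cell counts are drawn Poisson with mean
#' `expected_count(true_concentration, V_img, dilution)` -- the canonical
#' count model for a well-mixed suspension -- and one scene is generated per
#' image with a seed derived from `base_params$seed` and the image index.
#'
#' @param true_concentration True cells/mL (>= 0).
#' @param n_images Number of frames (>= 1).
#' @param calibration A `calibration` (or image volume in mm^3).
#' @param dilution Dilution factor D (>= 1).
#' @param base_params [scene_params()] template; `n_cells` and `seed` are
#'   overridden per image.
#' @return List of `synthetic_scene` objects.
#' @export
generate_sample <- function(true_concentration, n_images, calibration,
                            dilution = 1, base_params = scene_params()) {
  if (n_images < 1) stop("`n_images` must be >= 1", call. = FALSE)
  lambda <- expected_count(true_concentration, calibration, dilution)
  counts <- .with_seed(base_params$seed, stats::rpois(n_images, lambda))
  lapply(seq_len(n_images), function(i) {
    p <- base_params
    p$n_cells <- counts[i]
    p$seed <- base_params$seed + i
    generate_scene(p)
  })
}
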