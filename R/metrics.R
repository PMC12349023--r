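# Validation metrics for detection, segmentation and concentration estimates.

#' Mean absolute count error
#'
#' `(1/N) * sum(|x_i - y_i|)` over paired per-image true and predicted cell
#' counts.
#'
#' @param true_counts,predicted_counts Equal-length numeric vectors.
#' @return The mean absolute error.
#' @examples
#' count_mae(c(10, 20, 30), c(12, 18, 33))
#' @export
count_mae <- function(true_counts, predicted_counts) {
  if (length(true_counts) == 0L)
    stop("count vectors must be non-empty", call. = FALSE)
  if (length(true_counts) != length(predicted_counts))
    stop("count vectors must have equal length", call. = FALSE)
  mean(abs(true_counts - predicted_counts))
}

#' Intersection over union of two binary masks
#'
#' The Jaccard index `|A intersect B| / |A union B|` of two same-sized
#' logical masks. Two empty masks agree perfectly (1); exactly one empty
#' mask gives 0.
#'
#' @param a,b Logical (or 0/1) matrices of identical dimensions.
#' @return IoU in `[0, 1]`.
#' @export
mask_iou <- function(a, b) {
  if (!all(dim(a) == dim(b)))
    stop("masks must have identical dimensions", call. = FALSE)
  a <- a != 0
  b <- b != 0
  uni <- sum(a | b)
  if (uni == 0L) return(1)
  sum(a & b) / uni
}

#' Relative error of the mean cell area, in percent
#'
#' `|mean predicted area - mean true area| / mean true area * 100`. For
#' circle-parameterized inputs (a `detection_set` or a radius vector) areas
#' are `pi * r^2`; for a mask, connected components are labelled and their
#' pixel counts used. The definition is a reconstruction of the usual
#' "cell area error" column in segmentation benchmarks.
#'
#' @param predicted A `detection_set`, numeric radii, or a logical mask.
#' @param truth Numeric true radii, or a logical truth mask.
#' @return Percent error (>= 0).
#' @export
mean_area_error <- function(predicted, truth) {
  mean_area <- function(x, side) {
    if (inherits(x, "detection_set")) {
      if (x$count == 0L) stop(side, " side is empty", call. = FALSE)
      return(mean(pi * x$detections$radius_px^2))
    }
    if (is.matrix(x)) {
      lab <- EBImage::bwlabel(t(x != 0))
      n <- max(lab)
      if (n == 0L) stop(side, " mask is empty", call. = FALSE)
      return(sum(lab > 0) / n)
    }
    if (length(x) == 0L) stop(side, " side is empty", call. = FALSE)
    mean(pi * as.numeric(x)^2)
  }
  pa <- mean_area(predicted, "predicted")
  ta <- mean_area(truth, "truth")
  abs(pa - ta) / ta * 100
}

#' Percentage difference from an expert reference value
#'
#' `|automatic - expert| / expert * 100`: the absolute error of the
#' automated estimate as a percentage of the expert-derived value.
#'
#' @param expert Expert reference value(s), > 0.
#' @param automatic Automated estimate(s).
#' @return Percent difference(s) (>= 0).
#' @examples
#' percentage_difference(6.97, 5.71)
#' @export
percentage_difference <- function(expert, automatic) {
  if (any(!is.finite(expert)) || any(expert <= 0))
    stop("expert reference values must be positive", call. = FALSE)
  abs(automatic - expert) / expert * 100
}

#' Pearson correlation between paired measurement series
#'
#' Standard product-moment correlation, e.g. between automated and manual
#' concentration series.
#'
#' @param x,y Equal-length numeric vectors (length >= 2, non-zero variance).
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length", call. = FALSE)
  if (length(x) < 2L) stop("need at least two pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("both series need non-zero variance", call. = FALSE)
  stats::cor(x, y)
}

#' Mean, median and population SD of a column of values
#'
#' The aggregation used for per-sample summary columns: arithmetic mean,
#' median, and the population (divide-by-n) standard deviation.
#'
#' @param values Non-empty numeric vector.
#' @return List with `mean`, `median`, `sd_pop`.
#' @export
column_summary <- function(values) {
  if (length(values) == 0L) stop("`values` is empty", call. = FALSE)
  list(mean = mean(values),
       median = stats::median(values),
       sd_pop = sqrt(mean((values - mean(values))^2)))
}

#' Error-vs-agglomeration trend line
#'
#' Ordinary least-squares fit of percentage counting error on the
#' agglomeration (clumping) rate. Counting error grows with clumping for
#' manual and automated counting alike; a positive slope quantifies the
#' trend.
#'
#' @param rates Agglomeration rates (e.g. clump fractions).
#' @param pct_errors Percentage errors at those rates, equal length.
#' @return List with `slope` and `intercept`.
#' @export
agglomeration_trend <- function(rates, pct_errors) {
  if (length(rates) != length(pct_errors))
    stop("`rates` and `pct_errors` must have equal length", call. = FALSE)
  if (length(rates) < 2L) stop("need at least two points", call. = FALSE)
  fit <- stats::lm(pct_errors ~ rates)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]))
}
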