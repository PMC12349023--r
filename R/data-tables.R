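# Bundled reference tables.

#' Published validation tables for the automated counting method
#'
#' Per-sample expert versus automated cell concentrations (10^6 cells/mL)
#' and their percentage differences, as published by the method's authors
#' for two laboratory setups: `"high_magnification"` (21 cultured samples,
#' 60x, expert counting fully visual, both median- and mean-based automated
#' estimates) and `"low_magnification"` (15 controlled-dilution samples,
#' 40x, expert counting software-assisted, mean-based estimates). Useful as
#' reference input for [column_summary()] and [percentage_difference()].
#'
#' @param setup Which setup's table to return.
#' @return A data frame.
#' @examples
#' tab <- validation_table("high_magnification")
#' column_summary(tab$pct_diff_mean)
#' @export
validation_table <- function(setup = c("high_magnification",
                                       "low_magnification")) {
  setup <- match.arg(setup)
  f <- switch(setup,
              high_magnification = "highmag_validation.csv",
              low_magnification = "lowmag_validation.csv")
  utils::read.csv(system.file("extdata", f, package = "algaecount"),
                  check.names = TRUE)
}

#' Catalogue of common hemocytometer geometries
#'
#' Manufacturer characteristics of popular counting chambers, as published:
#' small-square area and chamber depth. Note that published catalogues are
#' not always internally consistent (the Goryaev chamber is variously quoted
#' with 0.02 mm or 0.1 mm working depth); this package therefore always
#' takes the chamber depth as explicit user input.
#'
#' @return A data frame with one row per chamber type.
#' @export
chamber_catalogue <- function() {
  data.frame(
    name = c("Neubauer Improved", "Thoma", "Petroff-Hausser", "Goryaev"),
    grid_size_mm = c(1, 1, 1, 1),
    small_square_area_mm2 = c(0.0625, 0.0625, 0.0625, 0.04),
    depth_mm = c(0.1, 0.1, 0.02, 0.02),
    volume_per_large_square_ml = c(0.1, 0.1, 0.02, 0.02))
}
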