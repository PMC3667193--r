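# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Integer rounding used throughout the 8-bit pipeline: `x + 0.5` floored,
#' so .5 always rounds up. `base::round()` rounds half to even, which would
#' make projections depend on parity of the pixel value.
#' @param x numeric
#' @return numeric of the same shape, integral values
#' @noRd
round_half_up <- function(x) floor(x + 0.5)

#' Clip values into the representable range of a bit depth
#' @noRd
clip_depth <- function(x, bit_depth = 8L) {
  pmin(pmax(x, 0), 2^bit_depth - 1)
}

abort_validation <- function(msg, class = "microcensus_validation_error") {
  stop(errorCondition(msg, class = c(class, "microcensus_error")))
}

abort_io <- function(msg) {
  stop(errorCondition(msg, class = c("microcensus_io_error", "microcensus_error")))
}

is_rgb <- function(img) length(dim(img)) == 3L
n_channels <- function(img) if (is_rgb(img)) dim(img)[3L] else 1L
frame_rows <- function(img) dim(img)[1L]
frame_cols <- function(img) dim(img)[2L]

#' Extract the pixel matrix from a frame, BackgroundModel or ResidualFrame
#' @noRd
as_pixels <- function(x) {
  if (inherits(x, c("background_model", "residual_frame"))) x$image else x
}
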