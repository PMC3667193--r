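#' Regions of interest
#'
#' The census only counts particles inside the arena (the box interior):
#' a rectangle, disk or polygon in 1-based pixel coordinates. Rectangle
#' edges are half-open: `min` edges inclusive, `max` edges exclusive.
#'
#' @param min_row,min_col,max_row,max_col rectangle bounds (half-open).
#' @return An object of class `roi` (subclass per shape).
#' @export
roi_rect <- function(min_row, min_col, max_row, max_col) {
  if (max_row <= min_row || max_col <= min_col)
    abort_validation("rectangle ROI has non-positive extent")
  structure(list(shape = "rectangle", min_row = min_row, min_col = min_col,
                 max_row = max_row, max_col = max_col),
            class = c("roi_rect", "roi"))
}

#' @rdname roi_rect
#' @param center_row,center_col,radius disk centre and radius in pixels.
#' @export
roi_disk <- function(center_row, center_col, radius) {
  if (radius <= 0) abort_validation("disk ROI needs a positive radius")
  structure(list(shape = "disk", center_row = center_row,
                 center_col = center_col, radius = radius),
            class = c("roi_disk", "roi"))
}

#' @rdname roi_rect
#' @param rows,cols polygon vertex coordinates (closed implicitly).
#' @export
roi_polygon <- function(rows, cols) {
  if (length(rows) != length(cols) || length(rows) < 3L)
    abort_validation("polygon ROI needs >= 3 vertices")
  structure(list(shape = "polygon", rows = rows, cols = cols),
            class = c("roi_polygon", "roi"))
}

#' Test whether points fall inside a region of interest
#'
#' @param roi an `roi` object.
#' @param rows,cols point coordinates (vectors of equal length).
#' @return logical vector.
#' @export
roi_contains <- function(roi, rows, cols) {
  UseMethod("roi_contains")
}

#' @export
roi_contains.roi_rect <- function(roi, rows, cols) {
  rows >= roi$min_row & rows < roi$max_row &
    cols >= roi$min_col & cols < roi$max_col
}

#' @export
roi_contains.roi_disk <- function(roi, rows, cols) {
  (rows - roi$center_row)^2 + (cols - roi$center_col)^2 <= roi$radius^2
}

#' @export
roi_contains.roi_polygon <- function(roi, rows, cols) {
  bnd <- cbind(roi$rows, roi$cols)
  mgcv::in.out(bnd, cbind(rows, cols))
}

#' Detect the arena (box border) automatically
#'
#' The rearing-box interior contrasts with the surround (darkened plaster
#' in a pale frame, by default darker). The background image is
#' Otsu-thresholded on that side, the largest connected component is
#' taken as the arena, and its bounding rectangle is shrunk inward by a
#' margin (default 2% of its width) to keep the wall itself out of the
#' census.
#'
#' @param background a `background_model` or grayscale matrix.
#' @param polarity `"dark"` (interior darker than surround) or
#'   `"bright"`.
#' @param margin_frac fraction of the detected width to trim from each
#'   side (default 0.02).
#' @return An [roi_rect()].
#' @export
detect_roi <- function(background, polarity = c("dark", "bright"),
                       margin_frac = 0.02) {
  polarity <- match.arg(polarity)
  g <- to_grayscale(as_pixels(background))
  mask <- tryCatch(
    threshold_residual(g, method = "otsu", polarity = polarity),
    microcensus_degenerate_error = function(e) abort_validation(
      "ROI detection failed on a uniform background; supply a manual ROI",
      class = "microcensus_roi_error"))
  lab <- label_particles(mask, connectivity = 8L)
  if (lab$n == 0L)
    abort_validation("ROI detection found no arena; supply a manual ROI",
                     class = "microcensus_roi_error")
  areas <- tabulate(lab$labels[lab$labels > 0L], nbins = lab$n)
  best <- which.max(areas)
  if (areas[best] < 0.1 * length(g))
    abort_validation(paste(
      "ROI detection failed: largest candidate covers < 10% of the frame;",
      "supply a manual ROI"), class = "microcensus_roi_error")
  idx <- which(lab$labels == best)
  r <- ((idx - 1L) %% nrow(g)) + 1L
  cl <- ((idx - 1L) %/% nrow(g)) + 1L
  width <- diff(range(cl)) + 1L
  m <- round(margin_frac * width)
  roi_rect(min(r) + m, min(cl) + m, max(r) + 1L - m, max(cl) + 1L - m)
}
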