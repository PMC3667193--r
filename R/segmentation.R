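#' Physical scale calibration
#'
#' Converts pixel measurements to millimetres. Either set the factor
#' manually or derive it from a known-size reference square with
#' [calibrate_scale()].
#'
#' @param pixels_per_mm positive number of pixels per millimetre.
#' @param source `"manual"` or `"reference_square"`.
#' @return An object of class `scale_calibration`.
#' @export
scale_calibration <- function(pixels_per_mm,
                              source = c("manual", "reference_square")) {
  source <- match.arg(source)
  if (!is.numeric(pixels_per_mm) || length(pixels_per_mm) != 1L ||
      !is.finite(pixels_per_mm) || pixels_per_mm <= 0)
    abort_validation("pixels_per_mm must be a single positive number")
  structure(list(pixels_per_mm = pixels_per_mm, source = source),
            class = "scale_calibration")
}

#' Otsu's threshold of an 8-bit image
#'
#' Chooses the grey level maximising the between-class variance of the
#' histogram split into {<= t} and {> t}. Implemented on cumulative
#' histogram sums. A two-level image makes every split between the two
#' levels equally optimal; ties are resolved to the midpoint of the
#' maximising plateau (rounded half up), placing the cut centrally
#' between the classes.
#'
#' @param x matrix of integral grey values.
#' @param levels number of grey levels (default 256).
#' @return the threshold t (integer grey level).
#' @export
otsu_threshold <- function(x, levels = 256L) {
  v <- as.vector(x)
  h <- tabulate(v + 1L, nbins = levels)
  if (sum(h > 0L) < 2L)
    abort_validation(
      "image is constant: no two intensity classes to separate",
      class = "microcensus_degenerate_error")
  g <- seq_len(levels) - 1
  w0 <- cumsum(h)
  m0 <- cumsum(h * g)
  n <- w0[levels]
  mT <- m0[levels]
  # between-class variance for split after level t (t = 0 .. levels-2)
  num <- (mT * w0 - n * m0)^2
  den <- w0 * (n - w0)
  sigma <- ifelse(den > 0, num / den, -Inf)
  sigma <- sigma[-levels]
  cand <- which(sigma == max(sigma))
  round_half_up(mean(g[cand]))
}

#' Threshold a residual frame into a binary mask
#'
#' Converts the grayscale residual to foreground/background. With bright
#' polarity (organisms lighter than the substrate, the default system)
#' the foreground is `pixels > t`; with dark polarity `pixels < t`. The
#' threshold is either fixed or chosen automatically by Otsu's method —
#' the background removal is what makes the automatic choice safe, since
#' a wide range of thresholds then gives the same particles.
#'
#' @param residual a `residual_frame` or grayscale matrix.
#' @param method `"otsu"` or `"fixed"`.
#' @param value threshold grey level, required for `method = "fixed"`.
#' @param polarity `"bright"` or `"dark"`.
#' @return An object of class `binary_mask`: list with logical `pixels`,
#'   `threshold_used`, `polarity`.
#' @export
threshold_residual <- function(residual, method = c("otsu", "fixed"),
                               value = NULL,
                               polarity = c("bright", "dark")) {
  method <- match.arg(method)
  polarity <- match.arg(polarity)
  img <- as_pixels(residual)
  if (is_rgb(img))
    abort_validation("thresholding operates on grayscale residuals; convert first")
  t <- if (method == "fixed") {
    if (is.null(value)) abort_validation("method = 'fixed' requires a threshold value")
    value
  } else {
    otsu_threshold(img)
  }
  px <- if (polarity == "bright") img > t else img < t
  structure(list(pixels = px, threshold_used = t, polarity = polarity),
            class = "binary_mask")
}

#' Label connected particles in a binary mask
#'
#' Each maximal connected set of foreground pixels becomes one particle,
#' the unit the census counts and measures. Connectivity 8 (diagonal
#' contact joins, the particle-analysis default) or 4.
#'
#' @param mask a `binary_mask` or logical matrix.
#' @param connectivity 4 or 8.
#' @return list with `labels` (integer matrix, background 0, particles
#'   numbered from 1 in raster order) and `n` (particle count).
#' @export
label_particles <- function(mask, connectivity = 8L) {
  px <- if (inherits(mask, "binary_mask")) mask$pixels else mask
  if (!is.logical(px)) storage.mode(px) <- "logical"
  if (!connectivity %in% c(4L, 8L))
    abort_validation("connectivity must be 4 or 8")
  lab <- .label_cc(px, as.integer(connectivity))
  list(labels = lab, n = attr(lab, "n"))
}

#' Measure labelled particles in physical units
#'
#' For each particle: area (pixel count / pixels_per_mm^2), length (major
#' axis of the ellipse sharing the component's second moments, with the
#' 1/12 pixel-extent correction, so a rendered ellipse of semi-axes a, b
#' measures ~2a), centroid, bounding box (half-open, 1-based), mean
#' intensity and — if `source_frame` is RGB — mean colour.
#'
#' @param labels labelled integer matrix, or the list from
#'   [label_particles()].
#' @param source_frame frame supplying intensities/colour (typically the
#'   original frame or the residual).
#' @param scale a [scale_calibration].
#' @param frame_index integer recorded in each row.
#' @return A data.frame with one row per particle: `label`,
#'   `frame_index`, `area_px`, `area_mm2`, `length_px`, `length_mm`,
#'   `centroid_row`, `centroid_col`, `bbox_min_row`, `bbox_min_col`,
#'   `bbox_max_row`, `bbox_max_col` (max edges exclusive),
#'   `mean_intensity`, `mean_r`, `mean_g`, `mean_b`, `touches_edge`.
#' @export
measure_particles <- function(labels, source_frame, scale,
                              frame_index = NA_integer_) {
  if (is.list(labels) && !is.null(labels$labels)) labels <- labels$labels
  if (missing(scale) || !inherits(scale, "scale_calibration"))
    abort_validation(paste(
      "a scale_calibration is required to report physical units;",
      "set pixels_per_mm manually or run calibrate_scale() on a",
      "reference square"))
  ppm <- scale$pixels_per_mm
  idx <- which(labels > 0L)
  empty <- data.frame(
    label = integer(), frame_index = integer(), area_px = numeric(),
    area_mm2 = numeric(), length_px = numeric(), length_mm = numeric(),
    centroid_row = numeric(), centroid_col = numeric(),
    bbox_min_row = integer(), bbox_min_col = integer(),
    bbox_max_row = integer(), bbox_max_col = integer(),
    mean_intensity = numeric(), mean_r = numeric(), mean_g = numeric(),
    mean_b = numeric(), touches_edge = logical())
  if (length(idx) == 0L) return(empty)
  lab <- labels[idx]
  rr <- ((idx - 1L) %% nrow(labels)) + 1L
  cc <- ((idx - 1L) %/% nrow(labels)) + 1L
  gray <- to_grayscale(source_frame)
  rgb <- is_rgb(source_frame)
  nr <- nrow(labels); ncl <- ncol(labels)
  groups <- split(seq_along(lab), lab)
  rows <- lapply(groups, function(g) {
    r <- rr[g]; cl <- cc[g]
    a <- length(g)
    cr <- mean(r); ccm <- mean(cl)
    # second central moments with the 1/12 per-pixel extent term
    mrr <- sum((r - cr)^2) / a + 1 / 12
    mcc <- sum((cl - ccm)^2) / a + 1 / 12
    mrc <- sum((r - cr) * (cl - ccm)) / a
    lam <- (mrr + mcc + sqrt((mrr - mcc)^2 + 4 * mrc^2)) / 2
    len <- 4 * sqrt(lam)
    pix <- idx[g]
    data.frame(
      label = lab[g[1L]], frame_index = frame_index,
      area_px = a, area_mm2 = a / ppm^2,
      length_px = len, length_mm = len / ppm,
      centroid_row = cr, centroid_col = ccm,
      bbox_min_row = min(r), bbox_min_col = min(cl),
      bbox_max_row = max(r) + 1L, bbox_max_col = max(cl) + 1L,
      mean_intensity = mean(gray[pix]),
      mean_r = if (rgb) mean(source_frame[pix]) else NA_real_,
      mean_g = if (rgb) mean(source_frame[pix + nr * ncl]) else NA_real_,
      mean_b = if (rgb) mean(source_frame[pix + 2L * nr * ncl]) else NA_real_,
      touches_edge = min(r) == 1L || min(cl) == 1L ||
        max(r) == nr || max(cl) == ncl)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Filter particle records by size, region and edge contact
#'
#' @param records data.frame from [measure_particles()].
#' @param min_area_mm2,max_area_mm2 inclusive area bounds.
#' @param roi optional region of interest ([roi_rect()] and friends);
#'   particles are kept when their centroid lies inside.
#' @param exclude_edge drop particles touching the frame edge
#'   (default `FALSE`: edge particles are kept).
#' @return the filtered data.frame, order preserved.
#' @export
filter_particles <- function(records, min_area_mm2 = 0,
                             max_area_mm2 = Inf, roi = NULL,
                             exclude_edge = FALSE) {
  if (min_area_mm2 > max_area_mm2)
    abort_validation("min_area_mm2 exceeds max_area_mm2")
  if (nrow(records) == 0L) return(records)
  keep <- records$area_mm2 >= min_area_mm2 & records$area_mm2 <= max_area_mm2
  if (!is.null(roi))
    keep <- keep & roi_contains(roi, records$centroid_row, records$centroid_col)
  if (exclude_edge) keep <- keep & !records$touches_edge
  records[keep, , drop = FALSE]
}

#' Derive the physical scale from a dark reference square
#'
#' A contrasted black square of known side placed in the scene gives the
#' pixel size: the background image is Otsu-thresholded on the dark side,
#' the largest dark component is taken as the square, and
#' `pixels_per_mm = sqrt(area_px) / reference_side_mm`. Fails when no
#' dark component exists or the component is far from square (bounding
#' box aspect ratio outside `[0.8, 1.25]`).
#'
#' @param background a `background_model` (or grayscale matrix).
#' @param reference_side_mm physical side length of the square, mm.
#' @return A [scale_calibration] with `source = "reference_square"`.
#' @export
calibrate_scale <- function(background, reference_side_mm) {
  if (!is.numeric(reference_side_mm) || reference_side_mm <= 0)
    abort_validation("reference_side_mm must be positive")
  g <- to_grayscale(as_pixels(background))
  mask <- tryCatch(
    threshold_residual(g, method = "otsu", polarity = "dark"),
    microcensus_degenerate_error = function(e) abort_validation(
      "calibration failed: image is uniform, no dark reference found",
      class = "microcensus_calibration_error"))
  lab <- label_particles(mask, connectivity = 8L)
  if (lab$n == 0L)
    abort_validation("calibration failed: no dark component found",
                     class = "microcensus_calibration_error")
  areas <- tabulate(lab$labels[lab$labels > 0L], nbins = lab$n)
  best <- which.max(areas)
  idx <- which(lab$labels == best)
  r <- ((idx - 1L) %% nrow(g)) + 1L
  cl <- ((idx - 1L) %/% nrow(g)) + 1L
  h <- diff(range(r)) + 1L
  w <- diff(range(cl)) + 1L
  aspect <- h / w
  if (aspect < 0.8 || aspect > 1.25)
    abort_validation(sprintf(
      "calibration failed: largest dark component is not square (aspect %.2f)",
      aspect), class = "microcensus_calibration_error")
  scale_calibration(sqrt(areas[best]) / reference_side_mm,
                    source = "reference_square")
}
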