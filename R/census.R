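#' Census configuration
#'
#' Bundles every knob of the per-box pipeline. Two arguments are
#' deliberately required: `removal_mode` (plain subtraction reveals only
#' organisms on the bright side of the substrate; the absolute difference
#' catches both sides — each dataset must state which it needs) and
#' `scale` (measurements are reported in millimetres, so the pixel size
#' must come from somewhere: a manual [scale_calibration()] or
#' `"reference_square"` together with `reference_side_mm` to calibrate
#' from a dark square in the scene).
#'
#' @param removal_mode `"subtract"` or `"difference"`.
#' @param scale a [scale_calibration()], or `"reference_square"`.
#' @param projection background projection method: `"min"` (organisms
#'   lighter than substrate — the default system), `"max"`, `"median"`,
#'   `"mean"`.
#' @param threshold_method `"otsu"` (automatic) or `"fixed"`.
#' @param threshold_value grey level for `threshold_method = "fixed"`.
#' @param polarity `"bright"` or `"dark"`: side of the threshold treated
#'   as organism.
#' @param connectivity 4 or 8 (default 8, diagonal contact joins).
#' @param min_area_mm2,max_area_mm2 particle size gate (defaults 0, Inf:
#'   no gate).
#' @param roi `"full"` (whole frame), `"auto"` ([detect_roi()] on the
#'   background), or an `roi` object.
#' @param roi_polarity passed to [detect_roi()] when `roi = "auto"`.
#' @param reference_side_mm side of the reference square, mm (required
#'   when `scale = "reference_square"`).
#' @param register re-align frames with [register_stack()] first.
#' @param aggregate `"mean"` (default) or `"median"` over per-frame
#'   counts.
#' @param exclude_edge drop particles touching the frame edge.
#' @param size_min_mm,size_max_mm,size_bin_mm size-distribution binning
#'   (defaults 0.1–3 mm in 0.02 mm classes).
#' @return An object of class `census_config`.
#' @export
census_config <- function(removal_mode, scale,
                          projection = c("min", "max", "median", "mean"),
                          threshold_method = c("otsu", "fixed"),
                          threshold_value = NULL,
                          polarity = c("bright", "dark"),
                          connectivity = 8L,
                          min_area_mm2 = 0, max_area_mm2 = Inf,
                          roi = "full", roi_polarity = "dark",
                          reference_side_mm = NULL,
                          register = FALSE,
                          aggregate = c("mean", "median"),
                          exclude_edge = FALSE,
                          size_min_mm = 0.1, size_max_mm = 3.0,
                          size_bin_mm = 0.02) {
  removal_mode <- match.arg(removal_mode, c("subtract", "difference"))
  projection <- match.arg(projection)
  threshold_method <- match.arg(threshold_method)
  polarity <- match.arg(polarity)
  aggregate <- match.arg(aggregate)
  if (threshold_method == "fixed" && is.null(threshold_value))
    abort_validation("threshold_method = 'fixed' requires threshold_value")
  if (identical(scale, "reference_square")) {
    if (is.null(reference_side_mm))
      abort_validation("scale = 'reference_square' requires reference_side_mm")
  } else if (!inherits(scale, "scale_calibration")) {
    abort_validation(
      "scale must be a scale_calibration or \"reference_square\"")
  }
  if (!identical(roi, "full") && !identical(roi, "auto") &&
      !inherits(roi, "roi"))
    abort_validation("roi must be \"full\", \"auto\" or an roi object")
  structure(
    list(removal_mode = removal_mode, scale = scale,
         projection = projection, threshold_method = threshold_method,
         threshold_value = threshold_value, polarity = polarity,
         connectivity = as.integer(connectivity),
         min_area_mm2 = min_area_mm2, max_area_mm2 = max_area_mm2,
         roi = roi, roi_polarity = roi_polarity,
         reference_side_mm = reference_side_mm, register = register,
         aggregate = aggregate, exclude_edge = exclude_edge,
         size_min_mm = size_min_mm, size_max_mm = size_max_mm,
         size_bin_mm = size_bin_mm),
    class = "census_config")
}

# threshold that degrades to an empty mask on a constant residual
# (an organism-free residual is all zeros; that is a zero count, not an error)
threshold_or_empty <- function(residual, config) {
  tryCatch(
    threshold_residual(residual, method = config$threshold_method,
                       value = config$threshold_value,
                       polarity = config$polarity),
    microcensus_degenerate_error = function(e) {
      structure(list(pixels = array(FALSE, dim(as_pixels(residual))),
                     threshold_used = NA_integer_,
                     polarity = config$polarity),
                class = "binary_mask")
    })
}

# shared single-frame detection step: residual -> mask -> labels -> records
detect_frame <- function(gray_frame, original_frame, background, config,
                         scale, frame_index) {
  res <- remove_background(gray_frame, background, config$removal_mode,
                           source_frame_index = frame_index)
  mask <- threshold_or_empty(res, config)
  lab <- label_particles(mask, config$connectivity)
  rec <- measure_particles(lab, original_frame, scale,
                           frame_index = frame_index)
  roi <- if (inherits(config$roi, "roi")) config$roi else NULL
  filter_particles(rec, config$min_area_mm2, config$max_area_mm2,
                   roi = roi, exclude_edge = config$exclude_edge)
}

# resolve "auto"/"reference_square" settings against a concrete background
resolve_config <- function(config, background) {
  if (identical(config$scale, "reference_square"))
    config$scale <- calibrate_scale(background, config$reference_side_mm)
  if (identical(config$roi, "auto"))
    config$roi <- detect_roi(background, polarity = config$roi_polarity)
  config
}

#' Census of one microcosm box
#'
#' The full pipeline on one stack: (optional) re-alignment, grayscale
#' conversion, background projection, per-frame background removal,
#' thresholding, particle labeling, measurement and filtering, then
#' aggregation into per-frame counts, the mean count, the biosurface
#' (mean over frames of the summed particle areas, mm^2 — a proxy for
#' population biomass) and the size distribution of all retained
#' particles. Deterministic given the stack and configuration.
#'
#' @param stack an [image_stack] (at least 2 frames for a motion signal;
#'   a single frame is processed with a warning).
#' @param config a [census_config()].
#' @return An object of class `census_result`: list with
#'   `per_frame_counts`, `mean_count`, `biosurface_mm2`,
#'   `size_histogram`, `corrected_count` (NA until [correct_density()]),
#'   `n_frames_used`, `particles` (pooled data.frame), `background`,
#'   `roi`, `scale`, `config`.
#' @export
census_box <- function(stack, config) {
  if (!inherits(stack, "image_stack"))
    abort_validation("census_box() expects an image_stack")
  if (!inherits(config, "census_config"))
    abort_validation("census_box() expects a census_config")
  if (n_frames(stack) < 2L)
    warning("census on a single frame: no motion signal, background equals the frame")
  if (config$register && n_frames(stack) >= 2L)
    stack <- register_stack(stack)$stack
  gray <- lapply(stack$frames, to_grayscale, bit_depth = stack$bit_depth)
  gstack <- image_stack(gray, frame_index = stack$frame_index,
                        timestamp_seconds = stack$timestamp_seconds,
                        bit_depth = stack$bit_depth)
  bg <- project(gstack, config$projection)
  config <- resolve_config(config, bg)
  per_frame <- lapply(seq_len(n_frames(stack)), function(i) {
    detect_frame(gray[[i]], stack$frames[[i]], bg, config,
                 config$scale, stack$frame_index[i])
  })
  counts <- vapply(per_frame, nrow, integer(1L))
  bio <- vapply(per_frame, function(p) sum(p$area_mm2), numeric(1L))
  particles <- do.call(rbind, per_frame)
  hist <- size_distribution(particles, min_mm = config$size_min_mm,
                            max_mm = config$size_max_mm,
                            bin_width_mm = config$size_bin_mm)
  structure(
    list(per_frame_counts = counts,
         mean_count = if (config$aggregate == "median")
           stats::median(counts) else mean(counts),
         biosurface_mm2 = mean(bio),
         size_histogram = hist,
         corrected_count = NA_real_,
         n_frames_used = n_frames(stack),
         particles = particles,
         background = bg, roi = config$roi, scale = config$scale,
         config = config),
    class = "census_result")
}

#' @export
print.census_result <- function(x, ...) {
  cat(sprintf(
    "<census_result> %d frame(s); mean count %.2f; biosurface %.3f mm^2%s\n",
    x$n_frames_used, x$mean_count, x$biosurface_mm2,
    if (is.na(x$corrected_count)) ""
    else sprintf("; corrected count %.1f", x$corrected_count)))
  invisible(x)
}

#' Size distribution over fixed classes
#'
#' Bins particle lengths into fixed-width classes — the defaults divide
#' 0.1 to 3 mm into 145 classes of 0.02 mm, the standard binning for
#' collembolan population structure. Bins are left-closed
#' (`[edge, edge + width)`), the last bin also includes the upper limit;
#' particles outside `[min_mm, max_mm]` are tallied in `underflow` /
#' `overflow` attributes, not in the bins.
#'
#' @param records data.frame with a `length_mm` column (or a numeric
#'   vector of lengths).
#' @param min_mm,max_mm range covered by the bins.
#' @param bin_width_mm class width; must divide `max_mm - min_mm`.
#' @return A data.frame of class `size_histogram` with columns
#'   `bin_left_mm`, `bin_right_mm`, `count`, plus attributes `underflow`
#'   and `overflow`.
#' @examples
#' h <- size_distribution(c(0.11, 0.47))
#' nrow(h)  # 145 classes
#' @export
size_distribution <- function(records, min_mm = 0.1, max_mm = 3.0,
                              bin_width_mm = 0.02) {
  if (bin_width_mm <= 0) abort_validation("bin width must be positive")
  if (max_mm <= min_mm) abort_validation("max_mm must exceed min_mm")
  nb <- (max_mm - min_mm) / bin_width_mm
  if (abs(nb - round(nb)) > 1e-9)
    abort_validation("bin width must divide the size range")
  nb <- as.integer(round(nb))
  x <- if (is.data.frame(records)) records$length_mm else records
  x <- x[!is.na(x)]
  under <- sum(x < min_mm)
  over <- sum(x > max_mm)
  inb <- x[x >= min_mm & x <= max_mm]
  # epsilon absorbs float error at the left edges; top edge closes the last bin
  bin <- pmin(floor((inb - min_mm) / bin_width_mm + 1e-9), nb - 1L) + 1L
  counts <- tabulate(bin, nbins = nb)
  edges <- min_mm + bin_width_mm * (seq_len(nb) - 1L)
  structure(
    data.frame(bin_left_mm = edges, bin_right_mm = edges + bin_width_mm,
               count = counts),
    underflow = under, overflow = over,
    class = c("size_histogram", "data.frame"))
}

#' Fit the biosurface-to-count density calibration
#'
#' At high density organisms adjoin, merge into single particles and the
#' raw count under-estimates the true density; the total biosurface does
#' not saturate that way. A linear regression of manually verified
#' counts on biosurface, fitted at low densities where the raw count is
#' trustworthy, converts biosurface into a de-biased density estimate.
#'
#' @param pairs data.frame (or 2-column matrix) with columns
#'   `biosurface_mm2` and `manual_count`.
#' @return An object of class `density_calibration`: list with `slope`,
#'   `intercept`, `fitted_on`.
#' @examples
#' fit_density_calibration(data.frame(biosurface_mm2 = c(1, 2),
#'                                    manual_count = c(12, 18)))
#' @export
fit_density_calibration <- function(pairs) {
  pairs <- as.data.frame(pairs)
  if (ncol(pairs) < 2L) abort_validation("pairs needs two columns")
  if (!all(c("biosurface_mm2", "manual_count") %in% names(pairs)))
    names(pairs)[1:2] <- c("biosurface_mm2", "manual_count")
  if (nrow(pairs) < 2L)
    abort_validation("at least 2 (biosurface, count) pairs are required")
  if (length(unique(pairs$biosurface_mm2)) < 2L)
    abort_validation("biosurfaces are identical: regression is degenerate")
  fit <- stats::lm(manual_count ~ biosurface_mm2, data = pairs)
  co <- stats::coef(fit)
  structure(list(slope = unname(co[2L]), intercept = unname(co[1L]),
                 fitted_on = pairs),
            class = "density_calibration")
}

#' Correct a census count via the density calibration
#'
#' Projects the box's biosurface onto the fitted regression:
#' `corrected = slope * biosurface + intercept`, floored at 0. The raw
#' counts are always retained alongside — the correction assumes
#' similar-sized, non-overlapping individuals and is a judgement call at
#' high density, never an automatic replacement.
#'
#' @param result a `census_result`.
#' @param calib a `density_calibration`.
#' @return the `census_result` with `corrected_count` filled in.
#' @export
correct_density <- function(result, calib) {
  if (!inherits(calib, "density_calibration"))
    abort_validation("correct_density() expects a density_calibration")
  result$corrected_count <-
    max(calib$slope * result$biosurface_mm2 + calib$intercept, 0)
  result
}

#' Biosurface as a function of stack size
#'
#' How many pictures are enough? The background is only exact where
#' every pixel is organism-free in at least one frame, so the measured
#' biosurface rises with the number of frames and plateaus once coverage
#' is complete — quickly at low density, later at high density. This
#' reruns the full census on growing prefixes of the stack (background
#' rebuilt from the same subset each time).
#'
#' @param stack an [image_stack].
#' @param config a [census_config()].
#' @param n_values stack sizes to evaluate (each <= `n_frames(stack)`).
#' @return data.frame with columns `n`, `biosurface_mm2`, `mean_count`.
#' @export
reliability_curve <- function(stack, config, n_values) {
  if (any(n_values > n_frames(stack)))
    abort_validation("n_values exceed the stack size")
  if (any(n_values < 2L))
    warning("n < 2 gives no motion signal; biosurface will be 0 or spurious")
  rows <- lapply(n_values, function(n) {
    res <- suppressWarnings(census_box(stack[seq_len(n)], config))
    data.frame(n = n, biosurface_mm2 = res$biosurface_mm2,
               mean_count = res$mean_count)
  })
  do.call(rbind, rows)
}

#' Write census outputs as CSV
#'
#' @param result a `census_result`.
#' @param particles_csv,histogram_csv output paths (either may be NULL).
#' @return invisibly, the paths written.
#' @export
write_census_csv <- function(result, particles_csv = NULL,
                             histogram_csv = NULL) {
  if (!is.null(particles_csv))
    utils::write.csv(result$particles, particles_csv, row.names = FALSE)
  if (!is.null(histogram_csv))
    utils::write.csv(
      result$size_histogram[, c("bin_left_mm", "count")],
      histogram_csv, row.names = FALSE)
  invisible(c(particles_csv, histogram_csv))
}
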