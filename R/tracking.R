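#' Sliding-window backgrounds for long time-lapses
#'
#' Over hours the scene is no longer still — lighting drifts, substrate
#' dries — and one global background blurs. Rebuilding the background on
#' a window of frames around each frame keeps it current. The window is
#' centred on the frame and kept at its full size near the stack ends by
#' shifting inward; `mode = "trailing"` uses only frames up to the
#' current one (online use).
#'
#' @param stack an [image_stack].
#' @param window number of frames per background (>= 2, <= stack size).
#' @param method projection method: `"min"`, `"median"` or `"mean"`.
#' @param mode `"centred"` (default) or `"trailing"`.
#' @return list of `background_model`, one per frame.
#' @export
sliding_background <- function(stack, window,
                               method = c("min", "median", "mean"),
                               mode = c("centred", "trailing")) {
  method <- match.arg(method)
  mode <- match.arg(mode)
  n <- n_frames(stack)
  if (window < 2L) abort_validation("window must be >= 2")
  if (window > n)
    abort_validation(sprintf("window %d exceeds stack size %d", window, n))
  half_lo <- (window - 1L) %/% 2L
  lapply(seq_len(n), function(i) {
    if (mode == "trailing") {
      hi <- i
      lo <- max(1L, i - window + 1L)
    } else {
      lo <- max(1L, i - half_lo)
      hi <- lo + window - 1L
      if (hi > n) { hi <- n; lo <- hi - window + 1L }
    }
    project(stack[lo:hi], method)
  })
}

# resolve a per-frame list of backgrounds: global projection or sliding
frame_backgrounds <- function(gstack, config, window = NULL,
                              window_method = "median",
                              window_mode = "centred") {
  if (is.null(window)) {
    bg <- project(gstack, config$projection)
    rep(list(bg), n_frames(gstack))
  } else {
    sliding_background(gstack, window, method = window_method,
                       mode = window_mode)
  }
}

#' Track a single organism through a stack
#'
#' One animal in the arena: per frame, the background-removed residual
#' is thresholded and the largest retained particle's centroid is taken
#' as the position. Frames with no particle (animal motionless against
#' the sliding background, or hidden) become gaps — reported, never
#' interpolated.
#'
#' @param stack an [image_stack].
#' @param config a [census_config()].
#' @param window optional sliding-background window (frames); `NULL`
#'   uses one global background.
#' @param window_method,window_mode passed to [sliding_background()].
#' @return An object of class `trajectory`: list with `points`
#'   (data.frame `frame_index`, `t_seconds`, `row`, `col`, `row_mm`,
#'   `col_mm`, `area_mm2`) and `gaps` (integer frame indices with no
#'   detection).
#' @export
track_single <- function(stack, config, window = NULL,
                         window_method = "median",
                         window_mode = "centred") {
  gray <- lapply(stack$frames, to_grayscale, bit_depth = stack$bit_depth)
  gstack <- image_stack(gray, frame_index = stack$frame_index,
                        timestamp_seconds = stack$timestamp_seconds,
                        bit_depth = stack$bit_depth)
  bgs <- frame_backgrounds(gstack, config, window, window_method, window_mode)
  config <- resolve_config(config, bgs[[1L]])
  ppm <- config$scale$pixels_per_mm
  ts <- stack$timestamp_seconds %||% stack$frame_index
  pts <- list()
  gaps <- integer()
  for (i in seq_len(n_frames(stack))) {
    rec <- detect_frame(gray[[i]], stack$frames[[i]], bgs[[i]], config,
                        config$scale, stack$frame_index[i])
    if (nrow(rec) == 0L) {
      gaps <- c(gaps, stack$frame_index[i])
    } else {
      best <- rec[which.max(rec$area_px), ]
      pts[[length(pts) + 1L]] <- data.frame(
        frame_index = stack$frame_index[i], t_seconds = ts[i],
        row = best$centroid_row, col = best$centroid_col,
        row_mm = best$centroid_row / ppm, col_mm = best$centroid_col / ppm,
        area_mm2 = best$area_mm2)
    }
  }
  points <- if (length(pts)) do.call(rbind, pts) else
    data.frame(frame_index = integer(), t_seconds = numeric(),
               row = numeric(), col = numeric(), row_mm = numeric(),
               col_mm = numeric(), area_mm2 = numeric())
  structure(list(points = points, gaps = gaps), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d point(s), %d gap frame(s)\n",
              nrow(x$points), length(x$gaps)))
  invisible(x)
}

#' Activity time series within a region
#'
#' Counts, per frame, the filtered particles whose centroid falls inside
#' the region of interest — e.g. ants active around a nest entrance over
#' many hours. Uses a global or sliding background.
#'
#' @param stack an [image_stack] (timestamps used when present, frame
#'   indices otherwise).
#' @param roi an `roi` object.
#' @param config a [census_config()].
#' @inheritParams track_single
#' @return An object of class `activity_series`: data.frame with columns
#'   `t_seconds` and `count`, attribute `window_size` (0 for a global
#'   background).
#' @export
activity_series <- function(stack, roi, config, window = NULL,
                            window_method = "median",
                            window_mode = "centred") {
  if (!inherits(roi, "roi")) abort_validation("activity_series() needs an roi")
  config$roi <- roi
  gray <- lapply(stack$frames, to_grayscale, bit_depth = stack$bit_depth)
  gstack <- image_stack(gray, frame_index = stack$frame_index,
                        timestamp_seconds = stack$timestamp_seconds,
                        bit_depth = stack$bit_depth)
  bgs <- frame_backgrounds(gstack, config, window, window_method, window_mode)
  config <- resolve_config(config, bgs[[1L]])
  ts <- stack$timestamp_seconds %||% stack$frame_index
  counts <- vapply(seq_len(n_frames(stack)), function(i) {
    nrow(detect_frame(gray[[i]], stack$frames[[i]], bgs[[i]], config,
                      config$scale, stack$frame_index[i]))
  }, integer(1L))
  structure(data.frame(t_seconds = ts, count = counts),
            window_size = if (is.null(window)) 0L else as.integer(window),
            class = c("activity_series", "data.frame"))
}

#' Block-mean smoothing of an activity series
#'
#' Averages consecutive blocks of `block` entries (a trailing partial
#' block is averaged over its own length). `block = 1` returns the
#' series unchanged.
#'
#' @param series an `activity_series`.
#' @param block positive integer block length.
#' @return data.frame with `t_seconds` (block mean) and `count`
#'   (block-mean count, real-valued).
#' @export
smooth_activity <- function(series, block) {
  if (block < 1L) abort_validation("block must be >= 1")
  if (block == 1L) return(series)
  grp <- (seq_len(nrow(series)) - 1L) %/% block
  data.frame(
    t_seconds = as.numeric(tapply(series$t_seconds, grp, mean)),
    count = as.numeric(tapply(series$count, grp, mean)))
}

#' Plot a trajectory over the background image
#'
#' Renders the background as a grayscale raster with the track overlaid
#' — the classic single-animal follow-up figure.
#'
#' @param trajectory a `trajectory`.
#' @param background a `background_model` or grayscale matrix.
#' @param path optional PNG output path; `NULL` draws on the active
#'   device.
#' @param col,lwd line colour and width.
#' @return `path` (or `NULL`), invisibly.
#' @export
plot_trajectory <- function(trajectory, background, path = NULL,
                            col = "red", lwd = 2) {
  img <- to_grayscale(as_pixels(background))
  if (!is.null(path)) {
    grDevices::png(path, width = ncol(img), height = nrow(img))
    on.exit(grDevices::dev.off())
    graphics::par(mar = c(0, 0, 0, 0))
  }
  ras <- grDevices::as.raster(img / 255)
  graphics::plot(NA, xlim = c(0.5, ncol(img) + 0.5),
                 ylim = c(nrow(img) + 0.5, 0.5), asp = 1,
                 xlab = "", ylab = "", axes = FALSE)
  graphics::rasterImage(ras, 0.5, nrow(img) + 0.5, ncol(img) + 0.5, 0.5)
  if (nrow(trajectory$points) > 1L)
    graphics::lines(trajectory$points$col, trajectory$points$row,
                    col = col, lwd = lwd)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
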