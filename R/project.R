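#' Still-background construction by Z-projection
#'
#' Reduces an image stack to a single composite image by a per-pixel
#' statistic across frames. Because the organisms move and the substrate
#' does not, the projection keeps only the motionless scene: with
#' organisms lighter than the substrate the minimum projection is the
#' still background (the darkest value at each pixel is substrate), with
#' darker organisms the maximum, and the median or mean are more robust
#' when lighting drifts slowly or contrast is marginal.
#'
#' All four statistics are computed channelwise for RGB stacks and return
#' integral pixel values in the input bit depth: the mean, and the median
#' of an even number of frames (mean of the two central order
#' statistics), are rounded half up.
#'
#' @param stack an [image_stack].
#' @param method one of `"min"`, `"max"`, `"median"`, `"mean"`.
#' @return An object of class `background_model`: list with `image` (same
#'   shape as the frames), `method`, and `source_frame_indices`.
#' @examples
#' fr <- lapply(c(5, 3, 7), function(v) matrix(v, 4, 4))
#' project(image_stack(fr), "min")$image[1, 1]  # 3
#' @export
project <- function(stack, method = c("min", "max", "median", "mean")) {
  method <- match.arg(method)
  if (!inherits(stack, "image_stack"))
    abort_validation("project() expects an image_stack")
  frames <- stack$frames
  n <- length(frames)
  shape <- dim(frames[[1L]])
  if (length(shape) == 3L) {
    chans <- lapply(seq_len(shape[3L]), function(k) {
      project_channel(lapply(frames, function(f) f[, , k]), method)
    })
    img <- array(unlist(chans, use.names = FALSE), dim = shape)
  } else {
    img <- project_channel(frames, method)
  }
  structure(list(image = img, method = method,
                 source_frame_indices = stack$frame_index),
            class = "background_model")
}

# per-pixel reduction of a list of matrices sharing one shape
project_channel <- function(frames, method) {
  n <- length(frames)
  if (n == 1L) return(frames[[1L]])
  switch(method,
    min = Reduce(pmin, frames),
    max = Reduce(pmax, frames),
    mean = {
      s <- Reduce(`+`, frames)
      m <- round_half_up(s / n)
      dim(m) <- dim(frames[[1L]])
      m
    },
    median = {
      # column-wise sort of the n x P value matrix in one order() call
      X <- do.call(rbind, lapply(frames, as.vector))
      Xs <- matrix(X[order(col(X), X)], nrow = n)
      med <- if (n %% 2L == 1L) Xs[(n + 1L) %/% 2L, ]
             else round_half_up((Xs[n %/% 2L, ] + Xs[n %/% 2L + 1L, ]) / 2)
      matrix(med, nrow = nrow(frames[[1L]]))
    })
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf("<background_model> %s projection of %d frame(s), %s px\n",
              x$method, length(x$source_frame_indices),
              paste(dim(x$image), collapse = " x ")))
  invisible(x)
}

#' Remove the still background from a frame
#'
#' `mode = "subtract"` computes `max(frame - background, 0)` and reveals
#' only organisms on the bright side of the substrate; `mode =
#' "difference"` computes `|frame - background|` and catches organisms
#' that are locally either brighter or darker (useful on faintly
#' contrasted substrates). RGB frames are handled channelwise.
#'
#' @param frame a frame (matrix or RGB array).
#' @param background a `background_model` (or bare pixel array) of the
#'   same shape.
#' @param mode `"subtract"` or `"difference"`.
#' @return An object of class `residual_frame`: list with non-negative
#'   `image`, `mode`, `source_frame_index`.
#' @export
remove_background <- function(frame, background,
                              mode = c("subtract", "difference"),
                              source_frame_index = NA_integer_) {
  mode <- match.arg(mode)
  bg <- as_pixels(background)
  if (!identical(dim(frame), dim(bg)))
    abort_validation(sprintf(
      "frame (%s) and background (%s) dimensions differ",
      paste(dim(frame), collapse = ","), paste(dim(bg), collapse = ",")))
  img <- if (mode == "subtract") pmax(frame - bg, 0) else abs(frame - bg)
  structure(list(image = img, mode = mode,
                 source_frame_index = as.integer(source_frame_index)),
            class = "residual_frame")
}

#' Re-align a translated stack by Fourier cross-correlation
#'
#' The whole method assumes perfectly lined-up frames: a nudged camera
#' blurs the projected background and the census fails. This recovers,
#' per frame, the integer-pixel translation maximising the circular
#' cross-correlation with a reference frame (computed as a product of
#' Fourier transforms, means removed), shifts the frame back, and fills
#' the vacated margins with the reference frame's pixels. Registration is
#' integer-pixel and translation-only.
#'
#' @param stack an [image_stack] with at least 2 frames.
#' @param reference_index position of the reference frame (default 1).
#' @return list with `stack` (the aligned [image_stack]) and `shifts`
#'   (n x 2 integer matrix of (row, col) shifts applied to each frame).
#' @export
register_stack <- function(stack, reference_index = 1L) {
  if (!inherits(stack, "image_stack"))
    abort_validation("register_stack() expects an image_stack")
  n <- n_frames(stack)
  if (n < 2L) abort_validation("registration needs at least 2 frames")
  if (reference_index < 1L || reference_index > n)
    abort_validation(sprintf(
      "reference_index %d out of range [1, %d]", reference_index, n))
  ref <- stack$frames[[reference_index]]
  ref_g <- to_grayscale(ref, stack$bit_depth)
  Fref <- stats::fft(ref_g - mean(ref_g))
  shifts <- matrix(0L, n, 2L, dimnames = list(NULL, c("row", "col")))
  frames <- stack$frames
  for (i in seq_len(n)) {
    if (i == reference_index) next
    g <- to_grayscale(frames[[i]], stack$bit_depth)
    cc <- Re(stats::fft(Fref * Conj(stats::fft(g - mean(g))), inverse = TRUE))
    k <- arrayInd(which.max(cc), dim(cc)) - 1L
    # wrap circular lags to signed shifts
    d <- dim(cc)
    k <- ifelse(k > d %/% 2L, k - d, k)
    shifts[i, ] <- k
    frames[[i]] <- shift_frame(frames[[i]], ref, k)
  }
  list(stack = image_stack(frames, frame_index = stack$frame_index,
                           timestamp_seconds = stack$timestamp_seconds,
                           bit_depth = stack$bit_depth),
       shifts = shifts)
}

# translate `frame` by integer (row, col) shift; margins from `fill_frame`
shift_frame <- function(frame, fill_frame, shift) {
  if (all(shift == 0L)) return(frame)
  d <- dim(frame)[1:2]
  out <- fill_frame
  dst_r <- max(1L, 1L + shift[1L]):min(d[1L], d[1L] + shift[1L])
  dst_c <- max(1L, 1L + shift[2L]):min(d[2L], d[2L] + shift[2L])
  src_r <- dst_r - shift[1L]
  src_c <- dst_c - shift[2L]
  if (is_rgb(frame)) out[dst_r, dst_c, ] <- frame[src_r, src_c, ]
  else out[dst_r, dst_c] <- frame[src_r, src_c]
  out
}
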