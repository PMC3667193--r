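#' Image stacks of a fixed scene
#'
#' An `image_stack` holds an ordered set of co-registered frames of one
#' scene: the raw material from which a still background is projected.
#' Frames are numeric matrices (grayscale) or `rows x cols x 3` arrays
#' (RGB) with integral pixel values in `[0, 2^bit_depth - 1]`. Pixel
#' coordinates are 1-based `(row, col)` with the origin at the top-left
#' corner, everywhere in this package.
#'
#' @param frames list of frames, all of identical dimensions and channel
#'   count.
#' @param frame_index integer vector, strictly increasing; defaults to
#'   `seq_along(frames)`.
#' @param timestamp_seconds optional numeric vector of acquisition times.
#' @param bit_depth integer, bits per channel (default 8).
#' @return An object of class `image_stack`: a list with elements
#'   `frames`, `frame_index`, `timestamp_seconds`, `bit_depth`.
#' @examples
#' f <- matrix(0, 10, 10)
#' s <- image_stack(list(f, f, f))
#' n_frames(s)
#' @export
image_stack <- function(frames, frame_index = seq_along(frames),
                        timestamp_seconds = NULL, bit_depth = 8L) {
  if (!is.list(frames) || length(frames) < 1L)
    abort_validation("an image stack needs at least one frame")
  d1 <- dim(frames[[1L]])
  for (i in seq_along(frames)) {
    di <- dim(frames[[i]])
    if (!identical(length(di), length(d1)) || !all(di == d1))
      abort_validation(sprintf(
        "frame %d has dimensions (%s); expected (%s)",
        i, paste(di, collapse = ","), paste(d1, collapse = ",")))
    rng <- range(frames[[i]])
    if (rng[1L] < 0 || rng[2L] > 2^bit_depth - 1)
      abort_validation(sprintf(
        "frame %d has pixel values outside [0, %d]", i, 2^bit_depth - 1L))
  }
  frame_index <- as.integer(frame_index)
  if (length(frame_index) != length(frames) ||
      any(diff(frame_index) <= 0L))
    abort_validation("frame_index must be strictly increasing, one per frame")
  if (!is.null(timestamp_seconds) &&
      length(timestamp_seconds) != length(frames))
    abort_validation("timestamp_seconds must have one entry per frame")
  structure(
    list(frames = frames, frame_index = frame_index,
         timestamp_seconds = timestamp_seconds,
         bit_depth = as.integer(bit_depth)),
    class = "image_stack")
}

#' @rdname image_stack
#' @param x an `image_stack`.
#' @export
n_frames <- function(x) length(x$frames)

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1L]])
  cat(sprintf("<image_stack> %d frame(s), %d x %d px, %s, %d-bit\n",
              n_frames(x), d[1L], d[2L],
              if (length(d) == 3L) sprintf("%d channels", d[3L]) else "grayscale",
              x$bit_depth))
  invisible(x)
}

#' Subset an image stack by frame position
#'
#' `s[i]` keeps frames at positions `i` (in order), retaining their
#' original frame indices and timestamps.
#' @param x an `image_stack`.
#' @param i integer positions.
#' @param ... ignored.
#' @export
`[.image_stack` <- function(x, i, ...) {
  i <- seq_len(n_frames(x))[i]
  image_stack(x$frames[i], frame_index = x$frame_index[i],
              timestamp_seconds = x$timestamp_seconds[i],
              bit_depth = x$bit_depth)
}

image_extensions <- c("tif", "tiff", "png", "jpg", "jpeg")

read_image_file <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("cannot read image file '%s'", path))
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path, all = TRUE),
    png = png::readPNG(path),
    jpg = , jpeg = jpeg::readJPEG(path),
    abort_io(sprintf("unsupported image format '%s' for '%s'", ext, path)))
  if (ext %in% c("tif", "tiff")) {
    # readTIFF(all = TRUE) returns a list of pages, values scaled to [0,1]
    imgs <- lapply(img, normalise_read_image)
  } else {
    imgs <- list(normalise_read_image(img))
  }
  imgs
}

normalise_read_image <- function(img) {
  img <- round_half_up(img * 255)
  if (length(dim(img)) == 3L) {
    if (dim(img)[3L] == 4L) img <- img[, , 1:3, drop = FALSE]  # drop alpha
    if (dim(img)[3L] == 1L) img <- img[, , 1L]
  }
  img
}

#' Load an ordered image sequence into a stack
#'
#' Reads TIFF/PNG/JPEG files in the given order (a single multi-page TIFF
#' expands to its pages). All files must share dimensions and channel
#' count; RGB is preserved as three channels, alpha channels are dropped.
#'
#' @param paths character vector of image file paths, in temporal order.
#' @param timestamp_seconds optional per-frame acquisition times.
#' @return An [image_stack] with `frame_index = seq_len(n)`.
#' @export
load_stack <- function(paths, timestamp_seconds = NULL) {
  if (length(paths) < 1L) abort_validation("at least one image path is required")
  frames <- list()
  origin <- character()
  for (p in paths) {
    imgs <- read_image_file(p)
    frames <- c(frames, imgs)
    origin <- c(origin, rep(p, length(imgs)))
  }
  d1 <- dim(frames[[1L]])
  for (i in seq_along(frames)) {
    if (!identical(dim(frames[[i]]), d1))
      abort_validation(sprintf(
        "image '%s' has dimensions (%s) but '%s' has (%s)",
        origin[i], paste(dim(frames[[i]]), collapse = ","),
        origin[1L], paste(d1, collapse = ",")))
  }
  image_stack(frames, timestamp_seconds = timestamp_seconds)
}

#' Convert an RGB frame to 8-bit grayscale
#'
#' Uses the Rec. 709 luminance weights
#' `0.2126 R + 0.7152 G + 0.0722 B`, rounded half up and clipped to the
#' bit-depth range. A single-channel input is returned unchanged.
#'
#' @param frame matrix (grayscale) or `rows x cols x 3` array (RGB).
#' @param bit_depth integer, bits per channel (default 8).
#' @return A grayscale matrix.
#' @examples
#' px <- array(c(100, 200, 50), dim = c(1, 1, 3))
#' to_grayscale(px)  # 168
#' @export
to_grayscale <- function(frame, bit_depth = 8L) {
  nc <- n_channels(frame)
  if (nc == 1L) return(frame)
  if (nc != 3L)
    abort_validation(sprintf("expected 1 or 3 channels, got %d", nc))
  g <- 0.2126 * frame[, , 1L] + 0.7152 * frame[, , 2L] + 0.0722 * frame[, , 3L]
  clip_depth(round_half_up(g), bit_depth)
}

#' Write an 8-bit image to TIFF or PNG
#'
#' @param image matrix or `rows x cols x 3` array with values in
#'   `[0, 255]`, or a `background_model` / `residual_frame`.
#' @param path output path; format chosen by extension (.tif/.tiff/.png).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  img <- as_pixels(image)
  img <- clip_depth(round_half_up(img)) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = tiff::writeTIFF(img, path, bits.per.sample = 8L),
    png = png::writePNG(img, path),
    abort_io(sprintf("unsupported output format '%s'", ext)))
  invisible(path)
}
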