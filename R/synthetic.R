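#' Specification of a synthetic microcosm scene
#'
#' Describes a seeded, fully ground-truthed imitation of a rearing-box
#' image stack: a static heterogeneous substrate (linear illumination
#' gradient, pixel speckle, fixed bright debris), organisms rendered as
#' filled 3:1 ellipses brighter (or darker) than the substrate that move
#' by independent random walks reflecting at the walls, i.i.d. Gaussian
#' pixel noise, and an optional slow global illumination drift. Every
#' random quantity comes from one stream seeded by `seed`, consumed in a
#' fixed order (substrate, organism attributes, walk steps, per-frame
#' noise), so the same spec always produces bit-identical frames.
#'
#' @param seed integer seed (mandatory).
#' @param frame_shape `(rows, cols)` in pixels.
#' @param n_frames number of frames.
#' @param n_organisms number of moving organisms.
#' @param length_mm organism length distribution: list with `dist`
#'   (`"uniform"` or `"lognormal"`), its parameters (`min`/`max`, or
#'   `meanlog`/`sdlog`), always truncated to `[trunc_min, trunc_max]`
#'   (defaults 0.1–3 mm, the collembolan size range).
#' @param organism_intensity grey-level offset of organism pixels over
#'   the local substrate (positive = brighter, as pale springtails on
#'   ink-darkened plaster).
#' @param background list: `base` grey level, `gradient` amplitude,
#'   `speckle_sd`, `n_debris`, `debris_intensity` (offset),
#'   `debris_size_px` (semi-axis range).
#' @param step_px random-walk step s.d. per axis per frame, pixels.
#' @param noise_sigma s.d. of additive Gaussian pixel noise.
#' @param illumination_drift additive grey-level offset per frame step.
#' @param pixels_per_mm spatial sampling.
#' @param bit_depth bits per pixel (default 8).
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(seed,
                       frame_shape = c(300L, 300L),
                       n_frames = 5L,
                       n_organisms = 50L,
                       length_mm = list(dist = "uniform", min = 0.5,
                                        max = 1.5),
                       organism_intensity = 120,
                       background = list(base = 60, gradient = 20,
                                         speckle_sd = 5, n_debris = 8,
                                         debris_intensity = 100,
                                         debris_size_px = c(2, 5)),
                       step_px = 5,
                       noise_sigma = 2,
                       illumination_drift = 0,
                       pixels_per_mm = 10,
                       bit_depth = 8L) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L)
    abort_validation("scene_spec requires a single integer seed")
  if (n_frames < 1L || n_organisms < 0L)
    abort_validation("n_frames must be >= 1 and n_organisms >= 0")
  length_mm$trunc_min <- length_mm$trunc_min %||% 0.1
  length_mm$trunc_max <- length_mm$trunc_max %||% 3.0
  bg_default <- list(base = 60, gradient = 20, speckle_sd = 5,
                     n_debris = 8, debris_intensity = 100,
                     debris_size_px = c(2, 5))
  background <- utils::modifyList(bg_default, background)
  structure(
    list(seed = as.integer(seed), frame_shape = as.integer(frame_shape),
         n_frames = as.integer(n_frames),
         n_organisms = as.integer(n_organisms), length_mm = length_mm,
         organism_intensity = organism_intensity, background = background,
         step_px = step_px, noise_sigma = noise_sigma,
         illumination_drift = illumination_drift,
         pixels_per_mm = pixels_per_mm, bit_depth = as.integer(bit_depth)),
    class = "scene_spec")
}

# fold coordinates into [lo, hi] by reflection at the walls
# (vectorised over x, lo and hi: each organism has its own margin)
reflect_into <- function(x, lo, hi) {
  span <- hi - lo
  y <- (x - lo) %% (2 * span)
  out <- lo + ifelse(y > span, 2 * span - y, y)
  ifelse(span <= 0, lo, out)
}

# linear pixel indices of a filled ellipse at (cr, cc), semi-axes a >= b,
# long axis at angle theta from the row axis; clipped to the frame
ellipse_pixels <- function(cr, cc, a, b, theta, nr, nc) {
  r0 <- max(1L, floor(cr - a)); r1 <- min(nr, ceiling(cr + a))
  c0 <- max(1L, floor(cc - a)); c1 <- min(nc, ceiling(cc + a))
  if (r0 > r1 || c0 > c1) return(integer())
  rs <- r0:r1; cs <- c0:c1
  dr <- rep(rs - cr, times = length(cs))
  dc <- rep(cs - cc, each = length(rs))
  u <- dr * cos(theta) + dc * sin(theta)
  v <- -dr * sin(theta) + dc * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  rr <- rep(rs, times = length(cs))[inside]
  cc2 <- rep(cs, each = length(rs))[inside]
  rr + (cc2 - 1L) * nr
}

#' Generate a synthetic scene with ground truth
#'
#' @param spec a [scene_spec()].
#' @return list with `stack` (an [image_stack]) and `truth`
#'   (class `ground_truth`): `true_background` (integer matrix),
#'   `organisms` (list, one data.frame per frame: `id`, `row`, `col`,
#'   `length_mm`, `area_px`), `pixels` (per frame, list of linear pixel
#'   index vectors per organism), `coverage_map` (per-pixel count of
#'   organism-free frames), and `spec`.
#' @export
generate_scene <- function(spec) {
  if (!inherits(spec, "scene_spec"))
    abort_validation("generate_scene() expects a scene_spec")
  nr <- spec$frame_shape[1L]; nc <- spec$frame_shape[2L]
  vmax <- 2^spec$bit_depth - 1
  lens_px_max <- max_length_px(spec)
  if (lens_px_max >= min(nr, nc))
    abort_validation("organisms larger than the frame")

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  bgspec <- spec$background
  # 1. substrate: base + plane gradient + speckle + fixed debris
  a12 <- stats::runif(2, -1, 1) * bgspec$gradient
  rowf <- (seq_len(nr) - 1) / max(nr - 1, 1)
  colf <- (seq_len(nc) - 1) / max(nc - 1, 1)
  bg <- bgspec$base + outer(rowf * a12[1L], colf * a12[2L], `+`)
  if (bgspec$speckle_sd > 0)
    bg <- bg + matrix(stats::rnorm(nr * nc, 0, bgspec$speckle_sd), nr, nc)
  if (bgspec$n_debris > 0L) {
    for (k in seq_len(bgspec$n_debris)) {
      dcr <- stats::runif(1, 1, nr); dcc <- stats::runif(1, 1, nc)
      ax <- stats::runif(2, bgspec$debris_size_px[1L],
                         bgspec$debris_size_px[2L])
      th <- stats::runif(1, 0, pi)
      px <- ellipse_pixels(dcr, dcc, max(ax), min(ax), th, nr, nc)
      bg[px] <- bg[px] + bgspec$debris_intensity
    }
  }
  true_bg <- clip_depth(round_half_up(bg), spec$bit_depth)

  # 2. organism attributes: lengths, orientations, starting positions
  n <- spec$n_organisms
  lens_mm <- draw_lengths(spec$length_mm, n)
  a <- pmax(lens_mm * spec$pixels_per_mm / 2, 1e-6)
  b <- a / 3
  theta <- stats::runif(n, 0, 2 * pi)
  margin <- pmin(a + 1, (min(nr, nc) - 1) / 2)
  pos_r <- stats::runif(n, 1 + margin, nr - margin)
  pos_c <- stats::runif(n, 1 + margin, nc - margin)

  # 3. random-walk steps, reflecting at the walls
  positions <- vector("list", spec$n_frames)
  positions[[1L]] <- cbind(pos_r, pos_c)
  if (spec$n_frames > 1L && n > 0L) {
    for (i in 2L:spec$n_frames) {
      stp <- matrix(stats::rnorm(2L * n, 0, spec$step_px), n, 2L)
      pr <- reflect_into(positions[[i - 1L]][, 1L] + stp[, 1L],
                         1 + margin, nr - margin)
      pc <- reflect_into(positions[[i - 1L]][, 2L] + stp[, 2L],
                         1 + margin, nc - margin)
      positions[[i]] <- cbind(pr, pc)
    }
  } else if (spec$n_frames > 1L) {
    positions[2L:spec$n_frames] <- list(cbind(pos_r, pos_c))
  }

  # 4. render frames, then drift and noise
  frames <- vector("list", spec$n_frames)
  organisms <- vector("list", spec$n_frames)
  pixel_sets <- vector("list", spec$n_frames)
  free_count <- matrix(0L, nr, nc)
  for (i in seq_len(spec$n_frames)) {
    img <- true_bg
    sets <- vector("list", n)
    if (n > 0L) {
      for (k in seq_len(n)) {
        px <- ellipse_pixels(positions[[i]][k, 1L], positions[[i]][k, 2L],
                             a[k], b[k], theta[k], nr, nc)
        img[px] <- clip_depth(true_bg[px] + spec$organism_intensity,
                              spec$bit_depth)
        sets[[k]] <- px
      }
    }
    occupied <- matrix(FALSE, nr, nc)
    occupied[unlist(sets, use.names = FALSE)] <- TRUE
    free_count <- free_count + !occupied
    organisms[[i]] <- data.frame(
      id = seq_len(n),
      row = if (n > 0L) positions[[i]][, 1L] else numeric(),
      col = if (n > 0L) positions[[i]][, 2L] else numeric(),
      length_mm = lens_mm,
      area_px = vapply(sets, length, integer(1L)))
    pixel_sets[[i]] <- sets
    if (spec$illumination_drift != 0)
      img <- img + spec$illumination_drift * (i - 1L)
    if (spec$noise_sigma > 0)
      img <- img + stats::rnorm(nr * nc, 0, spec$noise_sigma)
    frames[[i]] <- clip_depth(round_half_up(img), spec$bit_depth)
  }

  list(stack = image_stack(frames, bit_depth = spec$bit_depth),
       truth = structure(
         list(true_background = true_bg, organisms = organisms,
              pixels = pixel_sets, coverage_map = free_count, spec = spec),
         class = "ground_truth"))
}

max_length_px <- function(spec) {
  l <- spec$length_mm
  mx <- switch(l$dist,
    uniform = l$max,
    lognormal = l$trunc_max,
    abort_validation("length_mm$dist must be 'uniform' or 'lognormal'"))
  min(mx, l$trunc_max) * spec$pixels_per_mm
}

draw_lengths <- function(l, n) {
  if (n == 0L) return(numeric())
  x <- switch(l$dist,
    uniform = stats::runif(n, l$min, l$max),
    lognormal = stats::rlnorm(n, l$meanlog, l$sdlog),
    abort_validation("length_mm$dist must be 'uniform' or 'lognormal'"))
  pmin(pmax(x, l$trunc_min), l$trunc_max)
}

#' Fraction of substrate visible in at least one frame
#'
#' The background projection is only exact where every pixel is
#' organism-free in at least one frame; this is the fraction of pixels
#' meeting that condition. At 1 the still background is fully
#' recoverable.
#'
#' @param truth a `ground_truth` from [generate_scene()].
#' @return a number in `[0, 1]`.
#' @export
coverage_fraction <- function(truth) {
  mean(truth$coverage_map >= 1L)
}

#' Export a synthetic scene as numbered image files
#'
#' Writes the frames as `frame_001.png`, ... (or `.tif`) into a
#' directory, matching the batch directory layout, so the batch pipeline
#' can be exercised end-to-end on files.
#'
#' @param stack an [image_stack] (e.g. `generate_scene(spec)$stack`).
#' @param dir output directory (created if needed).
#' @param format `"png"` or `"tif"`.
#' @param prefix file-name prefix.
#' @return character vector of the paths written, invisibly.
#' @export
write_scene <- function(stack, dir, format = c("png", "tif"),
                        prefix = "frame") {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, sprintf("%s_%03d.%s", prefix,
                                  seq_len(n_frames(stack)), format))
  for (i in seq_len(n_frames(stack)))
    write_image(stack$frames[[i]], paths[i])
  invisible(paths)
}
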