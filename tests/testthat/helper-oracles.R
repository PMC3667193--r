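# Independent brute-force oracles and small scene builders used across
# the suite. Oracles deliberately share no code with the implementation.

# stack of constant-valued frames from a vector of pixel values
const_stack <- function(values, nr = 4, nc = 4) {
  image_stack(lapply(values, function(v) matrix(v, nr, nc)))
}

rhu <- function(x) floor(x + 0.5)  # round half up, local copy

# per-pixel projection by explicit loops over sorted values
oracle_project <- function(frames, method) {
  d <- dim(frames[[1]])
  out <- matrix(NA_real_, d[1], d[2])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    v <- sort(vapply(frames, function(f) f[i, j], numeric(1)))
    n <- length(v)
    out[i, j] <- switch(method,
      min = v[1], max = v[n],
      mean = rhu(sum(v) / n),
      median = if (n %% 2 == 1) v[(n + 1) / 2]
               else rhu((v[n / 2] + v[n / 2 + 1]) / 2))
  }
  out
}

# exhaustive Otsu: maximise between-class variance over all 256 splits;
# tied maximisers (identical class partitions) average to the plateau
# midpoint
oracle_otsu <- function(x) {
  v <- as.vector(x)
  s <- rep(-Inf, 255)
  for (t in 0:254) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (length(lo) == 0 || length(hi) == 0) next
    w0 <- length(lo) / length(v); w1 <- 1 - w0
    s[t + 1] <- w0 * w1 * (mean(lo) - mean(hi))^2
  }
  cand <- which(s == max(s)) - 1
  rhu(mean(cand))
}

# recursive flood-fill labeling (order-independent comparison via
# partition equality)
oracle_label <- function(mask, connectivity) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nb <- if (connectivity == 4)
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  else
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    queue <- list(c(i, j)); lab[i, j] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(nb))) {
        q <- p + nb[k, ]
        if (q[1] < 1 || q[1] > nr || q[2] < 1 || q[2] > nc) next
        if (mask[q[1], q[2]] && lab[q[1], q[2]] == 0L) {
          lab[q[1], q[2]] <- cur
          queue[[length(queue) + 1]] <- q
        }
      }
    }
  }
  lab
}

# both labelers assign labels in column-major first-encounter order, so
# equality of the label matrices is the partition-equality check
strip_attr <- function(m) { attributes(m) <- list(dim = dim(m)); m }

# a small noise-free scene with organisms bright over a flat-ish substrate
quiet_spec <- function(seed, ...) {
  args <- utils::modifyList(list(
    seed = seed, frame_shape = c(120L, 120L), n_frames = 5L,
    n_organisms = 8L,
    length_mm = list(dist = "uniform", min = 0.6, max = 1.2),
    organism_intensity = 120,
    background = list(base = 60, gradient = 20, speckle_sd = 5,
                      n_debris = 4, debris_intensity = 80,
                      debris_size_px = c(2, 4)),
    step_px = 8, noise_sigma = 0, pixels_per_mm = 10), list(...))
  do.call(scene_spec, args)
}

# ground-truth preconditions for exact-count claims: full coverage and
# organisms forming exactly n separate 8-connected components each frame
scene_is_clean <- function(scene) {
  truth <- scene$truth
  if (coverage_fraction(truth) < 1) return(FALSE)
  d <- dim(truth$true_background)
  for (i in seq_along(truth$pixels)) {
    sets <- truth$pixels[[i]]
    if (any(vapply(sets, length, integer(1)) == 0L)) return(FALSE)
    occ <- matrix(FALSE, d[1], d[2])
    occ[unlist(sets)] <- TRUE
    if (label_particles(occ, 8)$n != length(sets)) return(FALSE)
  }
  TRUE
}

# derive sub-seeds from a master seed and return the first clean scene
clean_scene <- function(seed, ..., max_tries = 50) {
  for (k in seq_len(max_tries)) {
    sc <- generate_scene(quiet_spec(seed * 1000 + k, ...))
    if (scene_is_clean(sc)) return(sc)
  }
  stop("no clean scene found; conditions too dense for these parameters")
}

default_config <- function(...) {
  args <- utils::modifyList(list(
    removal_mode = "subtract", scale = scale_calibration(10),
    projection = "min", threshold_method = "fixed",
    threshold_value = 50, polarity = "bright"), list(...))
  do.call(census_config, args)
}
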