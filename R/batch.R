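#' Discover microcosm boxes under a directory tree
#'
#' The batch layout is a directory tree whose leaf directories each hold
#' one box's ordered image sequence, e.g.
#' `root/line_A/box_01/frame_001.png`. A "box" is any leaf directory
#' (no subdirectories) containing at least one TIFF/PNG/JPEG file;
#' non-image files are ignored; frames are ordered lexicographically
#' (temporal order by naming convention); boxes are returned sorted by
#' id, so discovery is deterministic.
#'
#' @param root_dir root of the tree.
#' @return list of entries, each a list with `box_id` (path relative to
#'   root) and `paths` (ordered frame files).
#' @export
discover_boxes <- function(root_dir) {
  if (!dir.exists(root_dir))
    abort_io(sprintf("directory '%s' does not exist", root_dir))
  dirs <- c(root_dir, list.dirs(root_dir, recursive = TRUE,
                                full.names = TRUE))
  dirs <- unique(normalizePath(dirs))
  is_leaf <- vapply(dirs, function(d)
    length(list.dirs(d, recursive = FALSE)) == 0L, logical(1L))
  boxes <- list()
  for (d in sort(dirs[is_leaf])) {
    files <- list.files(d, full.names = TRUE)
    imgs <- files[tolower(tools::file_ext(files)) %in% image_extensions]
    if (length(imgs) == 0L) next
    id <- sub("^/", "", sub(normalizePath(root_dir), "", d, fixed = TRUE))
    if (id == "") id <- "."
    boxes[[length(boxes) + 1L]] <- list(box_id = id, paths = sort(imgs))
  }
  if (length(boxes) == 0L)
    abort_validation(sprintf(
      "no boxes (leaf directories with image files) found under '%s'",
      root_dir))
  boxes[order(vapply(boxes, `[[`, character(1L), "box_id"))]
}

#' Batch configuration
#'
#' Everything [run_batch()] needs: where the boxes are, where results
#' go, and the full census configuration applied to every box.
#'
#' @param root_dir directory tree of boxes (see [discover_boxes()]).
#' @param output_dir where result tables and images are written.
#' @param removal_mode,scale,... forwarded to [census_config()];
#'   `scale` may also be given as a bare number (pixels per mm).
#' @param write_background also save each box's background image as PNG.
#' @param log_level `"info"` or `"quiet"`.
#' @return An object of class `batch_config`.
#' @export
batch_config <- function(root_dir, output_dir, removal_mode, scale, ...,
                         write_background = TRUE,
                         log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  if (is.numeric(scale)) scale <- scale_calibration(scale)
  census <- census_config(removal_mode = removal_mode, scale = scale, ...)
  structure(list(root_dir = root_dir, output_dir = output_dir,
                 census = census, write_background = write_background,
                 log_level = log_level),
            class = "batch_config")
}

#' Read a batch configuration from a YAML file
#'
#' Keys mirror the arguments of [batch_config()] / [census_config()]
#' (e.g. `root_dir`, `output_dir`, `removal_mode`, `pixels_per_mm` or
#' `reference_side_mm`, `projection`, `threshold_method`,
#' `threshold_value`, `polarity`, `connectivity`, `min_area_mm2`,
#' `max_area_mm2`, `roi` (`full`/`auto`), `size_min_mm`, `size_max_mm`,
#' `size_bin_mm`, `write_background`, `log_level`).
#'
#' @param path YAML file.
#' @param root_dir,output_dir optional overrides.
#' @return A [batch_config()].
#' @export
read_batch_config <- function(path, root_dir = NULL, output_dir = NULL) {
  y <- yaml::read_yaml(path)
  if (!is.null(root_dir)) y$root_dir <- root_dir
  if (!is.null(output_dir)) y$output_dir <- output_dir
  if (!is.null(y$pixels_per_mm)) {
    y$scale <- scale_calibration(y$pixels_per_mm)
    y$pixels_per_mm <- NULL
  } else if (!is.null(y$reference_side_mm)) {
    y$scale <- "reference_square"
  }
  do.call(batch_config, y)
}

batch_log <- function(con, level, msg) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), msg)
  if (level == "info") message(line)
  if (!is.null(con)) writeLines(line, con)
}

# write a data.frame atomically: temp file in the same directory, then rename
write_csv_atomic <- function(df, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".csv")
  utils::write.csv(df, tmp, row.names = FALSE)
  file.rename(tmp, path)
}

#' Run the batch census over every discovered box
#'
#' Applies [census_box()] to each box in the tree. One box failing
#' (unreadable frame, mismatched sizes, failed calibration) never aborts
#' the batch: the error is recorded and the remaining boxes complete.
#' Outputs — a one-row-per-box summary CSV, per-box particle and
#' size-histogram CSVs, and optionally per-box background PNGs — are
#' written atomically, and re-running on identical inputs reproduces
#' them bit-exactly. A per-run log records the configuration hash for
#' provenance.
#'
#' @param config a [batch_config()].
#' @return An object of class `batch_result`: list with `summary`
#'   (data.frame), `results` (named list of `census_result`), `failures`
#'   (data.frame `box_id`, `error`), `config_hash`, `n_boxes`.
#' @export
run_batch <- function(config) {
  if (!inherits(config, "batch_config"))
    abort_validation("run_batch() expects a batch_config")
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out) || file.access(out, 2L) != 0L)
    abort_io(sprintf("output directory '%s' is not writable", out))
  boxes <- discover_boxes(config$root_dir)
  hash <- config_hash(config)
  logcon <- file(file.path(out, "run.log"), open = "at")
  on.exit(close(logcon))
  batch_log(logcon, config$log_level, sprintf(
    "batch start: %d box(es) under '%s', config %s, microcensus %s",
    length(boxes), config$root_dir, hash,
    as.character(utils::packageVersion("microcensus"))))
  results <- list()
  failures <- data.frame(box_id = character(), error = character())
  rows <- list()
  for (b in boxes) {
    res <- tryCatch({
      stack <- load_stack(b$paths)
      r <- census_box(stack, config$census)
      safe <- gsub("[/\\\\]", "_", b$box_id)
      write_census_csv(
        r, particles_csv = file.path(out, paste0(safe, "_particles.csv")),
        histogram_csv = file.path(out, paste0(safe, "_histogram.csv")))
      if (config$write_background)
        write_image(r$background, file.path(out, paste0(safe, "_background.png")))
      r
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- rbind(failures, data.frame(box_id = b$box_id,
                                             error = conditionMessage(res)))
      batch_log(logcon, config$log_level,
                sprintf("box '%s' FAILED: %s", b$box_id,
                        conditionMessage(res)))
    } else {
      results[[b$box_id]] <- res
      rows[[b$box_id]] <- data.frame(
        box_id = b$box_id, n_frames = res$n_frames_used,
        mean_count = res$mean_count,
        biosurface_mm2 = res$biosurface_mm2,
        corrected_count = res$corrected_count,
        min_frame_count = min(res$per_frame_counts),
        max_frame_count = max(res$per_frame_counts))
      batch_log(logcon, config$log_level, sprintf(
        "box '%s': mean count %.2f, biosurface %.3f mm^2",
        b$box_id, res$mean_count, res$biosurface_mm2))
    }
  }
  summary <- if (length(rows)) do.call(rbind, rows) else
    data.frame(box_id = character(), n_frames = integer(),
               mean_count = numeric(), biosurface_mm2 = numeric(),
               corrected_count = numeric(), min_frame_count = integer(),
               max_frame_count = integer())
  rownames(summary) <- NULL
  write_csv_atomic(summary, file.path(out, "summary.csv"))
  if (nrow(failures) > 0L)
    write_csv_atomic(failures, file.path(out, "failures.csv"))
  batch_log(logcon, config$log_level, sprintf(
    "batch done: %d ok, %d failed", nrow(summary), nrow(failures)))
  structure(list(summary = summary, results = results,
                 failures = failures, config_hash = hash,
                 n_boxes = length(boxes)),
            class = "batch_result")
}

# md5 of the serialized census configuration (provenance, not security)
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config$census, tmp, version = 2L)
  unname(tools::md5sum(tmp))
}

#' @export
print.batch_result <- function(x, ...) {
  cat(sprintf("<batch_result> %d box(es): %d ok, %d failed\n",
              x$n_boxes, nrow(x$summary), nrow(x$failures)))
  invisible(x)
}
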