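#' Run the full fence-analysis pipeline
#'
#' Executes the stages in order: detection input, spatiotemporal tracking,
#' gap splitting and fragment merging, fence membership and valid-path
#' extraction with metadata summaries, and (when configured) homography
#' mapping of each path to world coordinates. One log line per stage with
#' counts is written via `message()` when `verbose = TRUE`.
#'
#' @param detections A `"pose_detections"` data frame (e.g. from
#'   [read_detections()] or [simulate_scene()]).
#' @param config A `"fencetrack_config"` from [load_config()] /
#'   [as_fencetrack_config()].
#' @param annotations Optional annotation data frame (see
#'   [read_annotations()]).
#' @param analyzed_frames Analyzed frame indices. Defaults to the stride
#'   grid `0, frame_stride, ...` covering the detections (so trailing and
#'   interior empty frames age the tracker memory and drive the finalize
#'   trigger).
#' @param verbose Log per-stage counts (default `TRUE`).
#' @return A list of class `"fence_report"`: `fence` (config echo), counts
#'   per stage, `finalize_events`, `paths` (one entry per valid crossing
#'   with entry/exit frames, timing, metadata, image polyline and, when a
#'   homography is configured, `polyline_world`), `incomplete_paths`, and
#'   the intermediate `fence_paths` object as attribute `"fence_paths"`.
#' @export
run_pipeline <- function(detections, config, annotations = NULL,
                         analyzed_frames = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "fencetrack_config"))
  fen <- config$fence
  log <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))

  det <- detections
  if (is.null(analyzed_frames)) {
    top <- if (nrow(det)) max(det$frame) else 0L
    analyzed_frames <- sample_frames(top + 10L * fen$frame_stride + 1L,
                                     fen$frame_stride)
    if (nrow(det) && !all(det$frame %in% analyzed_frames))
      analyzed_frames <- sort(unique(c(analyzed_frames, det$frame)))
  }
  log("io: %d detections over %d frames", nrow(det),
      length(unique(det$frame)))

  tracks <- track_sequence(det, analyzed_frames = analyzed_frames,
                           match_frac = config$tracker$match_frac,
                           memory_frames = config$tracker$memory_frames)
  log("tracker: %d tracks", length(unique(tracks$track_id)))

  frags <- split_on_gaps(tracks)
  log("merger: %d fragments", nrow(attr(frags, "fragments")))

  merged <- merge_fragments(frags,
                            threshold = config$merger$merge_threshold,
                            lambda_t = config$merger$lambda_t,
                            fence = fen,
                            reverse_tol = config$merger$reverse_tol)
  log("merger: %d merged paths", length(attr(merged, "lineage")))

  fpaths <- extract_valid_paths(
    merged, fen,
    min_inside = config$fence_analysis$min_inside,
    annotations = annotations,
    team_aggregation = config$fence_analysis$team_aggregation)
  log("fence_analysis: %d valid paths (%d incomplete)",
      length(fpaths), length(attr(fpaths, "incomplete")))

  occ <- fence_occupancy(merged, fen, analyzed_frames)
  events <- finalize_trigger(occ,
                             config$fence_analysis$empty_frames_to_finalize)

  paths <- lapply(fpaths, function(p) {
    entry <- list(
      path_id = p$path_id,
      entry_frame = p$entry_frame, exit_frame = p$exit_frame,
      duration_s = p$duration_s, crossing_s = p$crossing_s,
      major_mode = p$major_mode,
      mode_breakdown = as.list(p$mode_breakdown),
      team_scores = as.list(p$team_scores),
      polyline = unname(p$polyline))
    if (!is.null(config$homography))
      entry$polyline_world <- unname(transform_points(config$homography,
                                                      p$polyline))
    entry
  })

  report <- structure(list(
    fence = list(xmin = fen$xmin, ymin = fen$ymin, xmax = fen$xmax,
                 ymax = fen$ymax, travel_axis = fen$travel_axis,
                 fps = fen$fps, frame_stride = fen$frame_stride),
    counts = list(detections = nrow(det),
                  tracks = length(unique(tracks$track_id)),
                  fragments = nrow(attr(frags, "fragments")),
                  merged_paths = length(attr(merged, "lineage")),
                  valid_paths = length(fpaths)),
    finalize_events = events$trigger_frame,
    paths = paths,
    incomplete_paths = attr(fpaths, "incomplete")),
    class = "fence_report")
  attr(report, "fence_paths") <- fpaths
  attr(report, "homography") <- config$homography
  report
}

#' @export
print.fence_report <- function(x, ...) {
  cat("<fence_report>\n")
  cat(sprintf("  detections %d -> tracks %d -> fragments %d -> merged %d -> valid paths %d\n",
              x$counts$detections, x$counts$tracks, x$counts$fragments,
              x$counts$merged_paths, x$counts$valid_paths))
  for (p in x$paths)
    cat(sprintf("  path %d: frames %d-%d, %.2f s, mode %s\n",
                p$path_id, p$entry_frame, p$exit_frame, p$crossing_s,
                p$major_mode))
  invisible(x)
}

#' Write a fence report as JSON
#'
#' Serializes the payload that would be published per finalize event:
#' fence geometry, per-path timing, metadata summaries and polylines (image
#' pixels, plus world coordinates when a homography is configured).
#'
#' @param report A `"fence_report"`.
#' @param path Output file, or `""` for stdout.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  out <- unclass(report)
  attr(out, "fence_paths") <- NULL
  attr(out, "homography") <- NULL
  json <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, null = "null")
  if (identical(path, "")) cat(json, "\n") else writeLines(json, path)
  invisible(path)
}

#' Read a fence report written by [write_report()]
#'
#' @param path JSON report file.
#' @return The report as a `"fence_report"` list (polylines as matrices).
#' @export
read_report <- function(path) {
  r <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                          simplifyDataFrame = FALSE, simplifyMatrix = TRUE)
  r$paths <- lapply(r$paths, function(p) {
    p$polyline <- matrix(unlist(p$polyline), ncol = 2L, byrow = !is.matrix(p$polyline))
    if (!is.null(p$polyline_world))
      p$polyline_world <- matrix(unlist(p$polyline_world), ncol = 2L,
                                 byrow = !is.matrix(p$polyline_world))
    p
  })
  structure(r, class = "fence_report")
}

#' Plot riding lines from a fence report
#'
#' Draws one polyline per valid path, in world coordinates when available,
#' otherwise in image pixels (with the y axis flipped to match the image
#' convention), plus the fence outline when plotting in pixels. Colors are
#' assigned in ascending `path_id` order, so rendering is deterministic.
#'
#' @param report A `"fence_report"`.
#' @param file Optional PNG output path; when `NULL`, draws on the current
#'   device.
#' @param ... Passed to [graphics::plot()].
#' @return `file` (or `NULL`), invisibly.
#' @export
plot_ridelines <- function(report, file = NULL, ...) {
  stopifnot(inherits(report, "fence_report"))
  if (!is.null(file)) {
    ok <- tryCatch({ grDevices::png(file, width = 800, height = 600); TRUE },
                   error = function(e)
                     stop("cannot open plot file: ", file, call. = FALSE))
    on.exit(grDevices::dev.off())
  }
  world <- length(report$paths) > 0 &&
    !is.null(report$paths[[1]]$polyline_world)
  polys <- lapply(report$paths, function(p)
    if (world) p$polyline_world else p$polyline)
  ord <- order(vapply(report$paths, function(p) p$path_id, numeric(1)))
  polys <- polys[ord]

  fen <- report$fence
  if (length(polys)) {
    xs <- unlist(lapply(polys, function(m) m[, 1]))
    ys <- unlist(lapply(polys, function(m) m[, 2]))
  } else { xs <- ys <- numeric(0) }
  if (!world) {
    xs <- c(xs, fen$xmin, fen$xmax); ys <- c(ys, fen$ymin, fen$ymax)
  }
  if (!length(xs)) { xs <- 0:1; ys <- 0:1 }
  ylim <- if (world) range(ys) else rev(range(ys))  # image y points down
  graphics::plot(range(xs), ylim, type = "n", asp = 1,
                 xlab = if (world) "world x" else "image x (px)",
                 ylab = if (world) "world y" else "image y (px)",
                 main = "Riding lines through the fence", ...)
  if (!world)
    graphics::rect(fen$xmin, fen$ymin, fen$xmax, fen$ymax, border = "grey40",
                   lty = 2)
  cols <- grDevices::hcl.colors(max(1L, length(polys)), "Dark 3")
  for (i in seq_along(polys)) {
    graphics::lines(polys[[i]], col = cols[i], lwd = 2)
    graphics::points(polys[[i]][1, , drop = FALSE], col = cols[i], pch = 16)
  }
  if (length(polys))
    graphics::legend("topright",
                     legend = sprintf("path %d",
                                      vapply(report$paths[ord],
                                             function(p) p$path_id,
                                             numeric(1))),
                     col = cols[seq_along(polys)], lwd = 2, bty = "n")
  invisible(file)
}
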