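default_params <- function() {
  list(
    tracker = list(match_frac = 0.25, memory_frames = 5L,
                   keypoint_min_conf = 0.05),
    merger = list(lambda_t = 10, merge_threshold = NA_real_,
                  reverse_tol = 0.1),
    fence_analysis = list(min_inside = 2L, empty_frames_to_finalize = 10L,
                          team_aggregation = "mean")
  )
}

#' Load a scene configuration
#'
#' The configuration declares the fence (rectangle, travel direction, frame
#' rate) and optionally overrides pipeline parameters and provides
#' image-to-world homography correspondences. YAML and JSON files are
#' accepted (chosen by file extension; `.json` is parsed as JSON, anything
#' else as YAML).
#'
#' Recognized keys and defaults:
#' \describe{
#'   \item{fence}{`xmin`, `ymin`, `xmax`, `ymax` (required), `travel_axis`
#'     (default `"left_to_right"`), `fps` (required), `frame_stride`
#'     (default 3).}
#'   \item{tracker}{`match_frac` (default 0.25: matching gate as a fraction
#'     of the new pose's bbox diagonal), `memory_frames` (default 5: how many
#'     analyzed frames an unmatched track is remembered),
#'     `keypoint_min_conf` (default 0.05).}
#'   \item{merger}{`lambda_t` (default 10 px per analyzed frame: weight of
#'     the temporal gap in the spatiotemporal merge distance),
#'     `merge_threshold` (default 0.25 x fence diagonal), `reverse_tol`
#'     (default 0.1: tolerated backward motion as a fraction of the fence
#'     extent along the travel axis).}
#'   \item{fence_analysis}{`min_inside` (default 2: minimum detections inside
#'     the fence for a valid path), `empty_frames_to_finalize` (default 10
#'     consecutive empty analyzed frames), `team_aggregation` (`"mean"` or
#'     `"max"`).}
#'   \item{homography}{`correspondences`: list of `{image: [x, y],
#'     world: [X, Y]}` pairs (>= 4). World units are meters by convention
#'     (documented, not enforced).}
#' }
#'
#' @param path Path to a YAML or JSON configuration file.
#' @return A list of class `"fencetrack_config"` with elements `fence` (a
#'   [fence()] object), `tracker`, `merger`, `fence_analysis` (parameter
#'   lists) and `homography` (a `"homography"` object or `NULL`).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                       simplifyMatrix = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  as_fencetrack_config(raw)
}

#' Build a configuration from an R list
#'
#' Same structure and defaults as [load_config()], for configs constructed
#' programmatically.
#'
#' @param raw Named list mirroring the config file structure.
#' @return A `"fencetrack_config"` object.
#' @export
as_fencetrack_config <- function(raw) {
  if (is.null(raw$fence)) stop("config: missing 'fence' section")
  fc <- raw$fence
  for (k in c("xmin", "ymin", "xmax", "ymax"))
    if (is.null(fc[[k]])) stop("config: fence rectangle is missing '", k, "'")
  if (is.null(fc$fps)) stop("config: fence is missing 'fps'")
  fen <- fence(fc$xmin, fc$ymin, fc$xmax, fc$ymax,
               travel_axis = if (is.null(fc$travel_axis)) "left_to_right"
                             else fc$travel_axis,
               fps = fc$fps,
               frame_stride = if (is.null(fc$frame_stride)) 3L
                              else fc$frame_stride)

  p <- default_params()
  for (sect in names(p)) {
    for (k in names(raw[[sect]])) {
      if (!k %in% names(p[[sect]]))
        stop(sprintf("config: unknown key '%s' in section '%s'", k, sect))
      p[[sect]][[k]] <- raw[[sect]][[k]]
    }
  }
  if (is.na(p$merger$merge_threshold))
    p$merger$merge_threshold <- 0.25 * fence_diagonal(fen)
  if (!p$fence_analysis$team_aggregation %in% c("mean", "max"))
    stop("config: team_aggregation must be 'mean' or 'max'")
  if (p$fence_analysis$min_inside < 2)
    stop("config: min_inside must be >= 2")

  hom <- NULL
  if (!is.null(raw$homography$correspondences)) {
    cp <- raw$homography$correspondences
    img <- do.call(rbind, lapply(cp, function(c.) as.numeric(unlist(c.$image))))
    wld <- do.call(rbind, lapply(cp, function(c.) as.numeric(unlist(c.$world))))
    hom <- estimate_homography(img, wld)
  }

  structure(list(fence = fen, tracker = p$tracker, merger = p$merger,
                 fence_analysis = p$fence_analysis, homography = hom),
            class = "fencetrack_config")
}

#' @export
print.fencetrack_config <- function(x, ...) {
  cat("<fencetrack_config>\n")
  print(x$fence)
  cat(sprintf("  tracker: match_frac=%g memory_frames=%d\n",
              x$tracker$match_frac, x$tracker$memory_frames))
  cat(sprintf("  merger: lambda_t=%g threshold=%.1f px reverse_tol=%g\n",
              x$merger$lambda_t, x$merger$merge_threshold,
              x$merger$reverse_tol))
  cat(sprintf("  fence_analysis: min_inside=%d empty_frames_to_finalize=%d team_aggregation=%s\n",
              x$fence_analysis$min_inside,
              x$fence_analysis$empty_frames_to_finalize,
              x$fence_analysis$team_aggregation))
  cat(sprintf("  homography: %s\n",
              if (is.null(x$homography)) "none" else "configured"))
  invisible(x)
}
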