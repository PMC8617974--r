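#' Dwell time between entry and exit frames
#'
#' Elapsed time between the first and last detection inside the fence, using
#' original video frame numbering, so the source frame rate applies
#' directly.
#'
#' @param entry_frame,exit_frame Original video frame indices,
#'   `exit_frame >= entry_frame`.
#' @param fps Frames per second of the source video (> 0).
#' @return Seconds, `(exit_frame - entry_frame) / fps`.
#' @examples
#' dwell_time(30, 120, 30)  # 3 s
#' @export
dwell_time <- function(entry_frame, exit_frame, fps) {
  if (any(fps <= 0)) stop("fps must be > 0")
  if (any(exit_frame < entry_frame)) stop("exit_frame must be >= entry_frame")
  (exit_frame - entry_frame) / fps
}

#' Detect fence-empty finalize triggers
#'
#' In streaming operation, path post-processing fires once the fence has
#' been empty for a configured number of consecutive analyzed frames. One
#' event is emitted at the `empty_needed`-th consecutive empty frame of each
#' empty run; the counter resets whenever the fence is occupied, and a run
#' longer than `empty_needed` does not re-trigger.
#'
#' @param occupancy Data frame with columns `frame` (analyzed frame indices,
#'   ascending) and `n_inside` (number of riders inside the fence at that
#'   frame).
#' @param empty_needed Consecutive empty analyzed frames required
#'   (default 10).
#' @return Data frame with columns `kind` (`"finalize"`) and
#'   `trigger_frame`.
#' @export
finalize_trigger <- function(occupancy, empty_needed = 10L) {
  stopifnot(empty_needed >= 1)
  if (is.unsorted(occupancy$frame, strictly = TRUE))
    stop("occupancy frames must be strictly increasing")
  run <- 0L
  trig <- integer(0)
  for (i in seq_len(nrow(occupancy))) {
    if (occupancy$n_inside[i] == 0L) {
      run <- run + 1L
      if (run == empty_needed) trig <- c(trig, occupancy$frame[i])
    } else run <- 0L
  }
  data.frame(kind = rep("finalize", length(trig)), trigger_frame = trig)
}

#' Fence occupancy per analyzed frame
#'
#' Counts detections whose bbox center lies inside the fence, for every
#' analyzed frame (frames with no detections count as empty).
#'
#' @param det Data frame with columns `frame`, `cx`, `cy`.
#' @param fence A [fence()] object.
#' @param analyzed_frames Analyzed frame indices; defaults to the frames
#'   present in `det`.
#' @return Data frame with columns `frame`, `n_inside`.
#' @export
fence_occupancy <- function(det, fence, analyzed_frames = NULL) {
  if (is.null(analyzed_frames)) analyzed_frames <- sort(unique(det$frame))
  inside <- det[in_fence(det$cx, det$cy, fence), , drop = FALSE]
  cnt <- table(factor(inside$frame, levels = analyzed_frames))
  data.frame(frame = analyzed_frames, n_inside = as.integer(cnt))
}

mode_majority <- function(labels) {
  if (!length(labels)) return("unknown")
  prio <- ride_modes()
  counts <- table(factor(labels, levels = prio))
  prio[which.max(counts)]  # which.max takes the first maximum: priority order
}

#' Summarize ride-mode and team metadata over a path's fence frames
#'
#' Aggregates per-detection annotations over the frames a rider spent inside
#' the fence: the major ride mode is the modal label (ties broken by the
#' fixed priority riding > running > crashing > spectator > unknown); the
#' mode breakdown converts per-mode frame counts to seconds using the
#' analyzed-frame period `frame_stride / fps`; team scores are the
#' arithmetic mean of the per-frame probability vectors, renormalized
#' (`aggregation = "max"` takes the per-team maximum instead, then
#' renormalizes).
#'
#' @param modes Character vector of ride-mode labels for the inside-fence
#'   frames (missing annotations should be passed as `"unknown"` or
#'   omitted).
#' @param team_probs List of named numeric probability vectors (entries may
#'   be `NULL`).
#' @param fence A [fence()] object supplying `fps` and `frame_stride`.
#' @param aggregation `"mean"` or `"max"`.
#' @return List with `major_mode`, `mode_breakdown` (named numeric, seconds,
#'   only modes actually observed), `team_scores` (named numeric summing to
#'   1, or empty).
#' @export
summarize_metadata <- function(modes, team_probs = list(), fence,
                               aggregation = c("mean", "max")) {
  aggregation <- match.arg(aggregation)
  period <- fence$frame_stride / fence$fps
  major <- mode_majority(modes)
  breakdown <- numeric(0)
  if (length(modes)) {
    tab <- table(modes)
    breakdown <- as.numeric(tab) * period
    names(breakdown) <- names(tab)
  }
  team_probs <- Filter(Negate(is.null), team_probs)
  scores <- numeric(0)
  if (length(team_probs)) {
    teams <- unique(unlist(lapply(team_probs, names)))
    m <- sapply(team_probs, function(p) {
      out <- setNames(numeric(length(teams)), teams)
      out[names(p)] <- p
      out
    })
    m <- matrix(m, nrow = length(teams),
                dimnames = list(teams, NULL))
    scores <- if (aggregation == "mean") rowMeans(m) else apply(m, 1, max)
    if (sum(scores) > 0) scores <- scores / sum(scores)
  }
  list(major_mode = major, mode_breakdown = breakdown, team_scores = scores)
}

#' Extract valid fence crossings from merged paths
#'
#' A valid path belongs to a rider who entered *and* exited the fence: it
#' must have at least one detection before its first inside-fence detection
#' (necessarily outside), at least `min_inside` detections inside, and at
#' least one detection after its last inside detection. The entry and exit
#' frames are the first and last inside detections (original video
#' numbering). `duration_s` is their difference over `fps`; because both
#' ends are quantized to the analyzed-frame grid, the additionally reported
#' `crossing_s` adds half an analyzed-frame period at each end
#' (`frame_stride / fps` in total), an estimate of the true boundary-to-
#' boundary crossing time that is accurate to within one analyzed-frame
#' period for steady motion.
#'
#' Paths that enter but are still inside when the stream ends are excluded
#' from the result and listed in the `incomplete` attribute.
#'
#' @param paths A `"merged_paths"` object from [merge_fragments()] (or a
#'   `"track_set"`, treating each track as a path).
#' @param fence A [fence()] object.
#' @param min_inside Minimum detections inside the fence (default 2).
#' @param annotations Optional annotation data frame (see
#'   [read_annotations()]) joined to detections by `(frame,
#'   detection_ref)`, where `detection_ref` is the 1-based position of the
#'   detection within its frame in the original input order.
#' @param team_aggregation Passed to [summarize_metadata()].
#' @return A list of class `"fence_paths"`; each element describes one valid
#'   crossing: `path_id`, `entry_frame`, `exit_frame`, `duration_s`,
#'   `crossing_s`, `positions` (data frame `frame`, `cx`, `cy`,
#'   `in_fence`), `polyline` (inside-fence centers, n x 2), `major_mode`,
#'   `mode_breakdown`, `team_scores`, `ride_mode_history`. Attribute
#'   `incomplete` lists path ids that entered without exiting.
#' @export
extract_valid_paths <- function(paths, fence, min_inside = 2L,
                                annotations = NULL,
                                team_aggregation = "mean") {
  stopifnot(min_inside >= 2)
  det <- as.data.frame(paths)
  if (!"path_id" %in% names(det)) {
    if ("track_id" %in% names(det)) det$path_id <- det$track_id
    else stop("paths must have a path_id (or track_id) column")
  }
  det <- det[order(det$path_id, det$frame), , drop = FALSE]
  det$in_fence <- in_fence(det$cx, det$cy, fence)

  ann_key <- NULL
  if (!is.null(annotations) && nrow(annotations))
    ann_key <- paste(annotations$frame, annotations$detection_ref)
  if (!"detection_ref" %in% names(det)) {
    # default join key: position of the detection within its frame
    o <- order(det$frame)
    ref <- integer(nrow(det))
    ref[o] <- stats::ave(rep(1L, nrow(det)), det$frame[o], FUN = seq_along)
    det$detection_ref <- ref
  }

  out <- list()
  incomplete <- integer(0)
  for (pid in unique(det$path_id)) {
    p <- det[det$path_id == pid, , drop = FALSE]
    ins <- which(p$in_fence)
    if (length(ins) < min_inside) next
    entered <- ins[1] > 1L
    exited <- ins[length(ins)] < nrow(p)
    if (!entered) next
    if (!exited) {
      incomplete <- c(incomplete, pid)
      next
    }
    entry <- p$frame[ins[1]]
    exit <- p$frame[ins[length(ins)]]
    dur <- dwell_time(entry, exit, fence$fps)

    modes <- character(0)
    probs <- list()
    hist <- data.frame(frame = integer(0), ride_mode = character(0))
    if (!is.null(ann_key)) {
      idx <- match(paste(p$frame, p$detection_ref), ann_key)
      got <- which(!is.na(idx))
      hist <- data.frame(frame = p$frame[got],
                         ride_mode = annotations$ride_mode[idx[got]])
      got_in <- got[got %in% ins]
      modes <- annotations$ride_mode[idx[got_in]]
      probs <- annotations$team_probs[idx[got_in]]
    }
    meta <- summarize_metadata(modes, probs, fence,
                               aggregation = team_aggregation)

    out[[length(out) + 1L]] <- list(
      path_id = pid,
      entry_frame = entry, exit_frame = exit,
      duration_s = dur,
      crossing_s = dur + fence$frame_stride / fence$fps,
      positions = p[, c("frame", "cx", "cy", "in_fence")],
      polyline = cbind(x = p$cx[ins], y = p$cy[ins]),
      major_mode = meta$major_mode,
      mode_breakdown = meta$mode_breakdown,
      team_scores = meta$team_scores,
      ride_mode_history = hist
    )
  }
  structure(out, class = "fence_paths", incomplete = incomplete,
            fence = fence)
}

#' @export
print.fence_paths <- function(x, ...) {
  cat(sprintf("<fence_paths> %d valid crossings", length(x)))
  inc <- attr(x, "incomplete")
  if (length(inc)) cat(sprintf(" (+%d incomplete, still inside at stream end)",
                               length(inc)))
  cat("\n")
  for (p in x)
    cat(sprintf("  path %d: frames %d-%d, %.2f s in fence, mode %s\n",
                p$path_id, p$entry_frame, p$exit_frame, p$crossing_s,
                p$major_mode))
  invisible(x)
}

#' @export
as.data.frame.fence_paths <- function(x, ...) {
  if (!length(x))
    return(data.frame(path_id = integer(0), entry_frame = integer(0),
                      exit_frame = integer(0), duration_s = numeric(0),
                      crossing_s = numeric(0), major_mode = character(0)))
  do.call(rbind, lapply(x, function(p)
    data.frame(path_id = p$path_id, entry_frame = p$entry_frame,
               exit_frame = p$exit_frame, duration_s = p$duration_s,
               crossing_s = p$crossing_s, major_mode = p$major_mode)))
}
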