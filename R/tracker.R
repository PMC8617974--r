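#' Match new pose detections to live track states
#'
#' One step of the spatiotemporal tracker. Distances are Euclidean, in pixel
#' space, between the last known centers of the live tracks and the centers
#' of the new poses. A new pose may only match its minimum-distance live
#' state, and only when that distance is strictly smaller than
#' `match_frac` times the diagonal of the *new* pose's bounding box (the
#' matching gate). Matches are mutually exclusive: when several poses claim
#' the same state, the claim with the smaller distance wins; ties are broken
#' by lower track id, then lower pose index. Unmatched poses are reported as
#' unassigned so the caller can open fresh tracks.
#'
#' @param states Data frame of live track states with columns `track_id`,
#'   `cx`, `cy` (last known center).
#' @param poses Data frame of new detections with columns `cx`, `cy`,
#'   `diagonal`.
#' @param match_frac Gate fraction of the new pose's bbox diagonal
#'   (default 0.25).
#' @return Integer vector of length `nrow(poses)`: the matched `track_id`
#'   per pose, `NA` where the pose is unmatched.
#' @export
match_frame <- function(states, poses, match_frac = 0.25) {
  stopifnot(match_frac > 0)
  np <- if (is.null(poses)) 0L else nrow(poses)
  if (np == 0L) return(integer(0))
  assign <- rep(NA_integer_, np)
  ns <- if (is.null(states)) 0L else nrow(states)
  if (ns == 0L) return(assign)
  if (!all(is.finite(c(states$cx, states$cy, poses$cx, poses$cy))))
    stop("match_frame: non-finite center coordinates")

  # distance matrix: states x poses
  dx <- outer(states$cx, poses$cx, "-")
  dy <- outer(states$cy, poses$cy, "-")
  d <- sqrt(dx^2 + dy^2)

  # per pose: its nearest live state (ties -> lower track_id), gated
  cand_state <- integer(np)
  cand_dist <- numeric(np)
  for (p in seq_len(np)) {
    dmin <- min(d[, p])
    tied <- which(d[, p] == dmin)
    s <- tied[which.min(states$track_id[tied])]
    cand_state[p] <- s
    cand_dist[p] <- dmin
  }
  ok <- cand_dist < match_frac * poses$diagonal
  # resolve conflicting claims in ascending distance
  ord <- order(cand_dist, states$track_id[cand_state], seq_len(np))
  taken <- logical(ns)
  for (p in ord) {
    if (!ok[p]) next
    s <- cand_state[p]
    if (!taken[s]) {
      taken[s] <- TRUE
      assign[p] <- states$track_id[s]
    }
  }
  assign
}

#' Drop track states not seen recently
#'
#' States whose age (current analyzed frame index minus the analyzed frame
#' index at which they were last matched) exceeds `memory_frames` are
#' removed from the live set. Ages are counted in analyzed frames, i.e. on
#' the post-stride processing grid.
#'
#' @param states Data frame of live states with a `last_aframe` column
#'   (analyzed-frame index of the last match).
#' @param current_aframe Current analyzed-frame index.
#' @param memory_frames Maximum age retained (default 5).
#' @return The surviving subset of `states`.
#' @export
evict_stale <- function(states, current_aframe, memory_frames = 5L) {
  stopifnot(memory_frames >= 1)
  if (is.null(states) || nrow(states) == 0L) return(states)
  states[current_aframe - states$last_aframe <= memory_frames, , drop = FALSE]
}

#' Track pose detections across analyzed frames
#'
#' Runs the full tracker loop over a detection stream: for each analyzed
#' frame, stale states are evicted, new poses are matched to live states
#' with [match_frame()], matched states are updated in place, and each
#' unmatched pose opens a fresh track with a monotonically increasing id.
#' The tracker is deterministic and seedless. Riders are assumed to travel
#' through the fence in a consistent direction, so centers move smoothly and
#' the diagonal-scaled gate suffices; identity-swap and re-identification
#' failures that survive this stage are repaired downstream by the fragment
#' merger.
#'
#' @param detections A `"pose_detections"` data frame (or any data frame
#'   with columns `frame`, `cx`, `cy`, `diagonal`).
#' @param analyzed_frames Strictly increasing integer vector of all analyzed
#'   frame indices, including frames with no detections (empty frames age
#'   and eventually evict track memory). Defaults to the sorted unique
#'   frames present in `detections`. Every detection frame must appear here.
#' @param match_frac Matching gate fraction, see [match_frame()].
#' @param memory_frames Track memory in analyzed frames, see
#'   [evict_stale()].
#' @return A `"track_set"`: the input data frame with an added integer
#'   `track_id` column and an added `aframe` column (1-based analyzed-frame
#'   index), with attributes `analyzed_frames` and `params`.
#' @export
track_sequence <- function(detections, analyzed_frames = NULL,
                           match_frac = 0.25, memory_frames = 5L) {
  det <- as.data.frame(detections)
  need <- c("frame", "cx", "cy", "diagonal")
  if (!all(need %in% names(det)))
    stop("detections must have columns frame, cx, cy, diagonal")
  if (is.null(analyzed_frames)) analyzed_frames <- sort(unique(det$frame))
  if (is.unsorted(analyzed_frames, strictly = TRUE))
    stop("analyzed_frames must be strictly increasing")
  if (nrow(det) && !all(det$frame %in% analyzed_frames))
    stop("detections contain frames not listed in analyzed_frames")

  det <- det[order(det$frame), , drop = FALSE]
  rownames(det) <- NULL
  det$aframe <- match(det$frame, analyzed_frames)
  det$track_id <- rep(NA_integer_, nrow(det))

  states <- data.frame(track_id = integer(0), cx = numeric(0),
                       cy = numeric(0), last_aframe = integer(0))
  next_id <- 1L
  by_frame <- split(seq_len(nrow(det)), det$aframe)

  for (a in seq_along(analyzed_frames)) {
    states <- evict_stale(states, a, memory_frames)
    rows <- by_frame[[as.character(a)]]
    if (is.null(rows)) next
    poses <- det[rows, , drop = FALSE]
    assign <- match_frame(states, poses, match_frac)
    for (j in seq_along(rows)) {
      if (is.na(assign[j])) {
        assign[j] <- next_id
        next_id <- next_id + 1L
        states <- rbind(states, data.frame(
          track_id = assign[j], cx = poses$cx[j], cy = poses$cy[j],
          last_aframe = a))
      } else {
        k <- match(assign[j], states$track_id)
        states$cx[k] <- poses$cx[j]
        states$cy[k] <- poses$cy[j]
        states$last_aframe[k] <- a
      }
    }
    det$track_id[rows] <- assign
  }

  structure(det,
            class = c("track_set", "data.frame"),
            analyzed_frames = analyzed_frames,
            params = list(match_frac = match_frac,
                          memory_frames = as.integer(memory_frames)))
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf("<track_set> %d detections, %d tracks, %d analyzed frames\n",
              nrow(x), length(unique(x$track_id)),
              length(attr(x, "analyzed_frames"))))
  invisible(x)
}
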