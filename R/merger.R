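#' Split tracks into gap-free fragments
#'
#' First step of the three-step merge strategy: tracks whose analyzed-frame
#' sequences contain jumps are split into maximal runs of consecutive
#' analyzed frames. Fragments from one track partition its detections.
#'
#' @param tracks A `"track_set"` from [track_sequence()].
#' @return A `"track_fragments"` data frame: the detections with an added
#'   integer `fragment_id` column (numbered in ascending order of fragment
#'   start frame, ties by source track id), plus a `fragments` attribute
#'   summarizing each fragment (`fragment_id`, `track_id`, `start_aframe`,
#'   `end_aframe`, `start_frame`, `end_frame`, start/end centers, `n`).
#' @export
split_on_gaps <- function(tracks) {
  det <- as.data.frame(tracks)
  stopifnot(all(c("track_id", "aframe") %in% names(det)))
  det <- det[order(det$track_id, det$aframe), , drop = FALSE]
  rownames(det) <- NULL
  if (nrow(det)) {
    new_run <- c(TRUE, diff(det$aframe) != 1L | diff(det$track_id) != 0L)
    run <- cumsum(new_run)
  } else run <- integer(0)
  det$fragment_id <- run

  # renumber fragments by (start aframe, track id) for a stable public order
  if (nrow(det)) {
    starts <- tapply(det$aframe, det$fragment_id, min)
    tids <- tapply(det$track_id, det$fragment_id, function(x) x[1])
    ord <- order(starts, tids)
    remap <- integer(length(ord))
    remap[ord] <- seq_along(ord)
    det$fragment_id <- remap[det$fragment_id]
    det <- det[order(det$fragment_id, det$aframe), , drop = FALSE]
    rownames(det) <- NULL
  }

  frags <- fragment_summary(det)
  structure(det, class = c("track_fragments", "data.frame"),
            fragments = frags,
            analyzed_frames = attr(tracks, "analyzed_frames"))
}

fragment_summary <- function(det) {
  if (!nrow(det))
    return(data.frame(fragment_id = integer(0), track_id = integer(0),
                      start_aframe = integer(0), end_aframe = integer(0),
                      start_frame = integer(0), end_frame = integer(0),
                      start_cx = numeric(0), start_cy = numeric(0),
                      end_cx = numeric(0), end_cy = numeric(0),
                      n = integer(0)))
  first <- !duplicated(det$fragment_id)
  last <- !duplicated(det$fragment_id, fromLast = TRUE)
  data.frame(
    fragment_id = det$fragment_id[first],
    track_id = det$track_id[first],
    start_aframe = det$aframe[first], end_aframe = det$aframe[last],
    start_frame = det$frame[first], end_frame = det$frame[last],
    start_cx = det$cx[first], start_cy = det$cy[first],
    end_cx = det$cx[last], end_cy = det$cy[last],
    n = as.integer(table(det$fragment_id)[as.character(det$fragment_id[first])])
  )
}

#' Spatiotemporal distance between two track fragments
#'
#' The merge weight from fragment `a` to fragment `b` is defined when `b`
#' starts strictly after `a` ends (on the analyzed-frame grid) as the
#' Euclidean distance between `a`'s last center and `b`'s first center plus
#' `lambda_t` pixels per analyzed frame of temporal gap. When the time order
#' is violated the pair is infeasible and `Inf` is returned; for fragments
#' with disjoint frame intervals exactly one direction is feasible.
#'
#' @param a,b One-row fragment summaries (rows of the `fragments` attribute
#'   of [split_on_gaps()] output, or lists with fields `end_aframe`,
#'   `end_cx`, `end_cy` for `a` and `start_aframe`, `start_cx`, `start_cy`
#'   for `b`).
#' @param lambda_t Temporal weight, pixels per analyzed frame (default 10).
#' @return Numeric weight in pixels, or `Inf` when infeasible.
#' @export
st_distance <- function(a, b, lambda_t = 10) {
  if (b$start_aframe <= a$end_aframe) return(Inf)
  sqrt((a$end_cx - b$start_cx)^2 + (a$end_cy - b$start_cy)^2) +
    lambda_t * (b$start_aframe - a$end_aframe)
}

axis_progress <- function(travel_axis, from_x, from_y, to_x, to_y) {
  switch(travel_axis,
         left_to_right = to_x - from_x,
         right_to_left = from_x - to_x,
         top_to_bottom = to_y - from_y,
         bottom_to_top = from_y - to_y)
}

axis_extent <- function(fence) {
  if (fence$travel_axis %in% c("left_to_right", "right_to_left"))
    fence$xmax - fence$xmin
  else fence$ymax - fence$ymin
}

#' Merge track fragments into rider paths
#'
#' Steps two and three of the merge strategy. Every ordered fragment pair
#' with disjoint time support gets a spatiotemporal weight
#' ([st_distance()]); links are formed greedily in ascending weight, subject
#' to: weight strictly below `threshold`; each fragment has at most one
#' predecessor and one successor; and, when a `fence` is supplied, the jump
#' from the end of one fragment to the start of the next must not move
#' backwards along the fence's travel axis by more than `reverse_tol` times
#' the fence extent on that axis (riders traverse the fence in a consistent
#' direction). Ties are broken by lower predecessor fragment id, then lower
#' successor id. Linked chains become merged paths; because a link requires
#' strictly later start, the frame-index lists of the fragments in one path
#' are pairwise disjoint, and re-running the merge on its own output changes
#' nothing.
#'
#' @param fragments A `"track_fragments"` object from [split_on_gaps()].
#' @param threshold Maximum merge weight in pixels. Defaults to a quarter of
#'   the fence diagonal when `fence` is given; otherwise must be supplied.
#' @param lambda_t Temporal weight passed to [st_distance()].
#' @param fence Optional [fence()] used for the threshold default and the
#'   direction-consistency check.
#' @param reverse_tol Tolerated backward motion, fraction of fence extent
#'   along the travel axis (default 0.1).
#' @return A `"merged_paths"` data frame: detections with an added integer
#'   `path_id` column, plus a `lineage` attribute mapping each path to its
#'   ordered fragment ids.
#' @export
merge_fragments <- function(fragments, threshold = NULL, lambda_t = 10,
                            fence = NULL, reverse_tol = 0.1) {
  det <- as.data.frame(fragments)
  frags <- attr(fragments, "fragments")
  if (is.null(frags)) stop("fragments must come from split_on_gaps()")
  if (is.null(threshold)) {
    if (is.null(fence))
      stop("either threshold or fence must be supplied")
    threshold <- 0.25 * fence_diagonal(fence)
  }
  nf <- nrow(frags)
  succ <- rep(NA_integer_, nf)
  pred <- rep(NA_integer_, nf)

  if (nf > 1L) {
    # all feasible ordered pairs below threshold
    cand_a <- integer(0); cand_b <- integer(0); cand_w <- numeric(0)
    for (i in seq_len(nf)) {
      for (j in seq_len(nf)) {
        if (i == j) next
        if (frags$start_aframe[j] <= frags$end_aframe[i]) next
        w <- sqrt((frags$end_cx[i] - frags$start_cx[j])^2 +
                  (frags$end_cy[i] - frags$start_cy[j])^2) +
             lambda_t * (frags$start_aframe[j] - frags$end_aframe[i])
        if (w >= threshold) next
        if (!is.null(fence)) {
          prog <- axis_progress(fence$travel_axis,
                                frags$end_cx[i], frags$end_cy[i],
                                frags$start_cx[j], frags$start_cy[j])
          if (prog < -reverse_tol * axis_extent(fence)) next
        }
        cand_a <- c(cand_a, i); cand_b <- c(cand_b, j); cand_w <- c(cand_w, w)
      }
    }
    if (length(cand_w)) {
      ord <- order(cand_w, frags$fragment_id[cand_a], frags$fragment_id[cand_b])
      for (k in ord) {
        i <- cand_a[k]; j <- cand_b[k]
        if (is.na(succ[i]) && is.na(pred[j])) {
          succ[i] <- j
          pred[j] <- i
        }
      }
    }
  }

  # walk chains from their heads
  path_of <- rep(NA_integer_, nf)
  lineage <- list()
  pid <- 0L
  heads <- which(is.na(pred))
  # order paths by start frame of their head fragment for stable ids
  heads <- heads[order(frags$start_aframe[heads], frags$fragment_id[heads])]
  for (h in heads) {
    pid <- pid + 1L
    chain <- integer(0)
    k <- h
    while (!is.na(k)) {
      path_of[k] <- pid
      chain <- c(chain, frags$fragment_id[k])
      k <- succ[k]
    }
    lineage[[pid]] <- chain
  }

  det$path_id <- path_of[match(det$fragment_id, frags$fragment_id)]
  det <- det[order(det$path_id, det$aframe), , drop = FALSE]
  rownames(det) <- NULL
  structure(det, class = c("merged_paths", "data.frame"),
            lineage = lineage, fragments = frags,
            analyzed_frames = attr(fragments, "analyzed_frames"))
}

#' @export
print.merged_paths <- function(x, ...) {
  cat(sprintf("<merged_paths> %d detections in %d paths (%d fragments)\n",
              nrow(x), length(attr(x, "lineage")),
              nrow(attr(x, "fragments"))))
  invisible(x)
}
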