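#' Build a pose-detection table from per-frame keypoint sets
#'
#' A detection is one skeleton in one frame: 17 COCO-ordered keypoints, each
#' `(x, y, confidence)`. The bounding box is derived as the tight axis-aligned
#' box over keypoints whose confidence exceeds `keypoint_min_conf`; the
#' center is the box midpoint and the diagonal its Euclidean length. These
#' derived fields are always recomputed from the keypoints, never read from a
#' file. If no keypoint passes the confidence filter, all keypoints are used.
#'
#' @param frame Integer vector of original-video frame indices, one per
#'   detection.
#' @param keypoints List of 17x3 numeric matrices (columns x, y, confidence),
#'   one per detection.
#' @param score Optional numeric detection score, one per detection.
#' @param keypoint_min_conf Keypoints with confidence <= this value are
#'   excluded from bounding-box derivation (default 0.05).
#' @return A data frame of class `"pose_detections"` with one row per
#'   detection and columns `frame`, `cx`, `cy`, `xmin`, `ymin`, `xmax`,
#'   `ymax`, `diagonal`, `score`, `detection_ref` (1-based position within
#'   the frame, the join key for annotations), plus a `keypoints` list
#'   column. Rows are sorted by frame (stable within frame).
#' @export
pose_detections <- function(frame, keypoints, score = NULL,
                            keypoint_min_conf = 0.05) {
  n <- length(frame)
  if (length(keypoints) != n)
    stop("frame and keypoints must have the same length")
  if (is.null(score)) score <- rep(NA_real_, n)
  frame <- as.integer(frame)

  boxes <- matrix(NA_real_, n, 4L)
  for (i in seq_len(n)) {
    kp <- keypoints[[i]]
    if (!is.matrix(kp) || nrow(kp) != 17L || ncol(kp) != 3L)
      stop(sprintf("detection %d (frame %s): expected a 17x3 keypoint matrix",
                   i, frame[i]))
    if (!all(is.finite(kp[, 1:2])))
      stop(sprintf("detection %d (frame %s): non-finite keypoint coordinates",
                   i, frame[i]))
    if (any(kp[, 3] < 0 | kp[, 3] > 1))
      stop(sprintf("detection %d (frame %s): keypoint confidence outside [0,1]",
                   i, frame[i]))
    keep <- kp[, 3] > keypoint_min_conf
    if (!any(keep)) keep <- rep(TRUE, 17L)
    boxes[i, ] <- c(min(kp[keep, 1]), min(kp[keep, 2]),
                    max(kp[keep, 1]), max(kp[keep, 2]))
  }

  out <- data.frame(
    frame = frame,
    cx = (boxes[, 1] + boxes[, 3]) / 2,
    cy = (boxes[, 2] + boxes[, 4]) / 2,
    xmin = boxes[, 1], ymin = boxes[, 2],
    xmax = boxes[, 3], ymax = boxes[, 4],
    diagonal = sqrt((boxes[, 3] - boxes[, 1])^2 + (boxes[, 4] - boxes[, 2])^2),
    score = as.numeric(score)
  )
  out$keypoints <- keypoints
  ord <- order(out$frame)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  # stable 1-based position within frame: the annotation join key
  out$detection_ref <- as.integer(
    stats::ave(rep(1L, nrow(out)), out$frame, FUN = seq_along))
  class(out) <- c("pose_detections", "data.frame")
  attr(out, "keypoint_min_conf") <- keypoint_min_conf
  out
}

#' @export
print.pose_detections <- function(x, ...) {
  cat(sprintf("<pose_detections> %d detections over %d frames\n",
              nrow(x), length(unique(x$frame))))
  if (nrow(x)) print.data.frame(utils::head(
    x[, c("frame", "cx", "cy", "diagonal", "score")], 10L))
  if (nrow(x) > 10L) cat(sprintf("  ... %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

kp_from_flat <- function(v) {
  matrix(as.numeric(v), ncol = 3L, byrow = TRUE)
}

#' Read pose detections from JSON
#'
#' Two dialects are supported. `"alphapose_json"` is a single JSON array of
#' records, each with an `image_id` (or `frame`) field, a flat `keypoints`
#' array of 51 numbers (`x, y, confidence` for the 17 COCO keypoints), and an
#' optional `score`. `"jsonl"` is line-delimited JSON: one such record per
#' line with an integer `frame` field. Bounding box, center and diagonal are
#' derived from the keypoints on read.
#'
#' @param path Path to the detections file.
#' @param dialect `"alphapose_json"` or `"jsonl"`.
#' @param keypoint_min_conf Confidence filter for bbox derivation, see
#'   [pose_detections()].
#' @return A `"pose_detections"` data frame sorted by frame.
#' @seealso [write_detections()]
#' @export
read_detections <- function(path, dialect = c("jsonl", "alphapose_json"),
                            keypoint_min_conf = 0.05) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("detections file not found: ", path)

  if (dialect == "alphapose_json") {
    recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    if (!is.list(recs)) stop("alphapose_json: expected a top-level JSON array")
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    recs <- lapply(lines, function(l) jsonlite::fromJSON(l, simplifyVector = FALSE))
  }
  if (!length(recs))
    return(pose_detections(integer(0), list(),
                           keypoint_min_conf = keypoint_min_conf))

  frames <- integer(length(recs))
  kps <- vector("list", length(recs))
  scores <- rep(NA_real_, length(recs))
  for (i in seq_along(recs)) {
    r <- recs[[i]]
    fr <- r$frame
    if (is.null(fr)) fr <- r$image_id
    if (is.null(fr))
      stop(sprintf("record %d: missing frame/image_id", i))
    if (is.character(fr)) {
      # Alphapose writes image filenames like "123.jpg"
      fr <- suppressWarnings(as.integer(sub("^0*([0-9]+).*$", "\\1", fr)))
    }
    fr <- suppressWarnings(as.integer(fr))
    if (is.na(fr)) stop(sprintf("record %d: unparseable frame index", i))
    kv <- unlist(r$keypoints)
    if (is.null(kv) || !is.numeric(kv))
      stop(sprintf("record %d (frame %d): missing or non-numeric keypoints",
                   i, fr))
    if (length(kv) != 51L)
      stop(sprintf(
        "record %d (frame %d): expected 17 keypoints (51 numbers), got %d numbers",
        i, fr, length(kv)))
    frames[i] <- fr
    kps[[i]] <- kp_from_flat(kv)
    if (!is.null(r$score)) scores[i] <- as.numeric(r$score)
  }
  pose_detections(frames, kps, scores, keypoint_min_conf = keypoint_min_conf)
}

#' Write pose detections as line-delimited JSON
#'
#' Emits one record per detection with `frame`, the flat 51-number
#' `keypoints` array, and `score`. Derived fields (bbox, center, diagonal)
#' are intentionally not written: they are a pure function of the keypoints
#' and are recomputed on read, so `read_detections(write_detections(x))`
#' returns `x`.
#'
#' @param det A `"pose_detections"` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_detections <- function(det, path) {
  stopifnot(inherits(det, "pose_detections"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(det))) {
    rec <- list(frame = det$frame[i],
                keypoints = as.numeric(t(det$keypoints[[i]])))
    if (!is.na(det$score[i])) rec$score <- det$score[i]
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Read per-detection frame annotations
#'
#' Annotations attach externally produced metadata to detections: a ride-mode
#' label (riding, running, crashing, spectator, unknown) and optionally a
#' named team-probability vector. Records are line-delimited JSON with fields
#' `frame`, `detection_ref` (1-based index of the detection within that
#' frame), `ride_mode`, and optional `team_probs` (object of
#' name-to-probability).
#'
#' @param path Path to the annotations file.
#' @return A data frame with columns `frame`, `detection_ref`, `ride_mode`
#'   and a `team_probs` list column of named numeric vectors (or `NULL`).
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotations file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(lines, function(l) jsonlite::fromJSON(l, simplifyVector = FALSE))
  modes <- ride_modes()
  n <- length(recs)
  out <- data.frame(frame = integer(n), detection_ref = integer(n),
                    ride_mode = character(n))
  tp <- vector("list", n)
  for (i in seq_along(recs)) {
    r <- recs[[i]]
    if (is.null(r$frame) || is.null(r$detection_ref))
      stop(sprintf("annotation record %d: missing frame or detection_ref", i))
    out$frame[i] <- as.integer(r$frame)
    out$detection_ref[i] <- as.integer(r$detection_ref)
    m <- if (is.null(r$ride_mode)) "unknown" else as.character(r$ride_mode)
    if (!m %in% modes)
      stop(sprintf("annotation record %d (frame %d): unknown ride_mode '%s'",
                   i, out$frame[i], m))
    out$ride_mode[i] <- m
    if (!is.null(r$team_probs)) {
      p <- unlist(r$team_probs)
      if (abs(sum(p) - 1) > 1e-6)
        stop(sprintf("annotation record %d (frame %d): team_probs sum to %g, not 1",
                     i, out$frame[i], sum(p)))
      tp[[i]] <- p
    }
  }
  out$team_probs <- tp
  out
}

#' Write frame annotations as line-delimited JSON
#'
#' @param ann Annotation data frame as returned by [read_annotations()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(ann))) {
    rec <- list(frame = ann$frame[i], detection_ref = ann$detection_ref[i],
                ride_mode = ann$ride_mode[i])
    if (!is.null(ann$team_probs[[i]]))
      rec$team_probs <- as.list(ann$team_probs[[i]])
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Closed vocabulary of per-frame rider behavior labels
#'
#' Order encodes the majority tie-break priority used when summarizing a
#' path's ride-mode history: earlier labels win ties.
#'
#' @return Character vector of the five recognized labels.
#' @export
ride_modes <- function() {
  c("riding", "running", "crashing", "spectator", "unknown")
}
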