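# Symmetric 17-point skeleton template (COCO order: nose, eyes, ears,
# shoulders, elbows, wrists, hips, knees, ankles) in a unit-height box
# centered at the origin. Only the bbox geometry matters downstream; the
# template is built so its tight bounding box is exactly centered on the
# rider center, hence with zero noise the derived centers lie exactly on
# the motion polyline.
kp_template <- function() {
  t(matrix(c(
     0.00, -0.50,   # nose (top of box)
    -0.05, -0.47,  0.05, -0.47,   # eyes
    -0.10, -0.44,  0.10, -0.44,   # ears
    -0.22, -0.30,  0.22, -0.30,   # shoulders
    -0.30, -0.10,  0.30, -0.10,   # elbows (box x extent)
    -0.28,  0.05,  0.28,  0.05,   # wrists
    -0.15,  0.10,  0.15,  0.10,   # hips
    -0.17,  0.30,  0.17,  0.30,   # knees
    -0.15,  0.50,  0.15,  0.50    # ankles (bottom of box)
  ), nrow = 2L))
}

#' Describe a synthetic fence scene
#'
#' Builds the full description of a simulated scene: riders traversing the
#' fence along piecewise-linear paths at constant speed, with optional
#' per-keypoint Gaussian noise, random whole-detection dropouts, forced
#' dropout runs that provoke tracker re-identification failures, and
#' per-rider ride-mode schedules. Defaults describe the reference study
#' conditions: a 600 x 400 px fence filmed at 30 fps and analyzed at stride
#' 3, riders of bbox diagonal 100 px travelling left to right at 5 px per
#' video frame (15 px per analyzed frame, safely under the 25 px matching
#' gate).
#'
#' @param n_riders Number of riders (default 3).
#' @param fence A [fence()] (default 600 x 400 px at (100, 50), 30 fps,
#'   stride 3, left_to_right).
#' @param frame_size `(width, height)` of the synthetic video frame in
#'   pixels; all waypoints must lie inside.
#' @param speeds Pixels per original video frame, per rider (default 5).
#' @param lanes Rider lane coordinate transverse to travel (default evenly
#'   spaced, non-overlapping, inside the fence).
#' @param waypoints Optional list (per rider) of n x 2 waypoint matrices;
#'   defaults to a straight line through the fence along the travel axis at
#'   the rider's lane, starting and ending outside the fence.
#' @param start_frames First video frame at which each rider appears
#'   (default staggered by 12 frames).
#' @param diagonal Rider bbox diagonal in pixels (default 100).
#' @param noise_sd Gaussian keypoint noise, pixels (default 0).
#' @param dropout Probability a rider's detection is missing at an analyzed
#'   frame (default 0).
#' @param breaks Data frame with columns `rider`, `frame`, and optionally
#'   `len` (analyzed frames, default 2): forced dropout runs starting at the
#'   analyzed frame nearest `frame`. Each break makes the rider reappear
#'   more than one gate-width away, forcing a fresh tracker id.
#' @param mode_schedule List (per rider) of data frames `frame`, `mode`:
#'   the rider's ride mode from `frame` onward (default all `"riding"`).
#' @param teams Character vector of team names (default `"A"`, `"B"`,
#'   `"C"`, recycled across riders).
#' @param team_conf Probability mass the simulated jersey classifier puts on
#'   the true team before noise (default 0.8).
#' @param total_frames Length of the synthetic video (default: long enough
#'   for the slowest rider to leave the scene, plus a tail of empty frames
#'   that triggers finalization).
#' @param seed RNG seed stored with the scenario (default 1).
#' @return A list of class `"sim_scenario"`.
#' @export
sim_scenario <- function(n_riders = 3L,
                         fence = fencetrack::fence(100, 50, 700, 450,
                                                   "left_to_right",
                                                   fps = 30, frame_stride = 3L),
                         frame_size = c(1920, 1080),
                         speeds = rep(5, n_riders),
                         lanes = NULL,
                         waypoints = NULL,
                         start_frames = seq(0L, by = 12L,
                                            length.out = n_riders),
                         diagonal = 100,
                         noise_sd = 0,
                         dropout = 0,
                         breaks = NULL,
                         mode_schedule = NULL,
                         teams = c("A", "B", "C"),
                         team_conf = 0.8,
                         total_frames = NULL,
                         seed = 1L) {
  stopifnot(n_riders >= 1, all(speeds > 0), diagonal > 0,
            dropout >= 0, dropout < 1, noise_sd >= 0)
  speeds <- rep_len(speeds, n_riders)
  start_frames <- rep_len(as.integer(start_frames), n_riders)

  horiz <- fence$travel_axis %in% c("left_to_right", "right_to_left")
  if (is.null(lanes)) {
    lo <- if (horiz) fence$ymin else fence$xmin
    hi <- if (horiz) fence$ymax else fence$xmax
    lanes <- lo + (seq_len(n_riders) - 0.5) / n_riders * (hi - lo)
  }
  lanes <- rep_len(lanes, n_riders)

  if (is.null(waypoints)) {
    margin <- diagonal  # start/end clear of the fence so paths enter and exit
    waypoints <- lapply(seq_len(n_riders), function(r) {
      from_to <- switch(fence$travel_axis,
        left_to_right = c(fence$xmin - margin, fence$xmax + margin),
        right_to_left = c(fence$xmax + margin, fence$xmin - margin),
        top_to_bottom = c(fence$ymin - margin, fence$ymax + margin),
        bottom_to_top = c(fence$ymax + margin, fence$ymin - margin))
      if (horiz) rbind(c(from_to[1], lanes[r]), c(from_to[2], lanes[r]))
      else rbind(c(lanes[r], from_to[1]), c(lanes[r], from_to[2]))
    })
  }
  for (r in seq_len(n_riders)) {
    w <- waypoints[[r]]
    if (any(w[, 1] < 0 | w[, 1] > frame_size[1] |
            w[, 2] < 0 | w[, 2] > frame_size[2]))
      stop(sprintf("rider %d: waypoints outside frame bounds", r))
  }

  if (is.null(mode_schedule))
    mode_schedule <- replicate(n_riders,
                               data.frame(frame = 0L, mode = "riding"),
                               simplify = FALSE)
  if (is.null(total_frames)) {
    lens <- vapply(waypoints, function(w)
      sum(sqrt(rowSums(diff(w)^2))), numeric(1))
    # tail long enough for the 10-empty-frame finalize rule
    total_frames <- max(start_frames + ceiling(lens / speeds)) +
      20L * fence$frame_stride
  }

  structure(list(n_riders = n_riders, fence = fence,
                 frame_size = frame_size, speeds = speeds, lanes = lanes,
                 waypoints = waypoints, start_frames = start_frames,
                 diagonal = diagonal, noise_sd = noise_sd, dropout = dropout,
                 breaks = breaks, mode_schedule = mode_schedule,
                 teams = rep_len(teams, n_riders), team_names = unique(teams),
                 team_conf = team_conf,
                 total_frames = as.integer(total_frames), seed = seed),
            class = "sim_scenario")
}

# position of a rider at elapsed distance s along its waypoint polyline
polyline_pos <- function(w, s) {
  seg <- sqrt(rowSums(diff(w)^2))
  cum <- c(0, cumsum(seg))
  if (s >= cum[length(cum)]) return(w[nrow(w), ])
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  f <- (s - cum[i]) / seg[i]
  w[i, ] + f * (w[i + 1L, ] - w[i, ])
}

#' Simulate a fence scene with ground truth
#'
#' Generates the detection stream, annotations and ground truth for a
#' [sim_scenario()]. Rider centers are sampled at the analyzed frames
#' (every `frame_stride`-th video frame); each detection synthesizes 17
#' keypoints from a fixed body template scaled to the rider's bbox diagonal
#' plus i.i.d. Gaussian noise. Dropouts and injected break runs delete whole
#' detections. Output is reproducible: the same scenario and seed give
#' byte-identical results.
#'
#' @param scenario A `"sim_scenario"`.
#' @param seed Overrides the scenario's stored seed when given.
#' @return A list of class `"fence_scene"` with elements `detections`
#'   (a `"pose_detections"`), `annotations` (see [read_annotations()]),
#'   `truth` (list: `detections` data frame with a ground-truth `rider`
#'   column per emitted detection; `riders` data frame with per-rider true
#'   entry/exit analyzed frames inside the fence, analytic crossing time in
#'   seconds, major ride mode and team; `analyzed_frames`), and `scenario`.
#' @export
simulate_scene <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  sc <- scenario
  if (is.null(seed)) seed <- sc$seed
  set.seed(seed)
  fen <- sc$fence
  aframes <- sample_frames(sc$total_frames, fen$frame_stride)
  tmpl <- kp_template()
  # scale template so its bbox diagonal is exactly sc$diagonal
  tw <- diff(range(tmpl[, 1])); th <- diff(range(tmpl[, 2]))
  s <- sc$diagonal / sqrt(tw^2 + th^2)
  tmpl <- tmpl * s

  frames <- integer(0); riders <- integer(0)
  kps <- list()
  modes <- character(0)
  drop_runs <- vector("list", sc$n_riders)
  if (!is.null(sc$breaks) && nrow(sc$breaks)) {
    len <- if ("len" %in% names(sc$breaks)) sc$breaks$len else
      rep(2L, nrow(sc$breaks))
    for (i in seq_len(nrow(sc$breaks))) {
      r <- sc$breaks$rider[i]
      a0 <- which.min(abs(aframes - sc$breaks$frame[i]))
      drop_runs[[r]] <- c(drop_runs[[r]], seq.int(a0, a0 + len[i] - 1L))
    }
  }

  truth_rows <- list()
  for (r in seq_len(sc$n_riders)) {
    w <- sc$waypoints[[r]]
    plen <- sum(sqrt(rowSums(diff(w)^2)))
    end_frame <- sc$start_frames[r] + plen / sc$speeds[r]
    for (ai in seq_along(aframes)) {
      f <- aframes[ai]
      if (f < sc$start_frames[r] || f > end_frame) next
      if (ai %in% drop_runs[[r]]) next
      if (sc$dropout > 0 && stats::runif(1) < sc$dropout) next
      pos <- polyline_pos(w, (f - sc$start_frames[r]) * sc$speeds[r])
      kp <- sweep(tmpl, 2L, pos, "+")
      if (sc$noise_sd > 0)
        kp <- kp + matrix(stats::rnorm(34L, 0, sc$noise_sd), 17L, 2L)
      frames <- c(frames, f); riders <- c(riders, r)
      kps[[length(kps) + 1L]] <- cbind(kp, 1)
      sched <- sc$mode_schedule[[r]]
      modes <- c(modes,
                 sched$mode[max(which(sched$frame <= f))])
    }

    # ground truth from the noiseless continuous path
    centers <- t(vapply(aframes, function(f)
      if (f < sc$start_frames[r] || f > end_frame) c(NA_real_, NA_real_)
      else polyline_pos(w, (f - sc$start_frames[r]) * sc$speeds[r]),
      numeric(2)))
    ins <- which(!is.na(centers[, 1]) &
                   in_fence(centers[, 1], centers[, 2], fen))
    crossing <- analytic_crossing_s(sc, r)
    sched <- sc$mode_schedule[[r]]
    in_modes <- vapply(aframes[ins], function(f)
      sched$mode[max(which(sched$frame <= f))], character(1))
    truth_rows[[r]] <- data.frame(
      rider = r,
      entry_frame = if (length(ins)) aframes[min(ins)] else NA_integer_,
      exit_frame = if (length(ins)) aframes[max(ins)] else NA_integer_,
      crossing_s = crossing,
      major_mode = mode_majority(in_modes),
      team = sc$teams[r])
  }

  det <- pose_detections(frames, kps)
  truth_det <- data.frame(frame = frames, rider = riders)
  # align truth with the sorted detection table via the stable sort by frame
  o <- order(frames)
  truth_det <- truth_det[o, , drop = FALSE]
  truth_det$detection_ref <- det$detection_ref
  rownames(truth_det) <- NULL
  modes <- modes[o]

  ann <- data.frame(frame = det$frame, detection_ref = det$detection_ref,
                    ride_mode = modes)
  teams <- sc$team_names
  ann$team_probs <- lapply(seq_len(nrow(ann)), function(i) {
    true_team <- sc$teams[truth_det$rider[i]]
    p <- setNames(rep((1 - sc$team_conf) / max(1, length(teams) - 1),
                      length(teams)), teams)
    p[true_team] <- sc$team_conf
    if (length(teams) == 1L) p[] <- 1
    jitter <- abs(stats::rnorm(length(p), 0, 0.02))
    p <- p + jitter
    p / sum(p)
  })

  structure(list(detections = det, annotations = ann,
                 truth = list(detections = truth_det,
                              riders = do.call(rbind, truth_rows),
                              analyzed_frames = aframes),
                 scenario = sc),
            class = "fence_scene")
}

# continuous time (seconds) the rider's noiseless center spends inside the
# fence, from the polyline geometry
analytic_crossing_s <- function(sc, r) {
  w <- sc$waypoints[[r]]
  fen <- sc$fence
  # sample the continuous path finely and measure the inside arc length
  plen <- sum(sqrt(rowSums(diff(w)^2)))
  s <- seq(0, plen, length.out = 20000L)
  pos <- t(vapply(s, function(si) polyline_pos(w, si), numeric(2)))
  ins <- in_fence(pos[, 1], pos[, 2], fen)
  if (!any(ins)) return(0)
  arc_inside <- (sum(ins) / length(ins)) * plen
  arc_inside / sc$speeds[r] / fen$fps
}

#' @export
print.fence_scene <- function(x, ...) {
  cat(sprintf("<fence_scene> %d riders, %d detections over %d analyzed frames (seed %s)\n",
              x$scenario$n_riders, nrow(x$detections),
              length(x$truth$analyzed_frames), format(x$scenario$seed)))
  invisible(x)
}
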