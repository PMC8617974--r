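# Brute-force reference implementations, kept deliberately literal and
# independent of the package's vectorized code paths.

# Literal matcher: enumerate all (state, pose) pairs, keep those whose
# distance beats the gate and where the state is that pose's nearest one,
# then greedily take pairs in ascending (distance, track_id, pose index)
# order with mutual exclusivity.
oracle_match <- function(states, poses, match_frac = 0.25) {
  np <- nrow(poses)
  assign <- rep(NA_integer_, np)
  if (np == 0L || is.null(states) || nrow(states) == 0L) return(assign)
  pairs <- expand.grid(s = seq_len(nrow(states)), p = seq_len(np))
  pairs$d <- sqrt((states$cx[pairs$s] - poses$cx[pairs$p])^2 +
                  (states$cy[pairs$s] - poses$cy[pairs$p])^2)
  keep <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    p <- pairs$p[i]
    dp <- pairs$d[pairs$p == p]
    is_min <- pairs$d[i] == min(dp)
    if (is_min) {
      # among tied nearest states, only the lowest track_id is eligible
      tied <- pairs[pairs$p == p & pairs$d == min(dp), ]
      is_min <- states$track_id[pairs$s[i]] == min(states$track_id[tied$s])
    }
    keep[i] <- is_min && pairs$d[i] < match_frac * poses$diagonal[p]
  }
  pairs <- pairs[keep, , drop = FALSE]
  pairs <- pairs[order(pairs$d, states$track_id[pairs$s], pairs$p), ,
                 drop = FALSE]
  used_s <- logical(nrow(states)); used_p <- logical(np)
  for (i in seq_len(nrow(pairs))) {
    s <- pairs$s[i]; p <- pairs$p[i]
    if (!used_s[s] && !used_p[p]) {
      used_s[s] <- TRUE; used_p[p] <- TRUE
      assign[p] <- states$track_id[s]
    }
  }
  assign
}

# Brute-force whole-sequence tracker: replays the stated rules frame by
# frame using oracle_match and a naive memory list.
oracle_track <- function(det, analyzed_frames, match_frac = 0.25,
                         memory_frames = 5L) {
  det <- det[order(det$frame), , drop = FALSE]
  det$track_id <- NA_integer_
  states <- NULL
  nid <- 1L
  for (a in seq_along(analyzed_frames)) {
    if (!is.null(states))
      states <- states[a - states$last_aframe <= memory_frames, , drop = FALSE]
    rows <- which(det$frame == analyzed_frames[a])
    if (!length(rows)) next
    poses <- det[rows, , drop = FALSE]
    asg <- oracle_match(states, poses, match_frac)
    for (j in seq_along(rows)) {
      if (is.na(asg[j])) {
        asg[j] <- nid; nid <- nid + 1L
        states <- rbind(states, data.frame(track_id = asg[j],
                                           cx = poses$cx[j],
                                           cy = poses$cy[j], last_aframe = a))
      } else {
        k <- which(states$track_id == asg[j])
        states$cx[k] <- poses$cx[j]; states$cy[k] <- poses$cy[j]
        states$last_aframe[k] <- a
      }
    }
    det$track_id[rows] <- asg
  }
  det
}

# Naive consecutive-run finder over a sorted integer vector: returns run ids.
oracle_runs <- function(v) {
  if (!length(v)) return(integer(0))
  run <- 1L
  out <- integer(length(v))
  out[1] <- run
  for (i in seq_along(v)[-1]) {
    if (v[i] != v[i - 1] + 1L) run <- run + 1L
    out[i] <- run
  }
  out
}

# Naive finalize scanner: event at the k-th consecutive empty frame of each
# empty run.
oracle_finalize <- function(n_inside, frames, k) {
  trig <- integer(0)
  i <- 1L
  while (i <= length(n_inside)) {
    if (n_inside[i] == 0L) {
      j <- i
      while (j <= length(n_inside) && n_inside[j] == 0L) j <- j + 1L
      if (j - i >= k) trig <- c(trig, frames[i + k - 1L])
      i <- j
    } else i <- i + 1L
  }
  trig
}

# Independent homography fit: no normalization, eliminate the scale by
# fixing h33 = 1 and solving the 8-unknown least-squares system directly.
oracle_homography <- function(image, world) {
  n <- nrow(image)
  A <- matrix(0, 2L * n, 8L)
  b <- numeric(2L * n)
  for (i in seq_len(n)) {
    x <- image[i, 1]; y <- image[i, 2]
    u <- world[i, 1]; v <- world[i, 2]
    A[2 * i - 1L, ] <- c(x, y, 1, 0, 0, 0, -u * x, -u * y)
    A[2 * i, ]      <- c(0, 0, 0, x, y, 1, -v * x, -v * y)
    b[2 * i - 1L] <- u
    b[2 * i] <- v
  }
  h <- qr.solve(A, b)
  matrix(c(h, 1), 3L, 3L, byrow = TRUE)
}

# Cross-ratio of four collinear points given as distances along the line.
cross_ratio <- function(t) {
  ((t[3] - t[1]) * (t[4] - t[2])) / ((t[3] - t[2]) * (t[4] - t[1]))
}

random_poses <- function(n, diag_range = c(50, 150)) {
  data.frame(cx = runif(n, 0, 1000), cy = runif(n, 0, 1000),
             diagonal = runif(n, diag_range[1], diag_range[2]))
}

random_states <- function(n) {
  data.frame(track_id = sample.int(1000L, n), cx = runif(n, 0, 1000),
             cy = runif(n, 0, 1000),
             last_aframe = sample.int(50L, n, replace = TRUE))
}

default_config <- function(...) {
  as_fencetrack_config(utils::modifyList(
    list(fence = list(xmin = 100, ymin = 50, xmax = 700, ymax = 450,
                      fps = 30, frame_stride = 3)),
    list(...)))
}
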