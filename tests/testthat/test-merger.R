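make_track_set <- function(df, analyzed_frames = NULL) {
  track_sequence(df, analyzed_frames = analyzed_frames)
}

# build a track_fragments object directly from a detection table that
# already carries track ids, bypassing the tracker
frags_from <- function(df, analyzed_frames = sort(unique(df$frame))) {
  df$aframe <- match(df$frame, analyzed_frames)
  structure(df, class = c("track_set", "data.frame"),
            analyzed_frames = analyzed_frames) |> split_on_gaps()
}

test_that("tracks split exactly at analyzed-frame jumps", {
  one <- data.frame(frame = 1:10, cx = 1:10, cy = 0, diagonal = 100,
                    track_id = 1L)
  f1 <- frags_from(one, analyzed_frames = 1:10)
  expect_equal(nrow(attr(f1, "fragments")), 1L)

  gap <- data.frame(frame = c(1:5, 9:12), cx = 1, cy = 0, diagonal = 100,
                    track_id = 1L)
  f2 <- frags_from(gap, analyzed_frames = 1:12)
  s <- attr(f2, "fragments")
  expect_equal(nrow(s), 2L)
  expect_equal(s$start_aframe, c(1L, 9L))
  expect_equal(s$end_aframe, c(5L, 12L))
})

test_that("fragment boundaries equal a run-length oracle on random gaps", {
  set.seed(42)
  for (rep in 1:50) {
    af <- sort(sample(1:60, sample(5:40, 1)))
    df <- data.frame(frame = af, cx = runif(length(af)), cy = 0,
                     diagonal = 100, track_id = 1L)
    f <- frags_from(df, analyzed_frames = 1:60)
    expect_equal(f$fragment_id, oracle_runs(af))
  }
})

test_that("spatiotemporal weight adds pixel gap and weighted frame gap", {
  a <- list(end_aframe = 10L, end_cx = 100, end_cy = 50)
  b <- list(start_aframe = 11L, start_cx = 100, start_cy = 50)
  expect_equal(st_distance(a, b, lambda_t = 2), 2)
  b2 <- list(start_aframe = 12L, start_cx = 103, start_cy = 54)
  expect_equal(st_distance(a, b2, lambda_t = 2), 9)  # 3-4-5 + 2 frames
  # time-order violation is infeasible, and only one direction is feasible
  a2 <- list(end_aframe = 5L, end_cx = 0, end_cy = 0,
             start_aframe = 1L, start_cx = 0, start_cy = 0)
  b3 <- list(start_aframe = 8L, start_cx = 0, start_cy = 0,
             end_aframe = 9L, end_cx = 0, end_cy = 0)
  expect_equal(st_distance(b3, a2, 2), Inf)
  expect_lt(st_distance(a2, b3, 2), Inf)
})

test_that("two fragments within threshold merge into one path", {
  df <- data.frame(frame = c(1:5, 8:12),
                   cx = c(1:5, 8:12) * 5, cy = 100, diagonal = 100,
                   track_id = c(rep(1L, 5), rep(2L, 5)))
  f <- frags_from(df, analyzed_frames = 1:12)
  m <- merge_fragments(f, threshold = 50, lambda_t = 2)
  expect_equal(length(attr(m, "lineage")), 1L)
  expect_equal(attr(m, "lineage")[[1]], c(1L, 2L))
  # below the gap weight, no merge happens
  m2 <- merge_fragments(f, threshold = 10, lambda_t = 2)
  expect_equal(length(attr(m2, "lineage")), 2L)
})

test_that("co-temporal fragments never merge", {
  df <- data.frame(frame = rep(1:5, 2), cx = rep(c(0, 300), each = 5),
                   cy = 100, diagonal = 100,
                   track_id = rep(1:2, each = 5))
  f <- frags_from(df, analyzed_frames = 1:5)
  m <- merge_fragments(f, threshold = 1e6, lambda_t = 1)
  expect_equal(length(attr(m, "lineage")), 2L)
  # frame lists of fragments within each path are pairwise disjoint
  for (chain in attr(m, "lineage")) {
    fsets <- lapply(chain, function(id) f$aframe[f$fragment_id == id])
    if (length(fsets) > 1)
      for (i in seq_along(fsets)[-1])
        expect_length(intersect(fsets[[i - 1]], fsets[[i]]), 0)
  }
})

test_that("direction reversals beyond tolerance are not merged", {
  fen <- fence(0, 0, 600, 400, "left_to_right", fps = 30)
  # second fragment restarts 200 px backwards: a 33% reversal of the extent
  df <- data.frame(frame = c(1:5, 8:12),
                   cx = c(seq(300, 340, 10), seq(140, 180, 10)), cy = 100,
                   diagonal = 100, track_id = c(rep(1L, 5), rep(2L, 5)))
  f <- frags_from(df, analyzed_frames = 1:12)
  m <- merge_fragments(f, threshold = 1e6, lambda_t = 1, fence = fen)
  expect_equal(length(attr(m, "lineage")), 2L)
  # a small backward jitter within tolerance is accepted
  df$cx[6:10] <- seq(320, 360, 10)  # 20 px back: 3.3% of extent
  f2 <- frags_from(df, analyzed_frames = 1:12)
  m2 <- merge_fragments(f2, threshold = 1e6, lambda_t = 1, fence = fen)
  expect_equal(length(attr(m2, "lineage")), 1L)
})

test_that("merging partitions fragments and is idempotent", {
  set.seed(9)
  scene <- simulate_scene(sim_scenario(
    n_riders = 3, noise_sd = 1, dropout = 0.08, seed = 77))
  tr <- track_sequence(scene$detections,
                       analyzed_frames = scene$truth$analyzed_frames)
  f <- split_on_gaps(tr)
  m <- merge_fragments(f, fence = scene$scenario$fence)
  lin <- attr(m, "lineage")
  # every fragment in exactly one path
  expect_equal(sort(unlist(lin)), sort(attr(f, "fragments")$fragment_id))
  # detections conserved
  expect_equal(nrow(m), nrow(scene$detections))
  expect_false(any(is.na(m$path_id)))
  # idempotence: re-running split+merge on the merged result, with path ids
  # as track ids, changes nothing
  redo <- as.data.frame(m)
  redo$track_id <- redo$path_id
  f2 <- frags_from(redo[, c("frame", "cx", "cy", "diagonal", "track_id")],
                   analyzed_frames = scene$truth$analyzed_frames)
  m2 <- merge_fragments(f2, fence = scene$scenario$fence)
  key <- function(x) x[order(x$frame, x$cx), c("frame", "cx", "cy")]
  expect_equal(length(attr(m2, "lineage")), length(lin))
  for (pid in unique(m$path_id))
    expect_equal(key(as.data.frame(m2)[m2$path_id == pid, ]),
                 key(as.data.frame(m)[m$path_id == pid, ]),
                 ignore_attr = TRUE)
})

test_that("injected identity breaks are fully repaired at zero noise", {
  breaks <- data.frame(rider = c(1L, 2L, 3L, 1L),
                       frame = c(60L, 75L, 90L, 105L))
  scene <- simulate_scene(sim_scenario(
    n_riders = 3, noise_sd = 0, dropout = 0, breaks = breaks, seed = 21))
  tr <- track_sequence(scene$detections,
                       analyzed_frames = scene$truth$analyzed_frames)
  expect_gt(length(unique(tr$track_id)), 3L)  # the breaks did fragment
  f <- split_on_gaps(tr)
  m <- merge_fragments(f, fence = scene$scenario$fence)
  expect_equal(length(attr(m, "lineage")), 3L)
  joined <- merge(as.data.frame(m)[, c("frame", "detection_ref", "path_id")],
                  scene$truth$detections)
  tab <- table(joined$path_id, joined$rider)
  expect_equal(sum(tab > 0), 3L)          # each path is one rider
  expect_equal(sum(tab), nrow(scene$detections))  # 100% recovery
})

test_that("recovery degrades monotonically as the threshold shrinks below the gap weight", {
  breaks <- data.frame(rider = c(1L, 2L, 3L), frame = c(60L, 75L, 90L))
  scene <- simulate_scene(sim_scenario(
    n_riders = 3, noise_sd = 0, dropout = 0, breaks = breaks, seed = 33))
  tr <- track_sequence(scene$detections,
                       analyzed_frames = scene$truth$analyzed_frames)
  f <- split_on_gaps(tr)
  n_paths <- vapply(c(200, 60, 10), function(th)
    length(attr(merge_fragments(f, threshold = th, lambda_t = 10), "lineage")),
    numeric(1))
  # break weight here is 3 * 15 px spatial + 10 * 3 temporal = 75 px
  expect_equal(n_paths[1], 3)   # threshold above the injected gap weight
  expect_true(all(diff(n_paths) >= 0))  # shrinking threshold never helps
  expect_equal(n_paths[3], 6)   # below every gap weight nothing merges
})
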