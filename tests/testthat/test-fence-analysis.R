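fen <- fence(0, 0, 100, 100, "left_to_right", fps = 30, frame_stride = 3)

test_that("fence membership uses the half-open rectangle", {
  expect_true(in_fence(50, 50, fen))
  expect_false(in_fence(100, 50, fen))  # right edge excluded
  expect_true(in_fence(0, 0, fen))      # left edge included
  set.seed(13)
  cx <- runif(1000, -20, 120); cy <- runif(1000, -20, 120)
  brute <- cx >= 0 & cx < 100 & cy >= 0 & cy < 100
  expect_equal(in_fence(cx, cy, fen), brute)
})

paths_df <- function(cxs, frames = seq(0, by = 3, length.out = length(cxs)),
                     pid = 1L) {
  data.frame(frame = frames, cx = cxs, cy = 50, diagonal = 100,
             path_id = pid, detection_ref = 1L)
}

test_that("valid paths must enter and exit with enough inside detections", {
  # entirely outside
  p1 <- paths_df(seq(200, 300, by = 10))
  expect_length(extract_valid_paths(p1, fen), 0)
  # outside -> 5 inside -> outside
  p2 <- paths_df(c(-10, 10, 30, 50, 70, 90, 110))
  got <- extract_valid_paths(p2, fen)
  expect_length(got, 1)
  expect_equal(got[[1]]$entry_frame, 3)
  expect_equal(got[[1]]$exit_frame, 15)
  expect_equal(got[[1]]$duration_s, 12 / 30)
  expect_equal(got[[1]]$crossing_s, 12 / 30 + 3 / 30)
  # enters but the stream ends inside: excluded, reported incomplete
  p3 <- paths_df(c(-10, 10, 30, 50))
  got3 <- extract_valid_paths(p3, fen)
  expect_length(got3, 0)
  expect_equal(attr(got3, "incomplete"), 1L)
  # only one detection inside: below min_inside
  p4 <- paths_df(c(-10, 50, 110))
  expect_length(extract_valid_paths(p4, fen), 0)
})

test_that("dwell time is frame difference over fps", {
  expect_equal(dwell_time(30, 120, 30), 3)
  expect_equal(dwell_time(17, 17, 25), 0)
  expect_error(dwell_time(10, 5, 30), "exit_frame")
  expect_error(dwell_time(0, 10, 0), "fps")
})

test_that("finalize fires at the n-th consecutive empty analyzed frame", {
  frames <- seq(0, by = 3, length.out = 20)
  occ <- data.frame(frame = frames,
                    n_inside = c(rep(0, 9), 1, rep(0, 10)))
  ev <- finalize_trigger(occ, empty_needed = 10)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$trigger_frame, frames[20])
  # fully occupied: no events
  expect_equal(nrow(finalize_trigger(
    data.frame(frame = frames, n_inside = 1), 10)), 0L)
  # a long empty run triggers once, not repeatedly
  ev2 <- finalize_trigger(data.frame(frame = frames, n_inside = 0), 10)
  expect_equal(ev2$trigger_frame, frames[10])
})

test_that("finalize equals the brute-force run scanner on random occupancy", {
  set.seed(4)
  for (rep in 1:200) {
    n <- sample(5:80, 1)
    occ <- data.frame(frame = seq_len(n) * 3L,
                      n_inside = rbinom(n, 1, 0.5))
    k <- sample(1:12, 1)
    expect_equal(finalize_trigger(occ, k)$trigger_frame,
                 oracle_finalize(occ$n_inside, occ$frame, k))
  }
})

test_that("metadata summary takes the modal mode with priority tie-break", {
  m <- summarize_metadata(c("riding", "riding", "running"), list(), fen)
  expect_equal(m$major_mode, "riding")
  expect_equal(m$mode_breakdown[["riding"]], 2 * 0.1)
  expect_equal(m$mode_breakdown[["running"]], 1 * 0.1)
  # 50/50 tie resolves to riding
  expect_equal(summarize_metadata(c("running", "riding"), list(),
                                  fen)$major_mode, "riding")
  expect_equal(summarize_metadata(c("crashing", "spectator"), list(),
                                  fen)$major_mode, "crashing")
  # no annotations at all
  m0 <- summarize_metadata(character(0), list(), fen)
  expect_equal(m0$major_mode, "unknown")
  expect_length(m0$mode_breakdown, 0)
})

test_that("team scores aggregate probability vectors", {
  probs <- list(c(A = 0.8, B = 0.2), c(A = 0.4, B = 0.6), NULL)
  m <- summarize_metadata(c("riding", "riding", "riding"), probs, fen)
  expect_equal(m$team_scores, c(A = 0.6, B = 0.4))
  mx <- summarize_metadata(c("riding"), probs, fen, aggregation = "max")
  expect_equal(unname(mx$team_scores), c(0.8, 0.6) / 1.4)
})

test_that("mode breakdown never exceeds the dwell plus one frame period", {
  scene <- simulate_scene(sim_scenario(
    n_riders = 2, noise_sd = 1, dropout = 0.05,
    mode_schedule = list(data.frame(frame = c(0L, 60L), mode = c("riding", "running")),
                         data.frame(frame = 0L, mode = "riding")),
    seed = 14))
  cfg <- default_config()
  rep <- run_pipeline(scene$detections, cfg, annotations = scene$annotations,
                      verbose = FALSE)
  for (p in attr(rep, "fence_paths")) {
    total <- sum(unlist(p$mode_breakdown))
    period <- cfg$fence$frame_stride / cfg$fence$fps
    expect_lte(total, p$duration_s + period + 1e-9)
  }
})

test_that("crossing counts match ground truth on randomized scenarios", {
  set.seed(202)
  fenbig <- fence(100, 50, 700, 450, "left_to_right", fps = 30,
                  frame_stride = 3)
  for (rep in 1:25) {
    n <- sample(1:4, 1)
    # some riders never reach the fence, some end inside it
    kinds <- sample(c("cross", "never", "end_inside"), n, replace = TRUE)
    wps <- lapply(kinds, function(k) {
      lane <- runif(1, 100, 400)
      switch(k,
             cross = rbind(c(0, lane), c(800, lane)),
             never = rbind(c(0, lane), c(60, lane)),
             end_inside = rbind(c(0, lane), c(400, lane)))
    })
    sc <- sim_scenario(n_riders = n, fence = fenbig, waypoints = wps,
                       lanes = rep(250, n), noise_sd = 0,
                       start_frames = seq(0, by = 30, length.out = n),
                       seed = sample.int(1e6, 1))
    scene <- simulate_scene(sc)
    tr <- track_sequence(scene$detections,
                         analyzed_frames = scene$truth$analyzed_frames)
    m <- merge_fragments(split_on_gaps(tr), fence = fenbig)
    got <- extract_valid_paths(m, fenbig)
    expect_equal(length(got), sum(kinds == "cross"))
    expect_equal(length(attr(got, "incomplete")), sum(kinds == "end_inside"))
  }
})
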