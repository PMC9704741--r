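# The per-attempt operators and the 25-indicator extraction.

cfg <- indicator_config()

test_that("indicator config validates its parameters", {
  expect_error(indicator_config(catch_radius_m = 0), "positive")
  expect_error(indicator_config(smoothing_window_frames = 4), "odd")
})

test_that("range crossings count hand-traced band entries", {
  # 1-D path: out, in, out, in (crosses the +/-0.12 band around x = 0)
  path <- make_path(t = 0:5, x = c(0.5, 0.05, 0.05, 0.5, 0.05, 0.05))
  a <- make_attempt(t_spawn = 0, t_apex = 2, t_end = 5, window_end = 5)
  rc <- range_crossings(path, a, cfg, "horizontal")
  expect_equal(rc$n_entries, 2L)
  expect_equal(rc$first_entry, 1)
  expect_equal(rc$last_entry, 4)

  # inside for the whole window: one entry at time zero
  inside <- make_path(t = 0:5, x = rep(0.01, 6))
  rc2 <- range_crossings(inside, a, cfg, "horizontal")
  expect_equal(rc2$n_entries, 1L)
  expect_equal(rc2$first_entry, 0)

  # never inside
  outside <- make_path(t = 0:5, x = rep(2, 6))
  rc3 <- range_crossings(outside, a, cfg, "full3d")
  expect_equal(rc3$n_entries, 0L)
  expect_true(is.na(rc3$first_entry) && is.na(rc3$last_entry))
})

test_that("aiming time is the first post-apex range entry", {
  a <- make_attempt(t_spawn = 0, t_apex = 2, t_end = 5, window_end = 5)
  # enters the band 0.4 s after the apex
  path <- make_path(t = seq(0, 5, 0.1),
                    x = ifelse(seq(0, 5, 0.1) >= 2.4, 0.0, 1.0))
  expect_equal(aiming_time(path, a, cfg, "horizontal"), 0.4)
  # already in range exactly at the apex
  path0 <- make_path(t = seq(0, 5, 0.1), x = 0)
  expect_equal(aiming_time(path0, a, cfg, "horizontal"), 0)
  # in range only before the apex
  pre_only <- make_path(t = seq(0, 5, 0.1),
                        x = ifelse(seq(0, 5, 0.1) < 1.5, 0.0, 1.0))
  expect_true(is.na(aiming_time(pre_only, a, cfg, "horizontal")))
})

test_that("stabilization-to-catch finds the parked interval before the catch", {
  tt <- seq(0, 3, by = 0.05)
  # hand sweeps in and parks at the target from t = 2.0; catch at t = 3
  x <- ifelse(tt < 2, 1 - tt / 2, 0)
  path <- make_path(t = tt, x = x)
  a <- make_attempt(t_spawn = 0, t_apex = 1, t_end = 3, window_end = 3,
                    outcome = "success")
  lenient <- indicator_config(stabilization_speed_mps = 0.05,
                              stabilization_dwell_s = 0.1,
                              smoothing_window_frames = 1L)
  expect_equal(stabilization_to_catch(path, a, lenient, "horizontal"), 1,
               tolerance = 1e-9)
  # a failed attempt is always missing
  a_fail <- make_attempt(outcome = "fail", t_end = 3, window_end = 3)
  expect_true(is.na(stabilization_to_catch(path, a_fail, lenient,
                                           "horizontal")))
  # speed never below threshold
  fast <- make_path(t = tt, x = sin(10 * tt) * 0.05)
  strict <- indicator_config(stabilization_speed_mps = 1e-6,
                             smoothing_window_frames = 1L)
  expect_true(is.na(stabilization_to_catch(fast, a, strict, "horizontal")))
  # dwell longer than the whole window
  long_dwell <- indicator_config(stabilization_dwell_s = 10,
                                 smoothing_window_frames = 1L)
  expect_true(is.na(stabilization_to_catch(path, a, long_dwell,
                                           "horizontal")))
})

test_that("speed statistics follow the max/mean/population-sigma definitions", {
  expect_equal(as.numeric(speed_stats(c(2, 2, 2))), c(2, 2, 0))
  expect_equal(as.numeric(speed_stats(c(1, 3))), c(3, 2, 1))
  v <- runif(50)
  s1 <- speed_stats(v)
  s2 <- speed_stats(sample(v))
  expect_equal(s1$sigma, s2$sigma)  # permutation-invariant
  expect_true(all(is.na(speed_stats(numeric(0)))))
})

test_that("movement ratio guards its denominator", {
  expect_equal(movement_ratio(10, 5), 2)
  expect_equal(movement_ratio(7, 7), 1)
  expect_warning(r <- movement_ratio(1, 0), "undefined")
  expect_true(is.na(r))
})

test_that("path length matches analytic and brute-force values", {
  still <- make_path(t = 0:10, x = rep(1, 11))
  expect_equal(path_length(still), 0)
  # unit-speed straight line for 3 s (no smoothing: edge windows of the
  # moving average would pull the endpoints inward)
  raw1 <- indicator_config(smoothing_window_frames = 1L)
  line <- make_path(t = seq(0, 3, 0.1), x = seq(0, 3, 0.1))
  expect_equal(path_length(line, raw1), 3, tolerance = 1e-12)
  # random walks vs plain segment sums (no smoothing)
  raw_cfg <- indicator_config(smoothing_window_frames = 1L)
  set.seed(8)
  for (i in 1:10) {
    n <- sample(5:40, 1)
    p <- tibble::tibble(t = seq_len(n), x = cumsum(rnorm(n)),
                        y = cumsum(rnorm(n)), z = cumsum(rnorm(n)))
    manual <- sum(sqrt(diff(p$x)^2 + diff(p$y)^2 + diff(p$z)^2))
    expect_equal(path_length(p, raw_cfg), manual, tolerance = 1e-12)
  }
})

test_that("extension extents are per-axis, non-negative and rest-relative", {
  tt <- seq(0, 1, 0.1)
  p <- tibble::tibble(t = tt, x = rep(2, 11), y = 2 + sin(pi * tt),
                      z = rep(5, 11))
  e <- extension_extents(p)
  expect_equal(e$max_x, 0)
  expect_equal(e$max_y, max(abs(sin(pi * tt))))
  expect_equal(e$max_z, 0)
  expect_true(all(as.numeric(e) >= 0))
  e2 <- extension_extents(p, rest_pose = c(0, 0, 0))
  expect_equal(e2$max_x, 2)
})

test_that("segmentation conserves attempts, alternates hands, nails the apex", {
  set.seed(12)
  rec <- simulate_session("s01", "pre", 0.2,
                          task_settings(target_catches = 10L))
  att <- segment_attempts(rec)
  expect_equal(nrow(att), 10L)
  expect_true(all(att$catching_hand == rep(c("right", "left"), 5)))
  tr <- attr(rec, "truth")
  # apex within one frame of the closed-form apex time
  expect_true(all(abs(att$t_apex - tr$t_apex) <= 1 / 30 + 1e-9))
  expect_true(all(abs(att$t_launch - tr$t_launch) <= 1 / 30 + 1e-9))
  expect_equal(att$outcome == "success", tr$success)
  # attempt ordering invariants
  expect_true(all(att$t_spawn <= att$t_launch))
  expect_true(all(att$t_launch < att$t_apex))
  expect_true(all(att$t_apex < att$t_end))
  # a session with no flight gives an empty table, not an error
  idle <- make_session(make_frames(c(0, 1 / 30, 2 / 30)))
  expect_equal(nrow(segment_attempts(idle)), 0L)
})

test_that("mirrored sessions give identical indicator vectors", {
  set.seed(13)
  rec <- simulate_session("s01", "pre", 0.4,
                          task_settings(target_catches = 4L,
                                        affected_side = "right"))
  fr <- rec$frames
  mir <- fr
  mir$lh_x <- -fr$rh_x
  mir$lh_y <- fr$rh_y
  mir$lh_z <- fr$rh_z
  mir$rh_x <- -fr$lh_x
  mir$rh_y <- fr$lh_y
  mir$rh_z <- fr$lh_z
  mir$ball_x <- -fr$ball_x
  rec_m <- vr_session("s01", "pre",
                      task_settings(target_catches = 4L,
                                    affected_side = "left"),
                      mir, rec$sample_rate_hz)
  i1 <- suppressWarnings(extract_indicators(rec))
  i2 <- suppressWarnings(extract_indicators(rec_m))
  expect_equal(as.numeric(i1[, indicator_names()]),
               as.numeric(i2[, indicator_names()]), tolerance = 1e-12)
})

test_that("doubling all positions doubles distances and speeds only", {
  set.seed(14)
  rec <- simulate_session("s01", "pre", 0.2,
                          task_settings(target_catches = 3L))
  fr2 <- rec$frames
  pos_cols <- setdiff(names(fr2), c("t", "ball_state"))
  for (cl in pos_cols) fr2[[cl]] <- 2 * fr2[[cl]]
  rec2 <- vr_session(rec$subject_id, rec$timepoint, rec$settings, fr2,
                     rec$sample_rate_hz)
  p1 <- hand_path(rec, "affected")
  p2 <- hand_path(rec2, "affected")
  expect_equal(path_length(p2), 2 * path_length(p1), tolerance = 1e-9)
  expect_equal(speed_series(p2)$v, 2 * speed_series(p1)$v,
               tolerance = 1e-9)
  expect_equal(as.numeric(extension_extents(p2)),
               2 * as.numeric(extension_extents(p1)), tolerance = 1e-9)
  # event times are position-scale free
  a1 <- segment_attempts(rec)
  a2 <- segment_attempts(rec2)
  expect_equal(a2$t_apex, a1$t_apex)
  expect_equal(a2$t_end, a1$t_end)
})

test_that("the ideal subject enters the range once per attempt", {
  set.seed(15)
  rec <- simulate_session("s01", "pre", 0,
                          task_settings(target_catches = 6L))
  ind <- extract_indicators(rec)
  expect_equal(ind$hmi_6, 1)
  expect_equal(ind$vmi_6, 1)
  expect_equal(ind$n_attempts_used, 3L)
})

test_that("a session without affected-hand attempts is all-missing with a warning", {
  set.seed(16)
  rec <- simulate_session("s01", "pre", 0.1,
                          task_settings(target_catches = 2L))
  # restrict frames to end before the affected (right) hand's attempt
  tr <- attr(rec, "truth")
  # right hand catches attempt 1: drop it by relabelling affected side
  one <- simulate_session("s01", "pre", 0.1,
                          task_settings(target_catches = 1L,
                                        affected_side = "left"))
  # single attempt is caught by the right hand; affected left never catches
  expect_warning(ind <- extract_indicators(one), "no affected-hand")
  expect_true(all(is.na(as.numeric(ind[, indicator_names()]))))
})
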