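# Ball physics, arm controller, scale generator and cohort reproducibility.

test_that("projectile apex matches the closed form v_y0 / g_eff", {
  s <- task_settings(gravity_fraction = 1 / 9)
  g <- 9.81 / 9
  # choose the apex height so the launch vertical speed is 1.09 m/s
  h <- 1.09^2 / (2 * g)
  fl <- simulate_ball_flight(s, c(-0.15, 1.2, 0.45), c(0.15, 1.2, 0.45),
                             apex_height = h)
  expect_equal(attr(fl, "v0")[2], 1.09, tolerance = 1e-12)
  expect_equal(attr(fl, "t_apex"), 1.09 / g, tolerance = 1e-12)
  expect_equal(attr(fl, "t_apex"), 1.0, tolerance = 1e-9)
})

test_that("symmetric endpoints put the apex midway and at the set height", {
  s <- task_settings(gravity_fraction = 2 / 9)
  fl <- simulate_ball_flight(s, c(-0.2, 1.2, 0.45), c(0.2, 1.2, 0.45),
                             apex_height = 0.21, dt = 1e-4)
  i <- which.max(fl$y)
  expect_equal(fl$x[i], 0, tolerance = 1e-3)
  expect_equal(max(fl$y), 1.2 + 0.21, tolerance = 1e-6)
  # whole path obeys the kinematic closed form to 1e-9
  g <- 2 / 9 * 9.81
  v0 <- attr(fl, "v0")
  expect_equal(fl$y, 1.2 + v0[2] * fl$t - 0.5 * g * fl$t^2,
               tolerance = 1e-9)
  expect_equal(fl$x, -0.2 + v0[1] * fl$t, tolerance = 1e-9)
  expect_error(simulate_ball_flight(s, c(0, 1.2, 0.45), c(0, 1.2, 0.45)),
               "separation")
})

test_that("an ideal controller catches everything; insufficient reach never does", {
  set.seed(1)
  ideal <- impairment_profile(0)
  ideal$reaction_delay_s <- 0.02
  ideal$max_hand_speed_mps <- 50
  att <- list(t_apex = 1, t_end = 1.6, target_center = c(0.1, 1.2, 0.45))
  for (i in 1:20) {
    plan <- simulate_arm(att, ideal, rest_pose = c(0.3, 1, 0.3))
    expect_true(plan$success)
  }
  weak <- impairment_profile(1)
  weak$reach_fraction <- 0.1  # below the lower range fraction
  for (i in 1:20) {
    plan <- simulate_arm(att, weak, rest_pose = c(0.3, 1, 0.3))
    expect_false(plan$success)
  }
})

test_that("mean aiming time matches reaction delay plus transit time", {
  set.seed(2)
  prof <- impairment_profile(0.3)
  rest <- c(0.3, 1, 0.3)
  target <- c(0.12, 1.2, 0.45)
  att <- list(t_apex = 1, t_end = 1.62, target_center = target)
  cfg <- indicator_config()
  aims <- replicate(200, {
    plan <- simulate_arm(att, prof, rest_pose = rest)
    path <- arm_trajectory(plan, seq(0, 3, by = 1 / 30))
    a <- make_attempt(t_spawn = 0, t_apex = 1, t_end = 1.62,
                      window_end = 3, target = target)
    aiming_time(path, a, cfg, "full3d")
  })
  dist <- sqrt(sum((target + c(0, -0.05 * 0.3, 0) - rest)^2))
  transit_to_entry <- (dist - cfg$catch_radius_m) /
    (0.8 * prof$max_hand_speed_mps)
  expected <- prof$reaction_delay_s + transit_to_entry
  # frame quantisation adds up to one frame; Monte-Carlo error ~ sd/sqrt(200)
  expect_equal(mean(aims), expected, tolerance = 0.05)
})

test_that("scale triples respect ranges, endpoints and monotonicity", {
  set.seed(3)
  no_noise <- c(0, 0, 0)
  s0 <- simulate_scales(0, noise_sd = no_noise)
  expect_equal(c(s0$fma, s0$tempa, s0$wmft), c(22, 27, 5))
  s1 <- simulate_scales(1, noise_sd = no_noise)
  expect_equal(c(s1$fma, s1$tempa, s1$wmft), c(0, 0, 0))
  expect_error(simulate_scales(1.2), "theta")

  th <- runif(100)
  fma <- vapply(th, function(t) simulate_scales(t)$fma, numeric(1))
  expect_lt(cor(th, fma, method = "spearman"), -0.9)
})

test_that("fixed seeds reproduce cohorts exactly, including written bytes", {
  spec <- cohort_spec(n_subjects = 3,
                      settings = task_settings(target_catches = 3L),
                      seed = 9)
  c1 <- simulate_cohort(spec)
  c2 <- simulate_cohort(spec)
  expect_identical(c1$scales, c2$scales)
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$sessions[[1]]$frames, c2$sessions[[1]]$frames)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(c1, d1)
  write_cohort(c2, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7),
                     label = f)
  }
})

test_that("post-timepoint severities improve and Wilcoxon detects FMA gains", {
  set.seed(4)
  # retention in (0,1) means theta can only improve
  coh <- simulate_cohort(cohort_spec(seed = 21), sessions = FALSE)
  wide <- tidyr::pivot_wider(coh$truth[, c("subject", "timepoint", "theta")],
                             names_from = "timepoint",
                             values_from = "theta")
  expect_true(all(wide$post <= wide$pre))

  # power: the simulated training effect is detectable in >= 90/100 cohorts
  hits <- 0
  for (i in 1:100) {
    co <- simulate_cohort(cohort_spec(seed = 1000 + i), sessions = FALSE)
    res <- prepost_scales(co$scales)
    if (res$p.value[res$scale == "fma"] < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 90)
})

test_that("impairment monotonicity: aiming time up, max speed and vertical extent down", {
  set.seed(6)
  by_theta <- lapply(c(0.1, 0.5, 0.9), function(th) {
    # >= 100 attempts per theta level across sessions
    inds <- lapply(1:3, function(i) {
      suppressWarnings(extract_indicators(simulate_session(
        "s", "pre", th, task_settings(target_catches = 20L))))
    })
    dplyr::bind_rows(inds)
  })
  aim <- vapply(by_theta, function(d) mean(d$hmi_4), numeric(1))
  vmax <- vapply(by_theta, function(d) mean(d$fbmi_5), numeric(1))
  vext <- vapply(by_theta, function(d) mean(d$fbmi_12), numeric(1))
  expect_true(all(diff(aim) > 0))
  expect_true(all(diff(vmax) < 0))
  expect_true(all(diff(vext) < 0))
})
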