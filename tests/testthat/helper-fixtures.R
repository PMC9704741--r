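# Programmatic fixtures shared across test files.

default_settings <- function(affected = "right", ...) {
  task_settings(affected_side = affected, ...)
}

# a minimal valid frames table: ball idle, hands at rest
make_frames <- function(t, lh = c(-0.3, 1, 0.3), rh = c(0.3, 1, 0.3),
                        ball = c(0, 1.2, 0.45), state = "idle") {
  n <- length(t)
  tibble::tibble(
    t = t,
    lh_x = rep(lh[1], n), lh_y = rep(lh[2], n), lh_z = rep(lh[3], n),
    rh_x = rep(rh[1], n), rh_y = rep(rh[2], n), rh_z = rep(rh[3], n),
    ball_x = rep(ball[1], n), ball_y = rep(ball[2], n),
    ball_z = rep(ball[3], n),
    ball_state = rep(state, length.out = n)
  )
}

make_session <- function(frames, affected = "right", subject = "s01",
                         timepoint = "pre") {
  vr_session(subject, timepoint, default_settings(affected), frames)
}

# a hand-built attempt descriptor for the per-attempt operators
make_attempt <- function(t_spawn = 0, t_launch = 0.2, t_apex = 1,
                         t_end = 2, window_end = 3, outcome = "success",
                         target = c(0, 0, 0)) {
  list(t_spawn = t_spawn, t_launch = t_launch, t_apex = t_apex,
       t_end = t_end, window_end = window_end, outcome = outcome,
       target_x = target[1], target_y = target[2], target_z = target[3])
}

# 1-D path along x at fixed times (y, z constant)
make_path <- function(t, x, y = 0, z = 0) {
  tibble::tibble(t = t, x = x, y = rep(y, length(t)) + x * 0,
                 z = rep(z, length(t)) + x * 0)
}

# scale triples drawn from separated impairment strata (scales only)
make_strata_scales <- function(n_per = 13, theta_means = c(0.1, 0.5, 0.9),
                               theta_sd = 0.04) {
  rows <- list()
  id <- 0
  for (m in theta_means) {
    for (i in seq_len(n_per)) {
      id <- id + 1
      th <- min(1, max(0, rnorm(1, m, theta_sd)))
      rows[[id]] <- simulate_scales(th, sprintf("s%02d", id), "pre")
      rows[[id]]$stratum <- match(m, theta_means)
      rows[[id]]$theta <- th
    }
  }
  dplyr::bind_rows(rows)
}

# small random simulated session (<= 5 attempts) for oracle-equivalence
random_small_session <- function(theta = NULL, n_attempts = NULL,
                                 affected = NULL) {
  theta <- theta %||% runif(1)
  n_attempts <- n_attempts %||% sample(2:5, 1)
  affected <- affected %||% sample(c("left", "right"), 1)
  simulate_session("sx", "pre", theta,
                   task_settings(target_catches = n_attempts,
                                 affected_side = affected))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
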