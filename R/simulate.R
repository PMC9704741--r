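# Session simulator: parabolic ball flight at fractional gravity plus a
# reaction-delayed, speed-capped, tremor-noised arm controller whose quality
# degrades with an impairment parameter theta. Stands in for a clinical
# cohort so the whole pipeline is testable end-to-end.
#
# Fixed stage geometry (metres): hands rest at (+/-0.30, 1.00, 0.30),
# laterally clear of the catching band around the landing points; the
# ball flies in the plane z = 0.45 and is launched/caught at y = 1.20.
# Timeline per attempt: spawn -> +0.4 s touch/launch -> flight -> outcome
# shown 0.2 s -> next spawn 0.5 s after landing.

REST_LEFT <- c(-0.30, 1.00, 0.30)
REST_RIGHT <- c(0.30, 1.00, 0.30)
BALL_Z <- 0.45
LAUNCH_Y <- 1.20
SPAWN_TO_LAUNCH <- 0.4
OUTCOME_HOLD <- 0.2
END_TO_SPAWN <- 0.5
SESSION_TAIL <- 0.9
RETURN_CUE_LAG <- 0.15
TARGET_DWELL <- 0.2
CATCH_RADIUS_SIM <- 0.12
APEX_FRACTION <- 0.35  # apex height above launch, as fraction of arm length

norm3 <- function(v) sqrt(sum(v^2))

# closed-form ballistic trajectory through start and target with given apex
# height above the start; returns position function and event times
ball_flight_fun <- function(start_pos, target_pos, g_eff, apex_height) {
  horiz <- norm3(c(target_pos[1] - start_pos[1], target_pos[3] - start_pos[3]))
  if (horiz < 1e-9) {
    abort("start and target have zero horizontal separation")
  }
  drop <- start_pos[2] + apex_height - target_pos[2]
  if (drop < 0) abort("apex height puts the apex below the target")
  v_y0 <- sqrt(2 * g_eff * apex_height)
  t_apex <- v_y0 / g_eff
  t_flight <- t_apex + sqrt(2 * drop / g_eff)
  vx <- (target_pos[1] - start_pos[1]) / t_flight
  vz <- (target_pos[3] - start_pos[3]) / t_flight
  pos <- function(t) {
    cbind(start_pos[1] + vx * t,
          start_pos[2] + v_y0 * t - 0.5 * g_eff * t^2,
          start_pos[3] + vz * t)
  }
  list(pos = pos, t_apex = t_apex, t_flight = t_flight,
       v0 = c(vx, v_y0, vz))
}

#' Simulate one parabolic ball flight
#'
#' Integrates nothing: the path is the closed-form ballistic trajectory
#' under effective gravity `g_eff = gravity_fraction * 9.81` m/s^2,
#' launched so that it passes through both endpoints with the configured
#' apex height above the launch point. The apex occurs `v_y0 / g_eff`
#' seconds after launch.
#'
#' @param settings A [task_settings()] object (supplies the gravity
#'   fraction and, via `arm_length_m`, the default apex height).
#' @param start_pos,target_pos Numeric length-3 launch and landing
#'   positions in metres. Must be horizontally separated.
#' @param apex_height Apex height above the launch point in metres;
#'   default `0.35 * arm_length_m`.
#' @param dt Sampling interval in seconds.
#' @return A tibble with columns `t`, `x`, `y`, `z` (times relative to
#'   launch; the final row is the landing point), with attributes
#'   `t_apex`, `t_flight` and `v0` (launch velocity).
#' @examples
#' s <- task_settings(gravity_fraction = 1/9)
#' fl <- simulate_ball_flight(s, c(-0.15, 1.2, 0.45), c(0.15, 1.2, 0.45))
#' attr(fl, "t_apex")  # = v_y0 / g_eff
#' @export
simulate_ball_flight <- function(settings, start_pos, target_pos,
                                 apex_height = NULL, dt = 1 / 30) {
  apex_height <- apex_height %||% (APEX_FRACTION * settings$arm_length_m)
  g_eff <- settings$gravity_fraction * 9.81
  fl <- ball_flight_fun(start_pos, target_pos, g_eff, apex_height)
  tt <- unique(c(seq(0, fl$t_flight, by = dt), fl$t_flight))
  p <- fl$pos(tt)
  out <- tibble(t = tt, x = p[, 1], y = p[, 2], z = p[, 3])
  attr(out, "t_apex") <- fl$t_apex
  attr(out, "t_flight") <- fl$t_flight
  attr(out, "v0") <- fl$v0
  out
}

#' Plan the catching hand's movement for one attempt
#'
#' Behavioural model of one reach-to-catch: the hand rests until
#' `t_apex + reaction_delay` (Gaussian-noised delay; at the apex the
#' landing point becomes predictable), then moves in a straight line
#' toward the target at 80% of its speed cap. Impairment adds a downward
#' aiming droop (`0.05 * theta` m) and the reach clamp stops the hand at
#' `reach_fraction * arm_length` from its rest pose. After dwelling at its
#' endpoint the hand returns to rest, cued by the next ball spawn. The
#' attempt succeeds iff the hand is within the catching radius of the
#' landing point when the ball lands; degenerate profiles yield failed
#' catches, never errors.
#'
#' Uses R's global RNG stream (seed upstream for reproducibility).
#'
#' @param attempt List (or one-row data frame) with `t_apex`, `t_end`
#'   (seconds) and `target_center` (length-3, metres).
#' @param profile An [impairment_profile()] (fields may be overridden).
#' @param rest_pose Length-3 rest position of the hand.
#' @param next_spawn Time of the next ball spawn (return cue); defaults to
#'   `t_end + 0.5`.
#' @param arm_length_m Arm length used by the reach clamp.
#' @return A list of class `vr_arm_plan`: `waypoints` (tibble `t,x,y,z`
#'   defining the piecewise-linear noiseless path), `success`, `onset`,
#'   `t_arrive`, `endpoint`, `clamped`.
#' @seealso [arm_trajectory()] to sample the plan at frame times.
#' @export
simulate_arm <- function(attempt, profile, rest_pose = REST_RIGHT,
                         next_spawn = NULL, arm_length_m = 0.6) {
  target <- as.numeric(attempt$target_center)
  next_spawn <- next_spawn %||% (attempt$t_end + END_TO_SPAWN)
  aim <- target + c(0, -0.05 * profile$theta, 0)
  dir <- aim - rest_pose
  dist <- norm3(dir)
  reach <- profile$reach_fraction * arm_length_m
  clamped <- dist > reach
  endpoint <- if (clamped) rest_pose + dir * reach / dist else aim
  travel <- min(dist, reach)
  delay_sd <- 0.02 + 0.05 * profile$theta
  onset <- attempt$t_apex +
    max(0.02, rnorm(1, profile$reaction_delay_s, delay_sd))
  v_move <- 0.8 * profile$max_hand_speed_mps
  t_arrive <- onset + travel / v_move
  ret_start <- max(next_spawn + RETURN_CUE_LAG, t_arrive + TARGET_DWELL)
  ret_end <- ret_start + travel / v_move
  wp <- tibble(
    t = c(onset, t_arrive, ret_start, ret_end),
    x = c(rest_pose[1], endpoint[1], endpoint[1], rest_pose[1]),
    y = c(rest_pose[2], endpoint[2], endpoint[2], rest_pose[2]),
    z = c(rest_pose[3], endpoint[3], endpoint[3], rest_pose[3])
  )
  success <- (t_arrive <= attempt$t_end) &&
    (norm3(endpoint - target) <= CATCH_RADIUS_SIM)
  structure(list(waypoints = wp, success = success, onset = onset,
                 t_arrive = t_arrive, endpoint = endpoint,
                 clamped = clamped),
            class = "vr_arm_plan")
}

# piecewise-linear sampling of waypoint paths, constant outside the hull
sample_waypoints <- function(wp, times) {
  if (nrow(wp) < 2L) {
    p <- if (nrow(wp) == 1L) c(wp$x, wp$y, wp$z) else c(0, 0, 0)
    return(matrix(p, nrow = length(times), ncol = 3, byrow = TRUE))
  }
  sapply(c("x", "y", "z"), function(cl) {
    stats::approx(wp$t, wp[[cl]], xout = times, rule = 2, ties = "ordered")$y
  })
}

#' Sample an arm plan at frame times, with tremor
#'
#' @param plan A `vr_arm_plan` from [simulate_arm()].
#' @param times Numeric vector of sample times (seconds).
#' @param tremor_sd Per-frame, per-axis Gaussian positional noise (m).
#' @return Tibble `t, x, y, z`.
#' @export
arm_trajectory <- function(plan, times, tremor_sd = 0) {
  p <- sample_waypoints(plan$waypoints, times)
  if (tremor_sd > 0) {
    p <- p + matrix(rnorm(length(times) * 3, 0, tremor_sd), ncol = 3)
  }
  tibble(t = times, x = p[, 1], y = p[, 2], z = p[, 3])
}

#' Simulate a clinical scale triple from impairment severity
#'
#' Each score is `round(clip(max_score * (1 - theta) + noise))` clipped to
#' its printed range (FMA 0-22, TEMPA 0-27, WMFT 0-5), so expected scores
#' decrease monotonically in `theta` and `theta = 0` without noise gives
#' the scale maxima (22, 27, 5).
#'
#' @param theta Impairment severity in \[0, 1\].
#' @param subject_id,timepoint Identity columns of the returned row.
#' @param noise_sd Length-3 Gaussian noise SDs for (fma, tempa, wmft).
#' @return One-row tibble `subject, timepoint, fma, tempa, wmft`.
#' @export
simulate_scales <- function(theta, subject_id = "s01", timepoint = "pre",
                            noise_sd = c(fma = 1.5, tempa = 2.0,
                                         wmft = 0.4)) {
  if (!is_number(theta) || theta < 0 || theta > 1) {
    abort("`theta` must be a single number in [0, 1].")
  }
  draw <- function(mx, sd) {
    round(min(mx, max(0, mx * (1 - theta) + rnorm(1, 0, sd))))
  }
  tibble(subject = subject_id, timepoint = timepoint,
         fma = draw(22, noise_sd[[1]]),
         tempa = draw(27, noise_sd[[2]]),
         wmft = draw(5, noise_sd[[3]]))
}

#' Simulate one full training session
#'
#' Assembles `settings$target_catches` alternating throw-catch attempts:
#' each ball spawns on one side, is launched 0.4 s later along the
#' closed-form parabola, and is caught (or not) by the opposite hand,
#' whose motion follows [simulate_arm()] with the given impairment. The
#' affected hand uses `impairment_profile(theta)`; the other hand an
#' unimpaired profile. Uses R's global RNG stream.
#'
#' @param subject_id,timepoint Session identity.
#' @param theta Impairment severity of the affected arm.
#' @param settings A [task_settings()].
#' @param sample_rate_hz Frame rate (default 30 Hz, Kinect-like).
#' @return A validated `vr_session` with attributes `theta` and `truth`
#'   (tibble of per-attempt ground truth: event times, catching hand,
#'   success, target position).
#' @export
simulate_session <- function(subject_id, timepoint, theta,
                             settings = task_settings(),
                             sample_rate_hz = 30) {
  arm <- settings$arm_length_m
  g_eff <- settings$gravity_fraction * 9.81
  apex_h <- APEX_FRACTION * arm
  n_att <- settings$target_catches
  affected <- settings$affected_side
  prof_aff <- impairment_profile(theta)
  prof_norm <- impairment_profile(0)

  d <- runif(n_att, settings$range_mode[1], settings$range_mode[2]) * arm
  start_side <- rep(c("left", "right"), length.out = n_att)
  catch_side <- ifelse(start_side == "left", "right", "left")
  sgn <- ifelse(start_side == "left", -1, 1)

  flights <- vector("list", n_att)
  t_launch <- t_apex <- t_end <- t_spawn <- numeric(n_att)
  targets <- matrix(0, n_att, 3)
  t_cursor <- 0
  for (k in seq_len(n_att)) {
    start_pos <- c(sgn[k] * d[k] / 2, LAUNCH_Y, BALL_Z)
    target_pos <- c(-sgn[k] * d[k] / 2, LAUNCH_Y, BALL_Z)
    fl <- ball_flight_fun(start_pos, target_pos, g_eff, apex_h)
    t_spawn[k] <- t_cursor
    t_launch[k] <- t_cursor + SPAWN_TO_LAUNCH
    t_apex[k] <- t_launch[k] + fl$t_apex
    t_end[k] <- t_launch[k] + fl$t_flight
    flights[[k]] <- c(fl, list(start = start_pos))
    targets[k, ] <- target_pos
    t_cursor <- t_end[k] + END_TO_SPAWN
  }
  t_total <- t_end[n_att] + SESSION_TAIL
  times <- seq(0, t_total, by = 1 / sample_rate_hz)

  # plan both hands' movements; RNG order is attempt order
  plans <- vector("list", n_att)
  for (k in seq_len(n_att)) {
    prof <- if (catch_side[k] == affected) prof_aff else prof_norm
    rest <- if (catch_side[k] == "left") REST_LEFT else REST_RIGHT
    nxt <- if (k < n_att) t_spawn[k + 1] else t_end[k] + END_TO_SPAWN
    plans[[k]] <- simulate_arm(
      attempt = list(t_apex = t_apex[k], t_end = t_end[k],
                     target_center = targets[k, ]),
      profile = prof, rest_pose = rest, next_spawn = nxt,
      arm_length_m = arm)
  }
  success <- vapply(plans, `[[`, logical(1), "success")

  hand_pos <- function(side) {
    rest <- if (side == "left") REST_LEFT else REST_RIGHT
    ks <- which(catch_side == side)
    wp <- bind_rows(
      tibble(t = 0, x = rest[1], y = rest[2], z = rest[3]),
      lapply(plans[ks], `[[`, "waypoints"))
    prof <- if (side == affected) prof_aff else prof_norm
    sample_waypoints(wp, times) +
      matrix(rnorm(length(times) * 3, 0, prof$tremor_sd_m), ncol = 3)
  }
  lh <- hand_pos("left")
  rh <- hand_pos("right")

  ball <- matrix(0, length(times), 3)
  state <- rep("idle", length(times))
  ball[, 1] <- flights[[1]]$start[1]
  ball[, 2] <- LAUNCH_Y
  ball[, 3] <- BALL_Z
  for (k in seq_len(n_att)) {
    idle_i <- times >= t_spawn[k] & times < t_launch[k]
    ball[idle_i, ] <- matrix(flights[[k]]$start, sum(idle_i), 3,
                             byrow = TRUE)
    fly_i <- times >= t_launch[k] & times < t_end[k]
    ball[fly_i, ] <- flights[[k]]$pos(times[fly_i] - t_launch[k])
    state[fly_i] <- "flying"
    out_i <- times >= t_end[k] & times <= t_end[k] + OUTCOME_HOLD
    ball[out_i, ] <- matrix(targets[k, ], sum(out_i), 3, byrow = TRUE)
    state[out_i] <- if (success[k]) "caught" else "missed"
    gap_i <- times > t_end[k] + OUTCOME_HOLD &
      (if (k < n_att) times < t_spawn[k + 1] else TRUE)
    hold <- if (k < n_att) flights[[k + 1]]$start else targets[k, ]
    ball[gap_i, ] <- matrix(hold, sum(gap_i), 3, byrow = TRUE)
  }

  frames <- tibble(
    t = times,
    lh_x = lh[, 1], lh_y = lh[, 2], lh_z = lh[, 3],
    rh_x = rh[, 1], rh_y = rh[, 2], rh_z = rh[, 3],
    ball_x = ball[, 1], ball_y = ball[, 2], ball_z = ball[, 3],
    ball_state = state
  )
  rec <- vr_session(subject_id, timepoint, settings, frames,
                    sample_rate_hz)
  attr(rec, "theta") <- theta
  attr(rec, "truth") <- tibble(
    index = seq_len(n_att), t_spawn = t_spawn, t_launch = t_launch,
    t_apex = t_apex, t_end = t_end, catching_hand = catch_side,
    success = success, target_x = targets[, 1], target_y = targets[, 2],
    target_z = targets[, 3], throw_distance = d)
  rec
}

#' Specify a synthetic cohort
#'
#' Defaults emulate a 20-patient pre/post trial with three well-separated
#' impairment strata: per-subject severity is drawn around stratum means
#' `theta_means` with SD `theta_sd` (clipped to \[0, 1\]), and the post
#' timepoint applies a Beta-distributed retention factor
#' (`theta_post = theta_pre * Beta(8, 2)`, mean 0.8), i.e. a stochastic
#' improvement.
#'
#' @param n_subjects Number of subjects (default 20).
#' @param timepoints Character subset of `c("pre", "post")`.
#' @param settings A [task_settings()] shared by all sessions.
#' @param theta_means,theta_sd Stratum means and within-stratum SD of the
#'   impairment severity.
#' @param retention_shape Length-2 Beta shape parameters of the pre-to-post
#'   retention factor.
#' @param scale_noise_sd Gaussian noise SDs for (fma, tempa, wmft).
#' @param seed Integer RNG seed; fixed seed implies a fully reproducible
#'   cohort.
#' @return An object of class `vr_cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 20L,
                        timepoints = c("pre", "post"),
                        settings = task_settings(),
                        theta_means = c(0.10, 0.50, 0.90),
                        theta_sd = 0.04,
                        retention_shape = c(8, 2),
                        scale_noise_sd = c(fma = 1.5, tempa = 2.0,
                                           wmft = 0.4),
                        seed = 1L) {
  n_subjects <- as.integer(n_subjects)
  if (is.na(n_subjects) || n_subjects < 1L) {
    abort("`n_subjects` must be >= 1")
  }
  timepoints <- match.arg(timepoints, c("pre", "post"), several.ok = TRUE)
  structure(
    list(n_subjects = n_subjects, timepoints = timepoints,
         settings = settings, theta_means = theta_means,
         theta_sd = theta_sd, retention_shape = retention_shape,
         scale_noise_sd = scale_noise_sd, seed = as.integer(seed)),
    class = "vr_cohort_spec"
  )
}

#' Simulate a cohort of sessions with matched clinical scales
#'
#' Draws per-subject impairment severities from `spec`'s strata, applies
#' the retention model for the post timepoint, and generates one session
#' recording (optional) plus one scale triple per subject x timepoint.
#' Fully deterministic given `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @param sessions If `FALSE`, skip trajectory simulation and return
#'   scales + severities only (fast; useful for scale-level analyses).
#' @return A list of class `vr_cohort`: `scales` (tibble), `truth`
#'   (tibble `subject, timepoint, theta, stratum`), `sessions` (named list
#'   of `vr_session`, or `NULL`), `spec`.
#' @export
simulate_cohort <- function(spec, sessions = TRUE) {
  stopifnot(inherits(spec, "vr_cohort_spec"))
  withr::with_seed(spec$seed, {
    n <- spec$n_subjects
    subj <- sprintf("s%02d", seq_len(n))
    # quota-balanced recruitment: subjects split as evenly as possible
    # across the severity strata, in shuffled order
    stratum <- sample(rep_len(seq_along(spec$theta_means), n))
    th_pre <- pmin(1, pmax(0, rnorm(n, spec$theta_means[stratum],
                                    spec$theta_sd)))
    retention <- rbeta(n, spec$retention_shape[1], spec$retention_shape[2])
    th <- list(pre = th_pre, post = th_pre * retention)

    # scales are drawn before any trajectory simulation so that task
    # physics settings cannot perturb the clinical-scale stream
    truth <- list()
    scales <- list()
    recs <- list()
    for (tp in spec$timepoints) {
      for (i in seq_len(n)) {
        id <- paste0(subj[i], "_", tp)
        truth[[id]] <- tibble(subject = subj[i], timepoint = tp,
                              theta = th[[tp]][i], stratum = stratum[i])
        scales[[id]] <- simulate_scales(th[[tp]][i], subj[i], tp,
                                        spec$scale_noise_sd)
      }
    }
    if (sessions) {
      for (tp in spec$timepoints) {
        for (i in seq_len(n)) {
          id <- paste0(subj[i], "_", tp)
          recs[[id]] <- simulate_session(subj[i], tp, th[[tp]][i],
                                         spec$settings)
        }
      }
    }
    structure(list(scales = bind_rows(scales), truth = bind_rows(truth),
                   sessions = if (sessions) recs else NULL, spec = spec),
              class = "vr_cohort")
  })
}

#' @export
print.vr_cohort <- function(x, ...) {
  cat(sprintf("<vr_cohort> %d subjects x %s, %d scale triples, %s sessions\n",
              x$spec$n_subjects, paste(x$spec$timepoints, collapse = "/"),
              nrow(x$scales),
              if (is.null(x$sessions)) "no" else length(x$sessions)))
  invisible(x)
}

#' Write a simulated cohort to a run directory
#'
#' Writes one frames CSV + JSON sidecar per session, a `scales.csv`, a
#' `truth.csv` (simulated severities) and returns the file listing.
#'
#' @param cohort A `vr_cohort` with sessions.
#' @param dir Output directory (created if needed).
#' @return Character vector of written files, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "vr_cohort"), !is.null(cohort$sessions))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (id in names(cohort$sessions)) {
    files <- c(files,
               write_session(cohort$sessions[[id]], file.path(dir, id)),
               file.path(dir, paste0(id, ".json")))
  }
  sc <- file.path(dir, "scales.csv")
  write_scales(cohort$scales, sc)
  tr <- file.path(dir, "truth.csv")
  tru <- cohort$truth
  lines <- c("subject,timepoint,theta,stratum",
             sprintf("%s,%s,%s,%d", tru$subject, tru$timepoint,
                     fmt_num(tru$theta), tru$stratum))
  con <- file(tr, open = "wb")
  writeLines(lines, con, sep = "\n")
  close(con)
  invisible(c(files, sc, tr))
}
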