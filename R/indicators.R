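#' Configuration for motor-indicator extraction
#'
#' Numeric parameters the indicator definitions leave open:
#'
#' @param catch_radius_m Radius (m) of the full-3D catching range around
#'   the landing point. Default 0.12 m, roughly ball-sized.
#' @param axis_band_m Half-width (m) of the per-axis band used by the
#'   horizontal/vertical indicator variants. Default 0.12 m.
#' @param stabilization_speed_mps Smoothed hand speed (m/s) below which
#'   the hand counts as stabilized. Default 0.05 m/s.
#' @param stabilization_dwell_s Minimum duration (s) below the speed
#'   threshold. Default 0.1 s.
#' @param smoothing_window_frames Odd width of the centred moving-average
#'   position smoother applied before differencing (suppresses
#'   differentiation noise from tremor). Default 5 frames.
#' @return An object of class `vr_indicator_config`.
#' @export
indicator_config <- function(catch_radius_m = 0.12,
                             axis_band_m = 0.12,
                             stabilization_speed_mps = 0.05,
                             stabilization_dwell_s = 0.1,
                             smoothing_window_frames = 5L) {
  vals <- c(catch_radius_m, axis_band_m, stabilization_speed_mps,
            stabilization_dwell_s, smoothing_window_frames)
  if (!all(vapply(vals, is_number, logical(1))) || any(vals <= 0)) {
    abort("all indicator-config parameters must be positive numbers")
  }
  w <- as.integer(smoothing_window_frames)
  if (w %% 2L == 0L) abort("`smoothing_window_frames` must be odd")
  structure(
    list(catch_radius_m = catch_radius_m, axis_band_m = axis_band_m,
         stabilization_speed_mps = stabilization_speed_mps,
         stabilization_dwell_s = stabilization_dwell_s,
         smoothing_window_frames = w),
    class = "vr_indicator_config"
  )
}

#' The 25 motor indicator names
#'
#' `hmi_1..6` (horizontal), `vmi_1..6` (vertical) and `fbmi_1..13`
#' (full-body). See [extract_indicators()] for semantics.
#'
#' @return Character vector of length 25.
#' @export
indicator_names <- function() {
  c(paste0("hmi_", 1:6), paste0("vmi_", 1:6), paste0("fbmi_", 1:13))
}

# centred moving average with shrinking symmetric windows at the edges
roll_mean <- function(x, w) {
  if (w <= 1L) return(x)
  h <- (w - 1L) %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(1L, i - h)
  hi <- pmin(n, i + h)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

smooth_path <- function(path, w) {
  tibble(t = path$t, x = roll_mean(path$x, w), y = roll_mean(path$y, w),
         z = roll_mean(path$z, w))
}

#' Instantaneous speed series of a hand path
#'
#' Positions are first smoothed with a centred moving average of
#' `config$smoothing_window_frames`, then differenced:
#' `v_i = ||p_(i+1) - p_i|| / (t_(i+1) - t_i)`. Element `i` is tagged with
#' the interval `[t_i, t_(i+1))`.
#'
#' @param path Tibble `t, x, y, z`.
#' @param config An [indicator_config()].
#' @return Tibble `t0, t1, v` of length `nrow(path) - 1`.
#' @export
speed_series <- function(path, config = indicator_config()) {
  sp <- smooth_path(path, config$smoothing_window_frames)
  n <- nrow(sp)
  if (n < 2L) return(tibble(t0 = numeric(0), t1 = numeric(0),
                            v = numeric(0)))
  d <- sqrt(diff(sp$x)^2 + diff(sp$y)^2 + diff(sp$z)^2)
  dt <- diff(sp$t)
  tibble(t0 = sp$t[-n], t1 = sp$t[-1L], v = d / dt)
}

in_range_flags <- function(path, target, config, axis_mode) {
  switch(axis_mode,
    horizontal = abs(path$x - target[1]) <= config$axis_band_m,
    vertical = abs(path$y - target[2]) <= config$axis_band_m,
    full3d = sqrt((path$x - target[1])^2 + (path$y - target[2])^2 +
                    (path$z - target[3])^2) <= config$catch_radius_m,
    abort("`axis_mode` must be 'horizontal', 'vertical' or 'full3d'")
  )
}

attempt_target <- function(attempt) {
  c(attempt$target_x, attempt$target_y, attempt$target_z)
}

attempt_window <- function(path, attempt, t_hi) {
  path[path$t >= attempt$t_spawn & path$t <= t_hi, , drop = FALSE]
}

#' Catching-range crossings of a hand within one attempt
#'
#' Tests, frame by frame over the attempt's analysis window
#' (`t_spawn` to `window_end`), whether the hand is inside the catching
#' range: `horizontal` mode uses `|hand_x - target_x| <= axis_band_m`,
#' `vertical` uses the y axis, `full3d` the Euclidean distance against
#' `catch_radius_m`. An entry is counted at each below-threshold crossing
#' (a hand already in range at the window start counts as one entry at
#' time 0). Times are relative to `t_spawn`.
#'
#' @param path Hand path tibble `t, x, y, z` (whole session; the attempt
#'   window is selected internally).
#' @param attempt One attempt: a one-row data frame or list from
#'   [segment_attempts()].
#' @param config An [indicator_config()].
#' @param axis_mode `"horizontal"`, `"vertical"` or `"full3d"`.
#' @return Tibble `first_entry, last_entry, n_entries`; a hand that never
#'   enters gives `(NA, NA, 0)`.
#' @export
range_crossings <- function(path, attempt, config = indicator_config(),
                            axis_mode = "full3d") {
  t_hi <- attempt$window_end %||% attempt$t_end
  if (is.na(t_hi)) t_hi <- attempt$t_end
  win <- attempt_window(path, attempt, t_hi)
  inr <- in_range_flags(win, attempt_target(attempt), config, axis_mode)
  rises <- which(inr & !c(FALSE, inr[-length(inr)]))
  if (length(rises) == 0L) {
    return(tibble(first_entry = NA_real_, last_entry = NA_real_,
                  n_entries = 0L))
  }
  tibble(first_entry = win$t[rises[1L]] - attempt$t_spawn,
         last_entry = win$t[rises[length(rises)]] - attempt$t_spawn,
         n_entries = length(rises))
}

#' Aiming time of one attempt
#'
#' Latency from the ball's apex to the hand's first presence in the
#' catching range at or after the apex: the first in-range frame with
#' `t >= t_apex`, minus `t_apex`. A hand already in range at the apex
#' scores 0; a hand that is in range only before the apex (and out after)
#' scores missing. Lower is a faster reaction.
#'
#' @inheritParams range_crossings
#' @return Seconds, or `NA` if the hand never occupies the range after
#'   the apex within the analysis window.
#' @export
aiming_time <- function(path, attempt, config = indicator_config(),
                        axis_mode = "full3d") {
  t_hi <- attempt$window_end %||% attempt$t_end
  if (is.na(t_hi)) t_hi <- attempt$t_end
  win <- attempt_window(path, attempt, t_hi)
  inr <- in_range_flags(win, attempt_target(attempt), config, axis_mode)
  post <- which(inr & win$t >= attempt$t_apex)
  if (length(post) == 0L) return(NA_real_)
  win$t[post[1L]] - attempt$t_apex
}

#' Stabilization-to-catch time of one attempt
#'
#' Finds the first interval, while the hand is inside the catching range
#' before the catch, during which the smoothed hand speed stays below
#' `stabilization_speed_mps` for at least `stabilization_dwell_s`; returns
#' `t_end` minus the start of that interval. Missing when the attempt
#' failed or the hand never stabilized. A tremor-free, parked hand thus
#' scores the time it spent waiting for the ball.
#'
#' @inheritParams range_crossings
#' @return Seconds, or `NA`.
#' @export
stabilization_to_catch <- function(path, attempt,
                                   config = indicator_config(),
                                   axis_mode = "full3d") {
  if (!identical(attempt$outcome, "success")) return(NA_real_)
  win <- attempt_window(path, attempt, attempt$t_end)
  if (nrow(win) < 2L) return(NA_real_)
  inr <- in_range_flags(win, attempt_target(attempt), config, axis_mode)
  sp <- speed_series(win, config)
  ok <- inr[-nrow(win)] & sp$v < config$stabilization_speed_mps
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in which(r$values)) {
    # run of speed intervals starts[j]..ends[j] spans t0[start]..t1[end]
    if (sp$t1[ends[j]] - sp$t0[starts[j]] >= config$stabilization_dwell_s) {
      return(attempt$t_end - sp$t0[starts[j]])
    }
  }
  NA_real_
}

#' Speed statistics: maximum, mean and V-variation
#'
#' For instantaneous speeds `v_i`: the maximum speed `max(v_i)`, the
#' average speed `mean(v_i)`, and the V-variation
#' `sigma = sqrt(mean((v_i - v_bar)^2))` — the *population* standard
#' deviation (divisor N), a speed-dispersion measure of motor control.
#'
#' @param v Numeric vector of speeds (m/s).
#' @return Tibble `v_max, v_bar, sigma`; an empty vector gives an
#'   all-missing row.
#' @examples
#' speed_stats(c(1, 3))  # v_max 3, v_bar 2, sigma 1
#' @export
speed_stats <- function(v) {
  v <- v[!is.na(v)]
  if (length(v) == 0L) {
    return(tibble(v_max = NA_real_, v_bar = NA_real_, sigma = NA_real_))
  }
  v_bar <- mean(v)
  tibble(v_max = max(v), v_bar = v_bar,
         sigma = sqrt(mean((v - v_bar)^2)))
}

#' Movement ratio between the normal and affected arm
#'
#' Ratio of the normal arm's movement distance to the affected arm's
#' movement distance over the session. Values above 1 mean the affected
#' arm moved less than the unimpaired arm.
#'
#' @param normal_dist_m,affected_dist_m Path lengths in metres.
#' @return Dimensionless ratio, or `NA` (with a warning) when the
#'   affected distance is not positive.
#' @export
movement_ratio <- function(normal_dist_m, affected_dist_m) {
  if (!is_number(affected_dist_m) || affected_dist_m <= 0) {
    warn("affected-arm distance is not positive; movement ratio undefined")
    return(NA_real_)
  }
  normal_dist_m / affected_dist_m
}

#' Total path length of a hand
#'
#' Sum of successive Euclidean displacements. Positions are smoothed with
#' the config's moving-average window first, so sensor/tremor noise does
#' not dominate the sum.
#'
#' @param path Tibble `t, x, y, z`.
#' @param config An [indicator_config()]; use
#'   `smoothing_window_frames = 1` for the raw polyline length.
#' @return Metres.
#' @export
path_length <- function(path, config = indicator_config()) {
  sp <- smooth_path(path, config$smoothing_window_frames)
  if (nrow(sp) < 2L) return(0)
  sum(sqrt(diff(sp$x)^2 + diff(sp$y)^2 + diff(sp$z)^2))
}

#' Maximum per-axis extension of a hand from its rest pose
#'
#' Maximum absolute displacement from `rest_pose` along each axis:
#' horizontal (x), vertical (y) and front-view/depth (z).
#'
#' @param path Tibble `t, x, y, z`.
#' @param rest_pose Length-3 rest position; defaults to the path's first
#'   sample.
#' @return Tibble `max_x, max_y, max_z` (metres, non-negative).
#' @export
extension_extents <- function(path, rest_pose = NULL) {
  if (is.null(rest_pose)) {
    rest_pose <- c(path$x[1], path$y[1], path$z[1])
  }
  tibble(max_x = max(abs(path$x - rest_pose[1])),
         max_y = max(abs(path$y - rest_pose[2])),
         max_z = max(abs(path$z - rest_pose[3])))
}

mean_or_na <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) NA_real_ else mean(x)
}

#' Extract the 25 motor indicators from one session
#'
#' Segments the session with [segment_attempts()] and computes, for the
#' affected hand:
#'
#' * `hmi_1..6` / `vmi_1..6` — per-attempt horizontal/vertical-band
#'   values averaged over the affected hand's attempts: first and last
#'   range-entry time, catch time (successes only; axis-independent, so
#'   `hmi_3 == vmi_3`), aiming time, stabilization-to-catch time
#'   (successes only), and mean number of range entries;
#' * `fbmi_1` — mean, over successful affected-hand attempts, of the
#'   catch time minus the preceding normal-hand touch (= launch) time;
#' * `fbmi_2` — total catching time of successful affected-hand attempts;
#' * `fbmi_3` — affected-hand path length over the session;
#' * `fbmi_4` — movement ratio (normal / affected path length);
#' * `fbmi_5..7` / `fbmi_8..10` — max speed, average speed and
#'   V-variation of the affected hand pooled over all attempts'
#'   before-apex windows (`[t_spawn, t_apex)`) / after-apex windows
#'   (`[t_apex, t_end]`);
#' * `fbmi_11..13` — maximum horizontal, vertical and front-view
#'   extension from the rest pose (the hand's first recorded position).
#'
#' Undefined values stay missing (`NA`) — never silently 0. A session
#' with no affected-hand attempts yields an all-missing row with a
#' warning.
#'
#' @param rec A validated `vr_session`.
#' @param config An [indicator_config()].
#' @return A one-row tibble: `subject, timepoint, n_attempts_used`, then
#'   the 25 indicator columns in [indicator_names()] order.
#' @export
extract_indicators <- function(rec, config = indicator_config()) {
  att <- segment_attempts(rec)
  aff_path <- hand_path(rec, "affected")
  nor_path <- hand_path(rec, "normal")
  out <- tibble(subject = rec$subject_id, timepoint = rec$timepoint,
                n_attempts_used = 0L)
  for (nm in indicator_names()) out[[nm]] <- NA_real_

  aff_att <- att[att$catching_hand == rec$settings$affected_side, ,
                 drop = FALSE]
  if (nrow(aff_att) == 0L) {
    warn(sprintf("session %s_%s: no affected-hand attempts; all indicators missing",
                 rec$subject_id, rec$timepoint))
    return(out)
  }
  out$n_attempts_used <- nrow(aff_att)

  per <- lapply(seq_len(nrow(aff_att)), function(i) {
    a <- aff_att[i, ]
    rc_h <- range_crossings(aff_path, a, config, "horizontal")
    rc_v <- range_crossings(aff_path, a, config, "vertical")
    ok <- a$outcome == "success"
    tibble(
      first_h = rc_h$first_entry, last_h = rc_h$last_entry,
      n_h = rc_h$n_entries,
      first_v = rc_v$first_entry, last_v = rc_v$last_entry,
      n_v = rc_v$n_entries,
      catch_time = if (ok) a$t_end - a$t_spawn else NA_real_,
      aim_h = aiming_time(aff_path, a, config, "horizontal"),
      aim_v = aiming_time(aff_path, a, config, "vertical"),
      stab_h = stabilization_to_catch(aff_path, a, config, "horizontal"),
      stab_v = stabilization_to_catch(aff_path, a, config, "vertical"),
      launch_to_catch = if (ok) a$t_end - a$t_launch else NA_real_
    )
  })
  per <- bind_rows(per)

  out$hmi_1 <- mean_or_na(per$first_h)
  out$hmi_2 <- mean_or_na(per$last_h)
  out$hmi_3 <- mean_or_na(per$catch_time)
  out$hmi_4 <- mean_or_na(per$aim_h)
  out$hmi_5 <- mean_or_na(per$stab_h)
  out$hmi_6 <- mean(per$n_h)
  out$vmi_1 <- mean_or_na(per$first_v)
  out$vmi_2 <- mean_or_na(per$last_v)
  out$vmi_3 <- out$hmi_3
  out$vmi_4 <- mean_or_na(per$aim_v)
  out$vmi_5 <- mean_or_na(per$stab_v)
  out$vmi_6 <- mean(per$n_v)

  out$fbmi_1 <- mean_or_na(per$launch_to_catch)
  out$fbmi_2 <- if (all(is.na(per$catch_time))) NA_real_ else
    sum(per$catch_time, na.rm = TRUE)
  aff_len <- path_length(aff_path, config)
  out$fbmi_3 <- aff_len
  out$fbmi_4 <- movement_ratio(path_length(nor_path, config), aff_len)

  sp <- speed_series(aff_path, config)
  pool <- function(lo, hi) {
    unlist(lapply(seq_len(nrow(att)), function(k) {
      sp$v[sp$t0 >= lo[k] & sp$t1 <= hi[k]]
    }))
  }
  pre <- speed_stats(pool(att$t_spawn, att$t_apex))
  post <- speed_stats(pool(att$t_apex, att$t_end))
  out$fbmi_5 <- pre$v_max
  out$fbmi_6 <- pre$v_bar
  out$fbmi_7 <- pre$sigma
  out$fbmi_8 <- post$v_max
  out$fbmi_9 <- post$v_bar
  out$fbmi_10 <- post$sigma

  ext <- extension_extents(aff_path)
  out$fbmi_11 <- ext$max_x
  out$fbmi_12 <- ext$max_y
  out$fbmi_13 <- ext$max_z
  out
}

#' Extract indicators for every session of a cohort
#'
#' @param x A `vr_cohort` (with sessions) or a list of `vr_session`.
#' @param config An [indicator_config()].
#' @return Tibble with one row per session.
#' @export
extract_cohort_indicators <- function(x, config = indicator_config()) {
  recs <- if (inherits(x, "vr_cohort")) x$sessions else x
  stopifnot(length(recs) > 0)
  bind_rows(lapply(recs, extract_indicators, config = config))
}

#' Write / read an indicators table
#'
#' Deterministic CSV with identity columns and the 25 indicator columns;
#' missing values are written as empty cells (never 0, which is a
#' meaningful value for counts and times).
#'
#' @param df Indicators tibble from [extract_indicators()].
#' @param path CSV path.
#' @return `path` / the tibble.
#' @export
write_indicators <- function(df, path) {
  cols <- c("subject", "timepoint", "n_attempts_used", indicator_names())
  stopifnot(all(cols %in% names(df)))
  num_fmt <- function(x) ifelse(is.na(x), "", fmt_num(x))
  body <- cbind(df$subject, df$timepoint, as.character(df$n_attempts_used),
                vapply(indicator_names(), function(cl) num_fmt(df[[cl]]),
                       character(nrow(df))))
  if (nrow(df) == 1L) body <- matrix(body, nrow = 1L)
  lines <- c(paste(cols, collapse = ","),
             apply(body, 1, paste, collapse = ","))
  con <- file(path, open = "wb")
  on.exit(close(con), add = TRUE)
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' @rdname write_indicators
#' @export
read_indicators <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  cols <- c("subject", "timepoint", "n_attempts_used", indicator_names())
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols)) {
    format_error("indicators CSV missing column(s): %s",
                 paste(missing_cols, collapse = ", "))
  }
  as_tibble(df[, cols])
}
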