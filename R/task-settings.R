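#' Task difficulty settings for the bilateral ball-catching task
#'
#' The task throws a virtual ball along a parabola from one side of the
#' patient to the other; the patient catches it with alternating hands.
#' Difficulty is controlled by the effective gravity (the ball falls at a
#' fraction of standard gravity, so slower balls are easier to track), the
#' horizontal flight range expressed as a fraction of the patient's arm
#' length, and the number of catches per session.
#'
#' @param gravity_fraction Fraction of standard gravity (9.81 m/s^2) acting
#'   on the ball. One of `1/9`, `2/9`, `3/9`.
#' @param range_mode Length-2 numeric: lower and upper bound of the
#'   horizontal throw distance as fractions of `arm_length_m`. One of
#'   `c(0.30, 0.50)`, `c(0.30, 0.75)`, `c(0.30, 1.00)`.
#' @param target_catches Number of throw-catch attempts in a session.
#' @param arm_length_m Patient arm length in metres.
#' @param affected_side Which arm is paretic: `"left"` or `"right"`.
#'
#' @return An object of class `vr_task_settings` (a named list).
#' @examples
#' task_settings(gravity_fraction = 1/9, affected_side = "right")
#' @export
task_settings <- function(gravity_fraction = 1 / 9,
                          range_mode = c(0.30, 0.50),
                          target_catches = 10L,
                          arm_length_m = 0.6,
                          affected_side = c("right", "left")) {
  affected_side <- match.arg(affected_side)
  allowed_g <- c(1, 2, 3) / 9
  if (!is_number(gravity_fraction) ||
      !any(abs(gravity_fraction - allowed_g) < 1e-12)) {
    abort("`gravity_fraction` must be one of 1/9, 2/9, 3/9.")
  }
  allowed_rm <- list(c(0.30, 0.50), c(0.30, 0.75), c(0.30, 1.00))
  ok <- any(vapply(allowed_rm, function(r) isTRUE(all.equal(r, range_mode)),
                   logical(1)))
  if (!ok) {
    abort("`range_mode` must be c(0.30,0.50), c(0.30,0.75) or c(0.30,1.00).")
  }
  if (!(range_mode[2] > range_mode[1] && range_mode[1] > 0)) {
    abort("`range_mode` upper bound must exceed the lower bound, both > 0.")
  }
  target_catches <- as.integer(target_catches)
  if (is.na(target_catches) || target_catches < 1L) {
    abort("`target_catches` must be a positive integer.")
  }
  if (!is_number(arm_length_m) || arm_length_m <= 0) {
    abort("`arm_length_m` must be a positive length in metres.")
  }
  structure(
    list(gravity_fraction = gravity_fraction,
         range_mode = as.numeric(range_mode),
         target_catches = target_catches,
         arm_length_m = arm_length_m,
         affected_side = affected_side),
    class = "vr_task_settings"
  )
}

#' @export
print.vr_task_settings <- function(x, ...) {
  cat(sprintf(
    "<vr_task_settings> g = %.3f G, range %.0f-%.0f%% of %.2f m arm, %d catches, affected %s\n",
    x$gravity_fraction, 100 * x$range_mode[1], 100 * x$range_mode[2],
    x$arm_length_m, x$target_catches, x$affected_side))
  invisible(x)
}

#' Impairment profile mapping severity to arm-control parameters
#'
#' Maps a scalar impairment severity `theta` in \[0, 1\] (0 = unimpaired) to
#' the kinematic parameters of the simulated arm controller. All maps are
#' affine in `theta`:
#'
#' * `reaction_delay_s = 0.15 + 0.8 theta` — latency from the ball's apex
#'   (the moment the landing point is predictable) to movement onset;
#' * `max_hand_speed_mps = 2.5 - 1.8 theta` — peak hand speed cap;
#' * `tremor_sd_m = 0.0005 + 0.003 theta` — per-frame Gaussian positional
#'   noise (intention tremor);
#' * `reach_fraction = 1 - 0.7 theta` — achievable fraction of arm length,
#'   limiting displacement from the rest pose.
#'
#' @param theta Impairment severity in \[0, 1\].
#' @return An object of class `vr_impairment_profile`.
#' @examples
#' impairment_profile(0)    # healthy control
#' impairment_profile(0.8)  # severely impaired
#' @export
impairment_profile <- function(theta) {
  if (!is_number(theta) || theta < 0 || theta > 1) {
    abort("`theta` must be a single number in [0, 1].")
  }
  structure(
    list(theta = theta,
         reaction_delay_s = 0.15 + 0.8 * theta,
         max_hand_speed_mps = 2.5 - 1.8 * theta,
         tremor_sd_m = 0.0005 + 0.003 * theta,
         reach_fraction = 1 - 0.7 * theta),
    class = "vr_impairment_profile"
  )
}

#' @export
print.vr_impairment_profile <- function(x, ...) {
  cat(sprintf(
    "<vr_impairment_profile> theta = %.2f (delay %.2f s, vmax %.2f m/s, tremor %.4f m, reach %.0f%%)\n",
    x$theta, x$reaction_delay_s, x$max_hand_speed_mps, x$tremor_sd_m,
    100 * x$reach_fraction))
  invisible(x)
}
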