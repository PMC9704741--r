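#' Segment a session into throw-catch attempts
#'
#' Scans the ball-state channel for flying episodes and derives one
#' attempt per episode:
#'
#' * `t_launch` — first flying frame; `t_end` — the outcome (caught or
#'   missed) frame ending the episode, or the last flying frame if the
#'   recording truncates the episode;
#' * `t_spawn` — start of the idle run immediately preceding the launch
#'   (the ball appearing on screen), or `t_launch` when there is none;
#' * `t_apex` — time of the maximum ball height within the episode;
#' * `catching_hand` — the side the ball lands on (`x > launch x` is a
#'   rightward throw, caught by the right hand), which alternates by task
#'   design;
#' * `target_center` — the ball position at `t_end`, i.e. the landing
#'   point (for both caught and missed balls the ball is at the landing
#'   point when the outcome registers);
#' * `window_end` — end of the attempt's analysis window: the next
#'   attempt's launch (or the last frame). Hand movement between a miss
#'   and the next throw still belongs to this attempt, so late range
#'   entries by slow movers are observable.
#'
#' @param rec A validated `vr_session`.
#' @return A tibble with one row per attempt: `index`, `t_spawn`,
#'   `t_launch`, `t_apex`, `t_end`, `window_end`, `catching_hand`,
#'   `outcome` (`"success"`/`"fail"`), `target_x/y/z`. Zero flying
#'   episodes give an empty tibble, not an error.
#' @export
segment_attempts <- function(rec) {
  validate_session(rec)
  fr <- rec$frames
  st <- fr$ball_state
  r <- rle(st)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  fly <- which(r$values == "flying")
  empty <- tibble(index = integer(0), t_spawn = numeric(0),
                  t_launch = numeric(0), t_apex = numeric(0),
                  t_end = numeric(0), window_end = numeric(0),
                  catching_hand = character(0), outcome = character(0),
                  target_x = numeric(0), target_y = numeric(0),
                  target_z = numeric(0))
  if (length(fly) == 0L) return(empty)

  rows <- lapply(seq_along(fly), function(j) {
    ri <- fly[j]
    i0 <- run_start[ri]
    i1 <- run_end[ri]
    t_launch <- fr$t[i0]
    # spawn: start of the idle run immediately before this flight
    t_spawn <- if (ri > 1L && r$values[ri - 1L] == "idle") {
      fr$t[run_start[ri - 1L]]
    } else {
      t_launch
    }
    # outcome frame right after the flight run, if any
    if (ri < length(r$values) && r$values[ri + 1L] %in% c("caught", "missed")) {
      i_end <- run_end[ri] + 1L
      outcome <- if (r$values[ri + 1L] == "caught") "success" else "fail"
    } else {
      i_end <- i1
      outcome <- "fail"
    }
    t_end <- fr$t[i_end]
    apex_i <- i0 + which.max(fr$ball_y[i0:i1]) - 1L
    hand <- if (fr$ball_x[i_end] >= fr$ball_x[i0]) "right" else "left"
    tibble(index = j, t_spawn = t_spawn, t_launch = t_launch,
           t_apex = fr$t[apex_i], t_end = t_end, window_end = NA_real_,
           catching_hand = hand, outcome = outcome,
           target_x = fr$ball_x[i_end], target_y = fr$ball_y[i_end],
           target_z = fr$ball_z[i_end])
  })
  att <- bind_rows(rows)
  att$window_end <- c(att$t_launch[-1L], fr$t[nrow(fr)])
  att
}

#' Extract one hand's path from a session
#'
#' @param rec A `vr_session`.
#' @param hand `"left"`, `"right"`, `"affected"` or `"normal"`.
#' @return Tibble `t, x, y, z`.
#' @export
hand_path <- function(rec, hand = c("affected", "normal", "left", "right")) {
  hand <- match.arg(hand)
  side <- switch(hand,
    affected = rec$settings$affected_side,
    normal = setdiff(c("left", "right"), rec$settings$affected_side),
    hand)
  pre <- if (side == "left") "lh" else "rh"
  tibble(t = rec$frames$t,
         x = rec$frames[[paste0(pre, "_x")]],
         y = rec$frames[[paste0(pre, "_y")]],
         z = rec$frames[[paste0(pre, "_z")]])
}
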