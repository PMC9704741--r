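#' Construct a session recording
#'
#' A session recording holds the time series of both hands' and the ball's
#' 3-D positions over one training session, together with the ball state,
#' the task settings and subject identity. Coordinates are metres in a
#' right-handed frame: x lateral, y vertical (up), z depth toward the
#' display.
#'
#' @param subject_id Character subject identifier.
#' @param timepoint `"pre"` or `"post"`.
#' @param settings A [task_settings()] object.
#' @param frames Data frame with columns `t`, `lh_x`, `lh_y`, `lh_z`,
#'   `rh_x`, `rh_y`, `rh_z`, `ball_x`, `ball_y`, `ball_z`, `ball_state`
#'   (one of `"idle"`, `"flying"`, `"caught"`, `"missed"`). Times in
#'   seconds from session start, strictly increasing, at least two rows.
#' @param sample_rate_hz Nominal capture rate in Hz.
#'
#' @return An object of class `vr_session`: a list with the fields above,
#'   `frames` stored as a tibble.
#' @seealso [read_session()], [write_session()], [segment_attempts()]
#' @export
vr_session <- function(subject_id, timepoint, settings, frames,
                       sample_rate_hz = 30) {
  rec <- structure(
    list(subject_id = as.character(subject_id),
         timepoint = match.arg(timepoint, c("pre", "post")),
         settings = settings,
         frames = as_tibble(frames),
         sample_rate_hz = sample_rate_hz),
    class = "vr_session"
  )
  validate_session(rec)
}

frame_cols <- c("t", "lh_x", "lh_y", "lh_z", "rh_x", "rh_y", "rh_z",
                "ball_x", "ball_y", "ball_z", "ball_state")
ball_states <- c("idle", "flying", "caught", "missed")

#' Validate a session recording's invariants
#'
#' Checks column presence, strictly increasing non-negative times, finite
#' positions, known ball states, and that every `caught`/`missed` state is
#' preceded by a `flying` state. Errors name the first offending row.
#'
#' @param rec A `vr_session`.
#' @return `rec`, invisibly unchanged, if valid.
#' @export
validate_session <- function(rec) {
  if (!inherits(rec, "vr_session")) abort("not a `vr_session` object")
  if (!inherits(rec$settings, "vr_task_settings")) {
    abort("`settings` must be a `vr_task_settings` object")
  }
  fr <- rec$frames
  missing_cols <- setdiff(frame_cols, names(fr))
  if (length(missing_cols)) {
    format_error("frames are missing column(s): %s",
                 paste(missing_cols, collapse = ", "))
  }
  if (nrow(fr) < 2L) format_error("a session needs at least 2 frames")
  if (!is_number(rec$sample_rate_hz) || rec$sample_rate_hz <= 0) {
    format_error("`sample_rate_hz` must be a positive number")
  }
  if (fr$t[1] < 0) format_error("negative time at row 1")
  dt <- diff(fr$t)
  if (any(dt <= 0)) {
    format_error("frame times not strictly increasing at row %d",
                 which(dt <= 0)[1] + 1L)
  }
  pos <- as.matrix(fr[, c("lh_x", "lh_y", "lh_z", "rh_x", "rh_y", "rh_z",
                          "ball_x", "ball_y", "ball_z")])
  if (!all(is.finite(pos))) {
    format_error("non-finite position at row %d",
                 which(!apply(is.finite(pos), 1, all))[1])
  }
  bad <- which(!fr$ball_state %in% ball_states)
  if (length(bad)) {
    format_error("unknown ball_state '%s' at row %d", fr$ball_state[bad[1]],
                 bad[1])
  }
  outcome <- fr$ball_state %in% c("caught", "missed")
  if (outcome[1]) format_error("row 1 has outcome state without prior flight")
  prev <- fr$ball_state[-nrow(fr)]
  cur <- fr$ball_state[-1]
  bad <- which(cur %in% c("caught", "missed") &
                 !(prev == "flying" | prev == cur))
  if (length(bad)) {
    format_error("outcome state not preceded by a flying state at row %d",
                 bad[1] + 1L)
  }
  invisible(rec)
}

#' @export
print.vr_session <- function(x, ...) {
  cat(sprintf(
    "<vr_session> subject %s (%s), %d frames @ %g Hz, %.1f s, affected %s\n",
    x$subject_id, x$timepoint, nrow(x$frames), x$sample_rate_hz,
    max(x$frames$t), x$settings$affected_side))
  invisible(x)
}

fmt_num <- function(x) sprintf("%.17g", x)

#' Write a session recording to disk
#'
#' Writes a frames CSV plus a JSON metadata sidecar. Output is bit-stable:
#' fixed column order and fixed float formatting, so re-writing the same
#' recording yields byte-identical files and golden-file tests can compare
#' exactly. Numbers are written with 17 significant digits so that
#' `read_session(write_session(rec))` reproduces `rec` exactly.
#'
#' @param rec A valid `vr_session`.
#' @param path Output stem or CSV path: `"dir/s01_pre"` (or
#'   `"dir/s01_pre.csv"`) produces `dir/s01_pre.csv` and
#'   `dir/s01_pre.json`.
#' @return The CSV path, invisibly.
#' @export
write_session <- function(rec, path) {
  validate_session(rec)
  stem <- sub("\\.csv$", "", path)
  fr <- rec$frames
  num <- vapply(frame_cols[1:10], function(cl) fmt_num(fr[[cl]]),
                character(nrow(fr)))
  if (nrow(fr) == 1L) num <- matrix(num, nrow = 1L)  # unreachable: >=2 frames
  lines <- c(paste(frame_cols, collapse = ","),
             paste(apply(num, 1, paste, collapse = ","), fr$ball_state,
                   sep = ","))
  csv_path <- paste0(stem, ".csv")
  con <- file(csv_path, open = "wb")
  on.exit(close(con), add = TRUE)
  writeLines(lines, con, sep = "\n")
  meta <- list(
    subject_id = rec$subject_id,
    timepoint = rec$timepoint,
    sample_rate_hz = rec$sample_rate_hz,
    settings = list(
      # stored as integer ninths so the fraction survives JSON exactly
      gravity_ninths = as.integer(round(rec$settings$gravity_fraction * 9)),
      range_mode = rec$settings$range_mode,
      target_catches = rec$settings$target_catches,
      arm_length_m = rec$settings$arm_length_m,
      affected_side = rec$settings$affected_side
    )
  )
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(csv_path)
}

#' Read a session recording from disk
#'
#' Reads the frames CSV + JSON sidecar written by [write_session()] and
#' validates every recording invariant; malformed input raises a format
#' error naming the offending row.
#'
#' @param path Stem or CSV path (see [write_session()]).
#' @return A validated `vr_session`.
#' @export
read_session <- function(path) {
  stem <- sub("\\.csv$", "", path)
  csv_path <- paste0(stem, ".csv")
  json_path <- paste0(stem, ".json")
  if (!file.exists(csv_path)) format_error("no frames CSV at '%s'", csv_path)
  if (!file.exists(json_path)) {
    format_error("no metadata sidecar at '%s'", json_path)
  }
  fr <- read.csv(csv_path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(frame_cols, names(fr))
  if (length(missing_cols)) {
    format_error("malformed header in '%s': missing %s", csv_path,
                 paste(missing_cols, collapse = ", "))
  }
  # extra columns (e.g. elbow/shoulder joints) are accepted but ignored
  fr <- as_tibble(fr[, frame_cols])
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  settings <- task_settings(
    gravity_fraction = meta$settings$gravity_ninths / 9,
    range_mode = as.numeric(meta$settings$range_mode),
    target_catches = meta$settings$target_catches,
    arm_length_m = as.numeric(meta$settings$arm_length_m),
    affected_side = meta$settings$affected_side
  )
  vr_session(subject_id = meta$subject_id, timepoint = meta$timepoint,
             settings = settings, frames = fr,
             sample_rate_hz = as.numeric(meta$sample_rate_hz))
}

scale_max <- c(fma = 22, tempa = 27, wmft = 5)

#' Read a clinical scales table
#'
#' Reads a CSV with columns `subject`, `timepoint`, `fma`, `tempa`, `wmft`
#' and validates the printed score ranges (FMA 0-22, TEMPA 0-27, WMFT 0-5).
#' An out-of-range score raises an error naming the subject and scale.
#'
#' @param path CSV path.
#' @return A tibble with one row per subject x timepoint.
#' @seealso [simulate_scales()], [kmeans_scales()]
#' @export
read_scales <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "timepoint", "fma", "tempa", "wmft")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    format_error("scales CSV missing column(s): %s",
                 paste(missing_cols, collapse = ", "))
  }
  df <- as_tibble(df[, need])
  validate_scales(df)
}

#' Validate a scales table against the scale score ranges
#'
#' @param df Data frame with `subject`, `timepoint`, `fma`, `tempa`, `wmft`.
#' @return The validated tibble.
#' @export
validate_scales <- function(df) {
  df <- as_tibble(df)
  bad_tp <- which(!df$timepoint %in% c("pre", "post"))
  if (length(bad_tp)) {
    format_error("subject %s: timepoint '%s' is not pre/post",
                 df$subject[bad_tp[1]], df$timepoint[bad_tp[1]])
  }
  for (sc in names(scale_max)) {
    v <- df[[sc]]
    if (!is.numeric(v)) format_error("scale %s is not numeric", sc)
    bad <- which(is.na(v) | v < 0 | v > scale_max[[sc]])
    if (length(bad)) {
      format_error("subject %s: %s score %s outside [0, %d]",
                   df$subject[bad[1]], sc, format(v[bad[1]]),
                   scale_max[[sc]])
    }
  }
  df
}

#' Write a clinical scales table
#'
#' Deterministic counterpart of [read_scales()]: fixed column order and
#' number formatting, so identical tables yield byte-identical files.
#'
#' @param df Validated scales table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_scales <- function(df, path) {
  df <- validate_scales(df)
  lines <- c("subject,timepoint,fma,tempa,wmft",
             sprintf("%s,%s,%s,%s,%s", df$subject, df$timepoint,
                     fmt_num(df$fma), fmt_num(df$tempa), fmt_num(df$wmft)))
  con <- file(path, open = "wb")
  on.exit(close(con), add = TRUE)
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
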