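#' @importFrom rlang .data
#' @importFrom dplyr %>%
NULL

# canonical column order of a sample stream tibble
stream_cols <- c(
  "t", "x_l", "y_l", "x_r", "y_r",
  "pupil_l", "pupil_r", "valid_l", "valid_r", "status"
)

new_sample_stream <- function(df) {
  stopifnot(all(stream_cols %in% names(df)))
  tibble::as_tibble(df[, stream_cols])
}

#' Read a raw gaze sample file
#'
#' Reads the tab-separated sample dialect written by the tracker export (and
#' by [simulate_cohort()]): columns `time`, `gaze_x_left`, `gaze_y_left`,
#' `gaze_x_right`, `gaze_y_right`, `pupil_left`, `pupil_right`,
#' `validity_left`, `validity_right` (1 = valid). Timestamp units
#' (microseconds vs milliseconds) are auto-detected from the median
#' inter-sample difference and can be forced. Samples with an invalid
#' validity flag or absent coordinates in both eyes get status `"missing"`;
#' everything else is `"valid"`. Samples are never reordered.
#'
#' @param path Path to the TSV file.
#' @param geometry A [screen_geometry()] (kept with the stream as an
#'   attribute for later angular conversions).
#' @param time_unit `"auto"` (default), `"us"`, `"ms"`, or `"s"`.
#' @param quiet Suppress the log line about the detected unit.
#' @return A sample-stream tibble with columns `t` (seconds), per-eye
#'   `x_l/y_l/x_r/y_r` (px), `pupil_l/pupil_r` (mm), `valid_l/valid_r`,
#'   and `status`.
#' @export
read_gaze_file <- function(path, geometry = screen_geometry(),
                           time_unit = "auto", quiet = FALSE) {
  raw <- utils::read.delim(path, check.names = FALSE)
  required <- c("time", "gaze_x_left", "gaze_y_left", "gaze_x_right",
                "gaze_y_right", "pupil_left", "pupil_right",
                "validity_left", "validity_right")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("gaze file lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  extra <- setdiff(names(raw), required)
  if (length(extra) && !quiet) {
    message("ignoring unknown columns: ", paste(extra, collapse = ", "))
  }
  tt <- as.numeric(raw$time)
  if (any(diff(tt) <= 0)) {
    bad <- which(diff(tt) <= 0)[1] + 1L
    stop("non-monotone timestamps: first offending row ", bad)
  }
  if (time_unit == "auto") {
    dt <- stats::median(diff(tt))
    # 300 Hz: ~3333 in us, ~3.33 in ms, ~0.0033 in s
    time_unit <- if (dt > 100) "us" else if (dt > 0.1) "ms" else "s"
    if (!quiet) message("detected timestamp unit: ", time_unit)
  }
  scale <- switch(time_unit, us = 1e-6, ms = 1e-3, s = 1,
                  stop("unknown time unit: ", time_unit))
  valid_l <- as.logical(raw$validity_left) &
    is.finite(raw$gaze_x_left) & is.finite(raw$gaze_y_left)
  valid_r <- as.logical(raw$validity_right) &
    is.finite(raw$gaze_x_right) & is.finite(raw$gaze_y_right)
  out <- tibble::tibble(
    t = tt * scale,
    x_l = ifelse(valid_l, raw$gaze_x_left, NA_real_),
    y_l = ifelse(valid_l, raw$gaze_y_left, NA_real_),
    x_r = ifelse(valid_r, raw$gaze_x_right, NA_real_),
    y_r = ifelse(valid_r, raw$gaze_y_right, NA_real_),
    pupil_l = ifelse(valid_l & is.finite(raw$pupil_left),
                     raw$pupil_left, NA_real_),
    pupil_r = ifelse(valid_r & is.finite(raw$pupil_right),
                     raw$pupil_right, NA_real_),
    valid_l = valid_l,
    valid_r = valid_r,
    status = ifelse(valid_l | valid_r, "valid", "missing")
  )
  attr(out, "geometry") <- geometry
  out
}

#' Write a sample stream in the raw gaze dialect
#'
#' Inverse of [read_gaze_file()]; timestamps are written in microseconds.
#' Used by the synthetic-session generator so that simulated cohorts pass
#' through exactly the same reader as real exports.
#'
#' @param stream A sample-stream tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gaze_file <- function(stream, path) {
  out <- data.frame(
    time = round(stream$t * 1e6),
    gaze_x_left = stream$x_l, gaze_y_left = stream$y_l,
    gaze_x_right = stream$x_r, gaze_y_right = stream$y_r,
    pupil_left = stream$pupil_l, pupil_right = stream$pupil_r,
    validity_left = as.integer(stream$valid_l),
    validity_right = as.integer(stream$valid_r)
  )
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

#' Segment a sample stream into trials
#'
#' Each trial spans the half-open window `[onset, onset + trial_duration)`.
#' Samples outside all trials are discarded; within-trial time is re-based
#' so that 0 is the attention-grabber onset. A trial whose window extends
#' past the end of the stream is kept but marked dropped with reason
#' `"truncated"`. Overlapping trial windows are rejected.
#'
#' @param stream Sample-stream tibble from [read_gaze_file()].
#' @param trial_log Tibble/data frame with columns `trial`, `onset_s` and
#'   condition labels (`cueing`, `stimulus`, `target_side`) if available.
#' @param paradigm A [paradigm_spec()].
#' @return A nested tibble: one row per trial with the condition labels,
#'   `onset_s`, `dropped`, `drop_reason`, and a `samples` list-column whose
#'   elements carry trial-local `t`.
#' @export
segment_trials <- function(stream, trial_log, paradigm = paradigm_spec()) {
  trial_log <- tibble::as_tibble(trial_log)
  stopifnot(all(c("trial", "onset_s") %in% names(trial_log)))
  dur <- paradigm$trial_duration
  ord <- order(trial_log$onset_s)
  onsets <- trial_log$onset_s[ord]
  if (any(diff(onsets) < dur)) stop("overlapping trial windows")
  t_end <- max(stream$t)
  seg_one <- function(onset) {
    sl <- stream[stream$t >= onset & stream$t < onset + dur, , drop = FALSE]
    sl$t <- sl$t - onset
    sl
  }
  out <- trial_log
  out$samples <- lapply(trial_log$onset_s, seg_one)
  truncated <- trial_log$onset_s + dur > t_end + 1 / paradigm$sampling_rate
  out$dropped <- truncated
  out$drop_reason <- ifelse(truncated, "truncated", NA_character_)
  tibble::as_tibble(out)
}

#' Write the per-trial features table
#'
#' Stable column order; round-trips exactly for logical flags and to
#' numerical precision for floats. Duplicate (participant, timepoint, trial)
#' keys are an error.
#'
#' @param features Tibble of per-trial features ([assemble_trial_features()]
#'   rows, or any table containing at least `participant`, `timepoint`,
#'   `trial`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_features_table <- function(features, path) {
  lead <- c("participant", "timepoint", "trial")
  stopifnot(all(lead %in% names(features)))
  key <- do.call(paste, c(features[lead], sep = "\r"))
  if (anyDuplicated(key)) {
    stop("duplicate (participant, timepoint, trial) keys in features table")
  }
  ordered <- features[, c(lead, setdiff(names(features), lead))]
  readr::write_csv(ordered, path, na = "")
  invisible(path)
}

#' Read a per-trial features table written by [write_features_table()]
#' @param path CSV path.
#' @return Tibble.
#' @export
read_features_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read an AOI geometry file
#'
#' CSV with columns `aoi`, `x0`, `y0`, `x1`, `y1`, `active_phase`, the same
#' layout [aoi_default()] returns.
#'
#' @param path CSV path.
#' @return AOI tibble.
#' @export
read_aoi_file <- function(path) {
  aois <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("aoi", "x0", "y0", "x1", "y1") %in% names(aois)))
  if (any(aois$x1 <= aois$x0 | aois$y1 <= aois$y0)) {
    stop("degenerate AOI region")
  }
  aois
}
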