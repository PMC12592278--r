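#' Cleaning configuration for gaze streams
#'
#' Holds every tunable of the preprocessing chain. Defaults follow the
#' published pipeline: blinks are tracking-loss gaps of 75-250 ms padded by
#' 25 ms, gaze samples moving faster than 1000 deg/s or accelerating faster
#' than 10000 deg/s^2 are implausible, smoothing is Savitzky-Golay with a
#' 70 ms window (order 3), fixations require stability below 1 deg/s (or a
#' 1 deg dispersion, see `fixation_criterion`) for at least 100 ms, and
#' trials retaining less than 50% of samples are dropped.
#'
#' @param blink_min_ms,blink_max_ms Blink duration band in ms.
#' @param blink_pad_ms Margin excluded before and after each blink, ms.
#' @param max_velocity Plausibility limit, deg/s.
#' @param max_acceleration Plausibility limit, deg/s^2.
#' @param sg_window_ms Savitzky-Golay window length in ms (rounded to an odd
#'   number of samples).
#' @param sg_order Savitzky-Golay polynomial order.
#' @param fixation_max_velocity Stability limit for fixation samples, deg/s.
#' @param fixation_dispersion_deg Dispersion limit (position range within a
#'   100 ms sliding window) used when `fixation_criterion = "dispersion"`.
#' @param fixation_min_ms Minimum fixation duration, ms.
#' @param fixation_criterion `"velocity"` (as printed in the source
#'   pipeline) or `"dispersion"` (robust alternative for noisy data).
#' @param min_valid_fraction Minimum retained-sample fraction for a trial.
#' @param pt_initial Initial peak-velocity threshold for the adaptive
#'   saccade detector, deg/s.
#' @param pt_sd_mult Multiplier k in mean + k*SD for the peak threshold.
#' @param onset_sd_mult Multiplier for the onset/offset threshold.
#' @param pt_tol Convergence tolerance of the adaptive iteration, deg/s.
#' @param pt_max_iter Iteration cap.
#' @param pt_floor Lower bound returned for degenerate (zero-variance)
#'   velocity input, deg/s.
#' @param saccade_min_ms Minimum saccade duration, ms.
#' @param saccade_merge_ms Minimum inter-saccade interval, ms; detected
#'   saccades separated by shorter gaps are merged into one event (smoothing
#'   can split a single movement into a main peak with small shoulders, and
#'   true saccades cannot follow each other this quickly).
#' @return A list of class `cleaning_config`.
#' @export
cleaning_config <- function(blink_min_ms = 75, blink_max_ms = 250,
                            blink_pad_ms = 25,
                            max_velocity = 1000, max_acceleration = 10000,
                            sg_window_ms = 70, sg_order = 3,
                            fixation_max_velocity = 1,
                            fixation_dispersion_deg = 1,
                            fixation_min_ms = 100,
                            fixation_criterion = c("velocity", "dispersion"),
                            min_valid_fraction = 0.5,
                            pt_initial = 100, pt_sd_mult = 6,
                            onset_sd_mult = 3, pt_tol = 1, pt_max_iter = 50,
                            pt_floor = 10, saccade_min_ms = 10,
                            saccade_merge_ms = 40) {
  fixation_criterion <- match.arg(fixation_criterion)
  stopifnot(blink_min_ms > 0, blink_min_ms < blink_max_ms, blink_pad_ms >= 0,
            max_velocity > 0, max_acceleration > 0, sg_window_ms > 0,
            fixation_min_ms > 0, min_valid_fraction >= 0,
            pt_initial > 0, pt_tol > 0)
  structure(as.list(environment()), class = "cleaning_config")
}

# --- run-length helpers -----------------------------------------------------

# maximal runs of TRUE in a logical vector -> tibble(start, end) of indices
runs_of <- function(flag) {
  flag[is.na(flag)] <- FALSE
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble::tibble(start = starts[keep], end = ends[keep])
}

sample_dt <- function(samples) {
  if (nrow(samples) < 2) return(NA_real_)
  stats::median(diff(samples$t))
}

#' Relabel blink gaps
#'
#' Contiguous missing runs whose duration falls in the blink band (default
#' 75-250 ms, inclusive) are relabelled `"blink"`, and valid samples within
#' the pad (default 25 ms) before and after such a run are relabelled
#' `"blink"` too, excluding the half-closed eyelid transients. Missing runs
#' outside the band are left as `"missing"`.
#'
#' @param samples A trial's sample tibble (statuses `valid`/`missing`).
#' @param cfg A [cleaning_config()].
#' @return The sample tibble with updated `status`.
#' @export
correct_blinks <- function(samples, cfg = cleaning_config()) {
  dt <- sample_dt(samples)
  if (is.na(dt)) return(samples)
  miss <- runs_of(samples$status == "missing")
  if (!nrow(miss)) return(samples)
  n <- nrow(samples)
  # "within 25 ms": samples at most blink_pad_ms from the gap (7 at 300 Hz)
  pad_n <- floor(cfg$blink_pad_ms / 1000 / dt + 1e-6)
  status <- samples$status
  for (i in seq_len(nrow(miss))) {
    len_ms <- (miss$end[i] - miss$start[i] + 1L) * dt * 1000
    # half-sample tolerance: durations are quantized to the sampling grid
    if (len_ms >= cfg$blink_min_ms - 1e-6 &&
        len_ms <= cfg$blink_max_ms + 1e-6) {
      lo <- max(1L, miss$start[i] - pad_n)
      hi <- min(n, miss$end[i] + pad_n)
      status[lo:hi] <- "blink"
    }
  }
  samples$status <- status
  samples
}

#' Combine the two eyes' gaze signals
#'
#' Adds combined `x`/`y` columns: the mean of both eyes where both are
#' valid, the single valid eye otherwise, `NA` where neither. Pupil size is
#' combined separately (see [combine_eyes()]) because its cleaning chain is
#' per eye.
#'
#' @param samples A trial's sample tibble.
#' @return The tibble with `x` and `y` columns added.
#' @export
combine_gaze <- function(samples) {
  both <- samples$valid_l & samples$valid_r
  x <- ifelse(both, (samples$x_l + samples$x_r) / 2,
              ifelse(samples$valid_l, samples$x_l,
                     ifelse(samples$valid_r, samples$x_r, NA_real_)))
  y <- ifelse(both, (samples$y_l + samples$y_r) / 2,
              ifelse(samples$valid_l, samples$y_l,
                     ifelse(samples$valid_r, samples$y_r, NA_real_)))
  samples$x <- x
  samples$y <- y
  samples
}

# raw sample-to-sample velocity (deg/s), assigned to the arriving sample;
# NA outside contiguous valid runs
raw_velocity <- function(samples, geometry) {
  n <- nrow(samples)
  v <- rep(NA_real_, n)
  ok <- samples$status == "valid" & is.finite(samples$x)
  idx <- which(ok[-1] & ok[-n]) + 1L
  if (length(idx)) {
    dt <- samples$t[idx] - samples$t[idx - 1L]
    amp <- px_to_deg(samples$x[idx] - samples$x[idx - 1L],
                     samples$y[idx] - samples$y[idx - 1L], geometry)
    v[idx] <- amp / dt
  }
  v
}

#' Drop physiologically implausible gaze samples
#'
#' Computed on the raw (pre-smoothing) combined gaze signal:
#' sample-to-sample velocity above `max_velocity` (1000 deg/s) or
#' sample-to-sample acceleration above `max_acceleration` (10000 deg/s^2)
#' marks the arriving sample `"implausible"`. Velocities are never computed
#' across gaps.
#'
#' @param samples A trial's sample tibble with combined gaze columns
#'   (see [combine_gaze()]).
#' @param cfg A [cleaning_config()].
#' @param geometry A [screen_geometry()].
#' @return The tibble with updated `status`.
#' @export
drop_implausible <- function(samples, cfg = cleaning_config(),
                             geometry = screen_geometry()) {
  v <- raw_velocity(samples, geometry)
  n <- length(v)
  a <- rep(NA_real_, n)
  if (n > 1) {
    dv <- diff(v)
    dt <- diff(samples$t)
    a[-1] <- dv / dt
  }
  bad <- (!is.na(v) & v > cfg$max_velocity) |
    (!is.na(a) & abs(a) > cfg$max_acceleration)
  samples$status[bad & samples$status == "valid"] <- "implausible"
  samples
}

#' Smooth gaze coordinates with a Savitzky-Golay filter
#'
#' Applied per axis within contiguous valid runs only, never across blinks
#' or other gaps. Runs shorter than the window are left unsmoothed. Window
#' length is `sg_window_ms` converted to samples and forced odd (21 samples
#' at 300 Hz for the default 70 ms).
#'
#' @inheritParams drop_implausible
#' @return The tibble with `x`/`y` replaced by their smoothed versions.
#' @export
smooth_gaze <- function(samples, cfg = cleaning_config()) {
  dt <- sample_dt(samples)
  if (is.na(dt)) return(samples)
  n_win <- round(cfg$sg_window_ms / 1000 / dt)
  if (n_win %% 2 == 0) n_win <- n_win + 1L
  if (n_win <= cfg$sg_order + 1) return(samples)
  runs <- runs_of(samples$status == "valid")
  for (i in seq_len(nrow(runs))) {
    idx <- runs$start[i]:runs$end[i]
    if (length(idx) < n_win) next
    samples$x[idx] <- signal::sgolayfilt(samples$x[idx], p = cfg$sg_order,
                                         n = n_win)
    samples$y[idx] <- signal::sgolayfilt(samples$y[idx], p = cfg$sg_order,
                                         n = n_win)
  }
  samples
}

#' Angular velocity and acceleration of the gaze signal
#'
#' Central-difference velocity of the (smoothed) combined gaze position,
#' expressed in degrees of visual angle per second, and its
#' central-difference acceleration. Undefined (NA) at run edges and across
#' gaps; gaps are never interpolated.
#'
#' @inheritParams drop_implausible
#' @return The tibble with `vel_deg_s` and `acc_deg_s2` columns.
#' @export
compute_velocity <- function(samples, geometry = screen_geometry()) {
  n <- nrow(samples)
  v <- rep(NA_real_, n)
  ok <- samples$status == "valid" & is.finite(samples$x)
  if (n >= 3) {
    mid <- which(ok[-c(1, 2)] & ok[-c(n - 1, n)] & ok[2:(n - 1)]) + 1L
    if (length(mid)) {
      dt2 <- samples$t[mid + 1L] - samples$t[mid - 1L]
      amp <- px_to_deg(samples$x[mid + 1L] - samples$x[mid - 1L],
                       samples$y[mid + 1L] - samples$y[mid - 1L], geometry)
      v[mid] <- amp / dt2
    }
  }
  a <- rep(NA_real_, n)
  if (n >= 3) {
    va <- which(!is.na(v[-c(1, 2)]) & !is.na(v[-c(n - 1, n)])) + 1L
    if (length(va)) {
      dt2 <- samples$t[va + 1L] - samples$t[va - 1L]
      a[va] <- (v[va + 1L] - v[va - 1L]) / dt2
    }
  }
  samples$vel_deg_s <- v
  samples$acc_deg_s2 <- a
  samples
}

#' Trial data-quality summary
#'
#' @param samples A cleaned trial sample tibble.
#' @param cfg A [cleaning_config()].
#' @return A one-row tibble with `missing_fraction` (share of samples whose
#'   status is not `"valid"`) and `dropped` (TRUE when the retained fraction
#'   falls below `min_valid_fraction`; a trial retaining exactly half its
#'   data is kept).
#' @export
trial_quality <- function(samples, cfg = cleaning_config()) {
  mf <- mean(samples$status != "valid")
  tibble::tibble(
    missing_fraction = mf,
    dropped = (1 - mf) < cfg$min_valid_fraction
  )
}
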