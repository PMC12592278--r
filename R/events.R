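#' Adaptive data-driven saccade threshold
#'
#' Iterative noise-adaptive scheme: starting from `pt_initial` (100 deg/s),
#' the peak threshold is repeatedly set to `mean + 6*SD` of all velocity
#' samples below the current threshold, until successive thresholds differ
#' by less than 1 deg/s (or 50 iterations). The saccade onset/offset
#' threshold is `mean + 3*SD` of the same sub-threshold samples. Because
#' the sub-threshold pool tracks each trial's own noise level, the
#' threshold adapts to intra- and inter-individual noise differences.
#'
#' @param velocity Numeric vector of angular velocities (deg/s); NAs
#'   ignored.
#' @param cfg A [cleaning_config()].
#' @return A list with `peak` (deg/s), `onset` (deg/s), `iterations`, and
#'   `degenerate` (TRUE when the velocity pool had no variance and the
#'   configured floor was returned).
#' @export
adaptive_saccade_threshold <- function(velocity, cfg = cleaning_config()) {
  v <- velocity[is.finite(velocity)]
  if (length(v) < 30) {
    return(list(peak = cfg$pt_initial, onset = cfg$pt_initial / 2,
                iterations = 0L, degenerate = TRUE))
  }
  pt <- cfg$pt_initial
  it <- 0L
  repeat {
    it <- it + 1L
    sub <- v[v < pt]
    if (!length(sub)) break
    new_pt <- mean(sub) + cfg$pt_sd_mult * stats::sd(sub)
    if (is.na(new_pt)) new_pt <- pt
    if (abs(new_pt - pt) < cfg$pt_tol || it >= cfg$pt_max_iter) {
      pt <- new_pt
      break
    }
    pt <- new_pt
  }
  sub <- v[v < pt]
  onset <- if (length(sub) > 1) mean(sub) + cfg$onset_sd_mult * stats::sd(sub) else 0
  degenerate <- !is.finite(pt) || pt < cfg$pt_floor
  if (degenerate) {
    # noise-free or near-constant input: fall back to the configured floor
    # for both thresholds so event extension still terminates
    pt <- cfg$pt_floor
    onset <- pt / 2
  }
  list(peak = pt, onset = onset, iterations = it, degenerate = degenerate)
}

#' Detect saccades from the velocity trace
#'
#' A saccade is a maximal run of samples at or above the peak threshold,
#' extended backward and forward while the velocity stays above the
#' onset/offset threshold. Runs shorter than `saccade_min_ms` (10 ms) are
#' discarded. Amplitude is the angular distance between the end positions;
#' peak velocity is the maximum over the event.
#'
#' @param samples Trial sample tibble with `vel_deg_s` (see
#'   [compute_velocity()]).
#' @param thresholds Result of [adaptive_saccade_threshold()].
#' @param cfg A [cleaning_config()].
#' @param geometry A [screen_geometry()].
#' @return Tibble of events: `kind`, `onset`, `offset` (trial-local s),
#'   `duration`, `amplitude_deg`, `peak_vel`.
#' @export
detect_saccades <- function(samples, thresholds, cfg = cleaning_config(),
                            geometry = screen_geometry()) {
  v <- samples$vel_deg_s
  n <- nrow(samples)
  empty <- tibble::tibble(kind = character(), onset = numeric(),
                          offset = numeric(), duration = numeric(),
                          amplitude_deg = numeric(), peak_vel = numeric())
  peaks <- runs_of(!is.na(v) & v >= thresholds$peak)
  if (!nrow(peaks)) return(empty)
  above_onset <- !is.na(v) & v > thresholds$onset
  lo <- integer(nrow(peaks))
  hi <- integer(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    s <- peaks$start[i]
    while (s > 1 && above_onset[s - 1L]) s <- s - 1L
    e <- peaks$end[i]
    while (e < n && above_onset[e + 1L]) e <- e + 1L
    lo[i] <- s
    hi[i] <- e
  }
  # merge overlapping extended runs and runs closer than the minimum
  # inter-saccade interval
  keep <- !duplicated(paste(lo, hi))
  lo <- lo[keep]; hi <- hi[keep]
  dt <- sample_dt(samples)
  merge_gap <- round(cfg$saccade_merge_ms / 1000 / dt)
  if (length(lo) > 1) {
    merged_lo <- lo[1]; merged_hi <- hi[1]
    for (i in 2:length(lo)) {
      j <- length(merged_hi)
      if (lo[i] <= merged_hi[j] + merge_gap) {
        merged_hi[j] <- max(merged_hi[j], hi[i])
      } else {
        merged_lo <- c(merged_lo, lo[i])
        merged_hi <- c(merged_hi, hi[i])
      }
    }
    lo <- merged_lo; hi <- merged_hi
  }
  out <- purrr::map_dfr(seq_along(lo), function(i) {
    idx <- lo[i]:hi[i]
    dur <- length(idx) * dt
    tibble::tibble(
      kind = "saccade",
      onset = samples$t[lo[i]],
      offset = samples$t[hi[i]] + dt,
      duration = dur,
      amplitude_deg = px_to_deg(samples$x[hi[i]] - samples$x[lo[i]],
                                samples$y[hi[i]] - samples$y[lo[i]],
                                geometry),
      peak_vel = max(samples$vel_deg_s[idx], na.rm = TRUE)
    )
  })
  out[out$duration >= cfg$saccade_min_ms / 1000, , drop = FALSE]
}

# per-sample stability flag for fixation classification
stability_flag <- function(samples, cfg, geometry) {
  n <- nrow(samples)
  if (cfg$fixation_criterion == "velocity") {
    v <- samples$vel_deg_s
    # undefined velocity at run edges carries no evidence of motion
    stable <- is.na(v) | v < cfg$fixation_max_velocity
  } else {
    half_n <- max(1L, round(0.05 / sample_dt(samples)))
    stable <- rep(TRUE, n)
    x <- samples$x
    y <- samples$y
    for (i in seq_len(n)) {
      lo <- max(1L, i - half_n)
      hi <- min(n, i + half_n)
      idx <- lo:hi
      idx <- idx[samples$status[idx] == "valid"]
      if (length(idx) < 2) next
      rng <- px_to_deg(max(x[idx]) - min(x[idx]),
                       max(y[idx]) - min(y[idx]), geometry)
      stable[i] <- rng < cfg$fixation_dispersion_deg
    }
  }
  stable
}

#' Classify fixations
#'
#' Fixations are maximal runs of samples that are (a) outside every saccade
#' interval, (b) status-valid, (c) stable under the configured criterion --
#' smoothed angular velocity below 1 deg/s by default, or position range
#' below 1 deg within a 100 ms sliding window in `"dispersion"` mode -- and
#' (d) at least 100 ms long. Shorter stable runs are left unlabelled.
#'
#' @param samples Trial sample tibble with velocity columns.
#' @param saccades Saccade events from [detect_saccades()].
#' @param cfg A [cleaning_config()].
#' @param geometry A [screen_geometry()].
#' @return Tibble of events: `kind`, `onset`, `offset`, `duration`,
#'   `cx_px`, `cy_px` (centroid).
#' @export
detect_fixations <- function(samples, saccades, cfg = cleaning_config(),
                             geometry = screen_geometry()) {
  n <- nrow(samples)
  in_saccade <- rep(FALSE, n)
  for (i in seq_len(nrow(saccades))) {
    in_saccade <- in_saccade |
      (samples$t >= saccades$onset[i] & samples$t < saccades$offset[i])
  }
  candidate <- samples$status == "valid" & !in_saccade
  candidate <- candidate & stability_flag(samples, cfg, geometry)
  runs <- runs_of(candidate)
  dt <- sample_dt(samples)
  if (!nrow(runs)) {
    return(tibble::tibble(kind = character(), onset = numeric(),
                          offset = numeric(), duration = numeric(),
                          cx_px = numeric(), cy_px = numeric()))
  }
  out <- purrr::map_dfr(seq_len(nrow(runs)), function(i) {
    idx <- runs$start[i]:runs$end[i]
    tibble::tibble(
      kind = "fixation",
      onset = samples$t[runs$start[i]],
      offset = samples$t[runs$end[i]] + dt,
      duration = length(idx) * dt,
      cx_px = mean(samples$x[idx]),
      cy_px = mean(samples$y[idx])
    )
  })
  out[out$duration >= cfg$fixation_min_ms / 1000 - 1e-9, , drop = FALSE]
}

#' Run the full gaze event-detection chain on one trial
#'
#' Convenience wrapper applying, in order: binocular gaze combination,
#' blink correction, plausibility filtering, Savitzky-Golay smoothing,
#' velocity computation, adaptive thresholding, saccade detection, and
#' fixation classification.
#'
#' @param samples Raw trial sample tibble (statuses valid/missing).
#' @param cfg A [cleaning_config()].
#' @param geometry A [screen_geometry()].
#' @return A list with `samples` (cleaned, with velocity), `events`
#'   (saccades and fixations bound together, time-ordered), `thresholds`,
#'   and `quality` (from [trial_quality()]).
#' @export
detect_gaze_events <- function(samples, cfg = cleaning_config(),
                               geometry = screen_geometry()) {
  samples <- combine_gaze(samples)
  samples <- correct_blinks(samples, cfg)
  samples <- drop_implausible(samples, cfg, geometry)
  samples <- smooth_gaze(samples, cfg)
  samples <- compute_velocity(samples, geometry)
  thresholds <- adaptive_saccade_threshold(samples$vel_deg_s, cfg)
  saccades <- detect_saccades(samples, thresholds, cfg, geometry)
  fixations <- detect_fixations(samples, saccades, cfg, geometry)
  events <- dplyr::bind_rows(saccades, fixations)
  events <- events[order(events$onset), , drop = FALSE]
  list(
    samples = samples,
    events = tibble::as_tibble(events),
    thresholds = thresholds,
    quality = trial_quality(samples, cfg)
  )
}
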