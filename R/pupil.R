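#' Pupillometry cleaning and feature configuration
#'
#' @param min_mm,max_mm Plausible pupil diameter range; values outside the
#'   open interval (2, 8) mm are dropped.
#' @param mad_multiplier Rolling-median outlier gate: samples deviating by
#'   more than this multiple of the window MAD are dropped.
#' @param mad_window_ms Rolling window for the median/MAD filter, ms.
#' @param interpolation_max_ms Longest gap bridged by linear interpolation,
#'   ms (150 as published); longer gaps stay missing.
#' @param bps_window Baseline window `[t0, t1)` in trial-local seconds
#'   (first half of the attention-grabber phase).
#' @param sepr_window Evoked-response window `[t0, t1)` in trial-local
#'   seconds (during target cueing).
#' @param min_coverage Minimum fraction of valid samples a window needs for
#'   its feature to be computed.
#' @return A list of class `pupil_config`.
#' @export
pupil_config <- function(min_mm = 2, max_mm = 8, mad_multiplier = 3,
                         mad_window_ms = 150, interpolation_max_ms = 150,
                         bps_window = c(0, 0.5), sepr_window = c(4.5, 5.5),
                         min_coverage = 0.5) {
  stopifnot(min_mm < max_mm, mad_multiplier > 0, interpolation_max_ms >= 0,
            bps_window[1] < bps_window[2], sepr_window[1] < sepr_window[2])
  structure(as.list(environment()), class = "pupil_config")
}

# clean one eye's pupil vector in place; returns the cleaned vector
clean_pupil_eye <- function(p, t, blink_mask, cfg) {
  dt <- stats::median(diff(t))
  p[blink_mask] <- NA_real_
  # (1) plausible range (open interval)
  p[!is.na(p) & (p <= cfg$min_mm | p >= cfg$max_mm)] <- NA_real_
  # (2) rolling-median / MAD outlier gate
  half_n <- max(1L, round(cfg$mad_window_ms / 1000 / dt / 2))
  n <- length(p)
  keep <- rep(TRUE, n)
  for (i in which(!is.na(p))) {
    lo <- max(1L, i - half_n)
    hi <- min(n, i + half_n)
    win <- p[lo:hi]
    win <- win[!is.na(win)]
    if (length(win) < 3) next
    med <- stats::median(win)
    mad <- stats::median(abs(win - med))
    if (abs(p[i] - med) > cfg$mad_multiplier * mad + 1e-12) keep[i] <- FALSE
  }
  p[!keep] <- NA_real_
  # (3) linear interpolation of short gaps; never alters valid samples
  gaps <- runs_of(is.na(p))
  for (g in seq_len(nrow(gaps))) {
    s <- gaps$start[g]
    e <- gaps$end[g]
    if (s == 1 || e == n) next
    if ((e - s + 1L) * dt * 1000 > cfg$interpolation_max_ms + 1e-6) next
    p[s:e] <- stats::approx(x = t[c(s - 1L, e + 1L)],
                            y = p[c(s - 1L, e + 1L)],
                            xout = t[s:e])$y
  }
  p
}

#' Clean both pupil channels of a trial
#'
#' Per eye, in order: blink samples removed (shared blink labelling from
#' the gaze chain), values outside the plausible (2, 8) mm range removed,
#' outliers deviating more than `mad_multiplier` times the rolling MAD from
#' the rolling median removed, and remaining gaps up to 150 ms linearly
#' interpolated from the flanking valid samples. Longer gaps stay missing.
#'
#' @param samples Trial sample tibble (after [correct_blinks()], so blink
#'   samples carry status `"blink"`).
#' @param cfg A [pupil_config()].
#' @return The tibble with `pupil_l`/`pupil_r` replaced by cleaned values.
#' @export
clean_pupil <- function(samples, cfg = pupil_config()) {
  blink <- samples$status == "blink"
  samples$pupil_l <- clean_pupil_eye(samples$pupil_l, samples$t, blink, cfg)
  samples$pupil_r <- clean_pupil_eye(samples$pupil_r, samples$t, blink, cfg)
  samples
}

#' Combine the two eyes into a single pupil series
#'
#' Sample-wise mean where both eyes are valid, the single valid eye
#' otherwise, missing where neither.
#'
#' @param samples Trial sample tibble with cleaned pupil channels.
#' @return The tibble with a combined `pupil` column (mm).
#' @export
combine_eyes <- function(samples) {
  l <- samples$pupil_l
  r <- samples$pupil_r
  samples$pupil <- dplyr::case_when(
    !is.na(l) & !is.na(r) ~ (l + r) / 2,
    !is.na(l) ~ l,
    !is.na(r) ~ r,
    TRUE ~ NA_real_
  )
  samples
}

window_mean <- function(t, x, window, min_coverage) {
  idx <- t >= window[1] & t < window[2]
  if (!any(idx)) return(NA_real_)
  vals <- x[idx]
  if (mean(!is.na(vals)) < min_coverage) return(NA_real_)
  mean(vals, na.rm = TRUE)
}

#' Baseline pupil size (BPS)
#'
#' Mean combined pupil diameter over the first 500 ms of the trial (the
#' first half of the attention-grabber phase), an index of tonic arousal.
#' Absent (NA) when fewer than `min_coverage` of the window's samples are
#' valid.
#'
#' @param samples Trial sample tibble with a combined `pupil` column.
#' @param cfg A [pupil_config()].
#' @return BPS in mm, or NA.
#' @export
compute_bps <- function(samples, cfg = pupil_config()) {
  window_mean(samples$t, samples$pupil, cfg$bps_window, cfg$min_coverage)
}

#' Baseline-correct a trial's pupil series
#'
#' Subtracts the trial's BPS from every sample; missing samples stay
#' missing.
#'
#' @param samples Trial sample tibble with a combined `pupil` column.
#' @param bps The trial's baseline pupil size (mm).
#' @return The tibble with a `pupil_norm` column (mm change from baseline).
#' @export
normalize_trial <- function(samples, bps) {
  if (is.na(bps)) stop("BPS is absent; normalization skipped upstream")
  samples$pupil_norm <- samples$pupil - bps
  samples
}

#' Stimulus-evoked pupillary response (SEPR)
#'
#' Mean baseline-corrected pupil diameter 4.5-5.5 s into the trial
#' (during target cueing); may be negative. Absent when window coverage is
#' insufficient.
#'
#' @param samples Trial sample tibble with a `pupil_norm` column.
#' @param cfg A [pupil_config()].
#' @return SEPR in mm, or NA.
#' @export
compute_sepr <- function(samples, cfg = pupil_config()) {
  window_mean(samples$t, samples$pupil_norm, cfg$sepr_window,
              cfg$min_coverage)
}

#' Run the full pupil feature chain on one trial
#'
#' Cleaning, binocular combination, BPS, baseline correction, SEPR.
#'
#' @param samples Trial sample tibble (blink labelling done).
#' @param cfg A [pupil_config()].
#' @return A one-row tibble: `bps`, `sepr`, `pupil_missing_fraction`.
#' @export
pupil_features <- function(samples, cfg = pupil_config()) {
  samples <- clean_pupil(samples, cfg)
  samples <- combine_eyes(samples)
  bps <- compute_bps(samples, cfg)
  sepr <- NA_real_
  if (!is.na(bps)) {
    samples <- normalize_trial(samples, bps)
    sepr <- compute_sepr(samples, cfg)
  }
  tibble::tibble(
    bps = bps,
    sepr = sepr,
    pupil_missing_fraction = mean(is.na(samples$pupil))
  )
}
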