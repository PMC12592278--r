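#' Test whether a fixation centroid falls inside an AOI region
#'
#' Boundary convention is half-open: the minimum edge is inside, the
#' maximum edge is not.
#'
#' @param cx_px,cy_px Fixation centroid in screen pixels.
#' @param region One-row AOI tibble (columns `x0`, `y0`, `x1`, `y1`).
#' @return Logical.
#' @export
aoi_hit <- function(cx_px, cy_px, region) {
  cx_px >= region$x0 & cx_px < region$x1 &
    cy_px >= region$y0 & cy_px < region$y1
}

#' Score reactive joint attention for one trial
#'
#' A trial counts as RJA when a fixation on the cued target object starts
#' in the target-cueing phase or later (onset >= cueing onset, default 3 s
#' trial-local) and is preceded by a fixation on the model's head whose
#' offset lies within the 500 ms before the target fixation's onset (gap in
#' `[0, 0.5]` s). Fixations on the distractor-side object neither qualify
#' nor disqualify, and the rule is identical across cueing conditions (no
#' separate hand region in the pointing condition).
#'
#' @param fixations Fixation events tibble (`onset`, `offset`, `cx_px`,
#'   `cy_px`); order irrelevant, sorted internally.
#' @param aois AOI tibble with regions `head`, `target_left`,
#'   `target_right` (see [aoi_default()]).
#' @param target_side `"left"` or `"right"`.
#' @param cueing_onset Trial-local cueing onset in seconds (default 3).
#' @param max_gap Maximum head-offset-to-target-onset gap in seconds
#'   (default 0.5).
#' @param duration_mode `"first"` (default): RJA duration is the first
#'   qualifying target fixation's duration; `"sum"`: sum over all
#'   qualifying target fixations.
#' @return A one-row tibble: `rja` (logical), `rja_latency` (s from cueing
#'   onset; NA when no RJA), `rja_duration` (s; NA when no RJA).
#' @export
score_rja <- function(fixations, aois, target_side,
                      cueing_onset = 3, max_gap = 0.5,
                      duration_mode = c("first", "sum")) {
  duration_mode <- match.arg(duration_mode)
  if (!target_side %in% c("left", "right")) {
    stop("unknown target_side: ", target_side)
  }
  none <- tibble::tibble(rja = FALSE, rja_latency = NA_real_,
                         rja_duration = NA_real_)
  if (is.null(fixations) || !nrow(fixations)) return(none)
  fx <- fixations[order(fixations$onset), , drop = FALSE]
  head_region <- aois[aois$aoi == "head", , drop = FALSE]
  target_region <- aois[aois$aoi == paste0("target_", target_side), ,
                        drop = FALSE]
  if (nrow(head_region) != 1 || nrow(target_region) != 1) {
    stop("AOI set must contain 'head' and 'target_", target_side, "'")
  }
  on_head <- aoi_hit(fx$cx_px, fx$cy_px, head_region)
  on_target <- aoi_hit(fx$cx_px, fx$cy_px, target_region)
  qualifies <- rep(FALSE, nrow(fx))
  for (i in which(on_target & fx$onset >= cueing_onset)) {
    gaps <- fx$onset[i] - fx$offset[on_head]
    if (any(gaps >= 0 & gaps <= max_gap)) qualifies[i] <- TRUE
  }
  if (!any(qualifies)) return(none)
  first <- which(qualifies)[1]
  dur <- if (duration_mode == "first") {
    fx$offset[first] - fx$onset[first]
  } else {
    sum(fx$offset[qualifies] - fx$onset[qualifies])
  }
  tibble::tibble(
    rja = TRUE,
    rja_latency = fx$onset[first] - cueing_onset,
    rja_duration = dur
  )
}

#' Total fixation duration within a trial window
#'
#' Sum of fixation durations clipped to the (half-open) trial window.
#'
#' @param fixations Fixation events tibble.
#' @param window Numeric `c(t0, t1)` in trial-local seconds.
#' @return Seconds.
#' @export
total_fixation_duration <- function(fixations, window = c(0, 11)) {
  if (is.null(fixations) || !nrow(fixations)) return(0)
  lo <- pmax(fixations$onset, window[1])
  hi <- pmin(fixations$offset, window[2])
  sum(pmax(hi - lo, 0))
}

#' Assemble the per-trial feature row
#'
#' Combines the RJA score, fixation durations, pupil features, and data
#' quality into the one-row record the statistical layer consumes. Dropped
#' trials (less than half of the samples retained) produce no row. Absent
#' pupil features are left `NA`, never imputed.
#'
#' @param detection Result of [detect_gaze_events()].
#' @param pupil Result of [pupil_features()] (may be NULL when the pupil
#'   channel is unusable).
#' @param aois AOI tibble.
#' @param trial_info One-row tibble with `trial`, `cueing`, `stimulus`,
#'   `target_side` (and optionally `participant`, `timepoint`).
#' @param paradigm A [paradigm_spec()].
#' @return A one-row tibble of trial features, or NULL for a dropped trial.
#' @export
assemble_trial_features <- function(detection, pupil, aois, trial_info,
                                    paradigm = paradigm_spec()) {
  if (detection$quality$dropped) return(NULL)
  fx <- detection$events[detection$events$kind == "fixation", , drop = FALSE]
  score <- score_rja(fx, aois, trial_info$target_side,
                     cueing_onset = unname(paradigm$phase_onsets["cueing"]))
  ids <- trial_info[intersect(c("participant", "timepoint", "trial",
                                "cueing", "stimulus", "target_side"),
                              names(trial_info))]
  dplyr::bind_cols(
    tibble::as_tibble(ids),
    score,
    tibble::tibble(
      total_fixation_duration = total_fixation_duration(
        fx, c(0, paradigm$trial_duration)),
      bps = if (is.null(pupil)) NA_real_ else pupil$bps,
      sepr = if (is.null(pupil)) NA_real_ else pupil$sepr,
      missing_fraction = detection$quality$missing_fraction,
      pupil_missing_fraction = if (is.null(pupil)) NA_real_ else
        pupil$pupil_missing_fraction
    )
  )
}
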