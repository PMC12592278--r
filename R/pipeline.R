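#' Preprocess one session into per-trial features
#'
#' Runs the full chain on a raw sample stream: trial segmentation, gaze
#' cleaning and event detection, RJA scoring, and pupil features, returning
#' one feature row per retained trial. Trials marked dropped at
#' segmentation (truncated) or by the data-quality rule contribute no row.
#'
#' @param stream Sample-stream tibble from [read_gaze_file()] or the
#'   simulator.
#' @param trial_log Tibble with `trial`, `onset_s` and condition labels.
#' @param aois AOI tibble.
#' @param paradigm A [paradigm_spec()].
#' @param cfg A [cleaning_config()].
#' @param pupil_cfg A [pupil_config()].
#' @param participant,timepoint Identifier columns added to every row.
#' @return A tibble of per-trial features.
#' @export
process_session <- function(stream, trial_log, aois,
                            paradigm = paradigm_spec(),
                            cfg = cleaning_config(),
                            pupil_cfg = pupil_config(),
                            participant = "P01", timepoint = "BL") {
  segments <- segment_trials(stream, trial_log, paradigm)
  rows <- vector("list", nrow(segments))
  for (i in seq_len(nrow(segments))) {
    if (segments$dropped[i]) next
    samples <- segments$samples[[i]]
    detection <- detect_gaze_events(samples, cfg, paradigm$geometry)
    if (detection$quality$dropped) next
    pupil <- pupil_features(detection$samples, pupil_cfg)
    info <- tibble::tibble(
      participant = participant, timepoint = timepoint,
      trial = segments$trial[i],
      cueing = segments$cueing[i], stimulus = segments$stimulus[i],
      target_side = segments$target_side[i]
    )
    rows[[i]] <- assemble_trial_features(detection, pupil, aois, info,
                                         paradigm)
  }
  dplyr::bind_rows(rows)
}

#' Preprocess a simulated cohort directory
#'
#' Reads every session written by [simulate_cohort()] and concatenates the
#' per-trial features.
#'
#' @param dir Directory produced by [simulate_cohort()].
#' @param paradigm A [paradigm_spec()].
#' @param cfg A [cleaning_config()].
#' @param pupil_cfg A [pupil_config()].
#' @return A tibble of per-trial features with `participant`, `group`, and
#'   `timepoint` columns.
#' @export
process_cohort <- function(dir, paradigm = paradigm_spec(),
                           cfg = cleaning_config(),
                           pupil_cfg = pupil_config()) {
  sessions <- readr::read_csv(file.path(dir, "participants.csv"),
                              show_col_types = FALSE, progress = FALSE)
  aois <- read_aoi_file(file.path(dir, "aoi.csv"))
  out <- vector("list", nrow(sessions))
  for (i in seq_len(nrow(sessions))) {
    stem <- sprintf("%s_%s", sessions$participant[i],
                    sessions$timepoint[i])
    stream <- read_gaze_file(file.path(dir, paste0(stem, "_gaze.tsv")),
                             paradigm$geometry, quiet = TRUE)
    trial_log <- readr::read_csv(file.path(dir, paste0(stem, "_trials.csv")),
                                 show_col_types = FALSE, progress = FALSE)
    feats <- process_session(stream, trial_log, aois, paradigm, cfg,
                             pupil_cfg,
                             participant = sessions$participant[i],
                             timepoint = sessions$timepoint[i])
    if (nrow(feats)) feats$group <- sessions$group[i]
    out[[i]] <- feats
  }
  dplyr::bind_rows(out)
}
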