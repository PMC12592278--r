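#' @keywords internal
# Evaluate code under a temporary RNG seed, restoring the caller's state.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# main-sequence peak velocity (deg/s) for a saccade amplitude (deg)
main_sequence_vp <- function(amplitude_deg) {
  500 * (1 - exp(-amplitude_deg / 15))
}

# raised-cosine saccade displacement profile: fraction of amplitude covered
# at phase u in [0, 1]
saccade_profile <- function(u) {
  u - sin(2 * pi * u) / (2 * pi)
}

# band-limited Gaussian positional noise: white noise convolved with a
# Gaussian kernel (SD `kernel_sd` samples; default ~83 ms at 300 Hz) and
# scaled back to marginal SD `sd`. Gaze-position error in remote tracking
# of young children is dominated by slow drift; white noise of the same
# amplitude would carry sample-to-sample accelerations far beyond the
# 10000 deg/s^2 plausibility limit and is not seen in raw tracker output.
correlated_noise <- function(n, sd, kernel_sd = 25) {
  if (sd <= 0) return(rep(0, n))
  half <- ceiling(4 * kernel_sd)
  k <- stats::dnorm(-half:half, sd = kernel_sd)
  k <- k / sqrt(sum(k^2))
  w <- stats::rnorm(n + 2 * half)
  as.vector(stats::filter(w, k, sides = 2))[(half + 1):(half + n)] * sd
}

#' Build a fixation plan for one synthetic trial
#'
#' A plan lists the fixation targets (screen px) and dwell durations; the
#' generator synthesises main-sequence saccades between consecutive
#' fixations. When `onset` is not given, fixation onsets are laid out
#' sequentially: each saccade's duration follows from its amplitude A (deg)
#' via the main-sequence peak velocity Vp = 500(1 - exp(-A/15)) deg/s and
#' the raised-cosine profile (duration = 2A/Vp, at least two samples).
#'
#' @param x,y Fixation target coordinates, px.
#' @param duration Dwell times, s.
#' @param onset Optional explicit fixation onsets (trial-local s); when
#'   given, each inter-fixation gap hosts the connecting saccade.
#' @return A tibble with columns `x`, `y`, `onset`, `duration`.
#' @export
trial_plan <- function(x, y, duration, onset = NULL) {
  stopifnot(length(x) == length(y), length(x) == length(duration),
            all(duration > 0))
  tibble::tibble(x = x, y = y, duration = duration,
                 onset = if (is.null(onset)) NA_real_ else onset)
}

# resolve NA onsets sequentially using main-sequence saccade durations
resolve_plan <- function(plan, paradigm) {
  geom <- paradigm$geometry
  dt <- 1 / paradigm$sampling_rate
  n <- nrow(plan)
  if (all(is.na(plan$onset))) {
    onset <- numeric(n)
    onset[1] <- 0
    if (n > 1) {
      for (i in 2:n) {
        amp <- px_to_deg(plan$x[i] - plan$x[i - 1],
                         plan$y[i] - plan$y[i - 1], geom)
        sac_dur <- if (amp > 0) max(2 * amp / main_sequence_vp(amp), 2 * dt)
                   else 2 * dt
        onset[i] <- onset[i - 1] + plan$duration[i - 1] + sac_dur
      }
    }
    plan$onset <- onset
  }
  ends <- plan$onset + plan$duration
  if (any(diff(plan$onset) <= 0) ||
      any(plan$onset[-1] < ends[-n] - 1e-12)) {
    stop("fixation plan intervals overlap or are out of order")
  }
  if (max(ends) > paradigm$trial_duration + 1e-9) {
    stop(sprintf("dwell plan exceeds trial duration (%.2f s > %g s)",
                 max(ends), paradigm$trial_duration))
  }
  plan
}

#' Simulate one trial's gaze stream
#'
#' Renders a 300 Hz binocular sample stream for a fixation plan: constant
#' position during fixations, raised-cosine main-sequence saccades between
#' them (bell-shaped velocity, peak velocity rising with amplitude), the
#' final fixation extended to the end of the trial, optional blink gaps
#' (missing samples in all channels), and band-limited Gaussian positional
#' noise -- white noise low-passed to the smoothness real tracker jitter
#' shows at 300 Hz, with marginal SD `noise_sd_deg`. The same noise stream
#' drives both eyes, so the stated SD is the effective noise of the
#' combined signal.
#'
#' @param plan A [trial_plan()].
#' @param paradigm A [paradigm_spec()].
#' @param noise_sd_deg Positional noise SD, degrees of visual angle.
#' @param blinks Optional tibble (`onset`, `duration`, seconds) of blink
#'   gaps.
#' @param seed Integer RNG seed.
#' @return A list with `samples` (sample-stream tibble with trial-local
#'   `t`) and `truth`: the exact event intervals used (`kind`, `onset`,
#'   `offset`, `x`, `y`, `amplitude_deg`, `peak_vel`).
#' @export
simulate_trial_gaze <- function(plan, paradigm = paradigm_spec(),
                                noise_sd_deg = 0, blinks = NULL, seed = 1) {
  plan <- resolve_plan(plan, paradigm)
  geom <- paradigm$geometry
  fs <- paradigm$sampling_rate
  dt <- 1 / fs
  n <- round(paradigm$trial_duration * fs)
  t <- (seq_len(n) - 1L) * dt
  x <- rep(NA_real_, n)
  y <- rep(NA_real_, n)
  np <- nrow(plan)
  truth <- list()
  fix_end <- c(plan$onset[-1], paradigm$trial_duration)
  for (i in seq_len(np)) {
    # fixation dwell
    f_lo <- plan$onset[i]
    f_hi <- plan$onset[i] + plan$duration[i]
    if (i == np) f_hi <- paradigm$trial_duration  # extend last fixation
    idx <- t >= f_lo - 1e-12 & t < f_hi - 1e-12
    x[idx] <- plan$x[i]
    y[idx] <- plan$y[i]
    truth[[length(truth) + 1L]] <- tibble::tibble(
      kind = "fixation", onset = f_lo, offset = f_hi,
      x = plan$x[i], y = plan$y[i], amplitude_deg = 0, peak_vel = 0
    )
    if (i < np) {
      # saccade from this fixation to the next
      s_lo <- f_hi
      s_hi <- plan$onset[i + 1]
      amp <- px_to_deg(plan$x[i + 1] - plan$x[i],
                       plan$y[i + 1] - plan$y[i], geom)
      idx <- t >= s_lo - 1e-12 & t < s_hi - 1e-12
      u <- (t[idx] - s_lo) / (s_hi - s_lo)
      frac <- saccade_profile(u)
      x[idx] <- plan$x[i] + frac * (plan$x[i + 1] - plan$x[i])
      y[idx] <- plan$y[i] + frac * (plan$y[i + 1] - plan$y[i])
      truth[[length(truth) + 1L]] <- tibble::tibble(
        kind = "saccade", onset = s_lo, offset = s_hi,
        x = NA_real_, y = NA_real_, amplitude_deg = amp,
        peak_vel = 2 * amp / (s_hi - s_lo)
      )
    }
  }
  samples <- with_local_seed(seed, {
    if (noise_sd_deg > 0) {
      px_sd <- deg_to_px(noise_sd_deg, geom)
      x <- x + correlated_noise(n, px_sd)
      y <- y + correlated_noise(n, px_sd)
    }
    planned <- !is.na(x)  # plans starting after 0 leave a leading gap
    tibble::tibble(
      t = t,
      x_l = x, y_l = y, x_r = x, y_r = y,
      pupil_l = NA_real_, pupil_r = NA_real_,
      valid_l = planned, valid_r = planned,
      status = ifelse(planned, "valid", "missing")
    )
  })
  if (!is.null(blinks) && nrow(blinks)) {
    for (i in seq_len(nrow(blinks))) {
      idx <- samples$t >= blinks$onset[i] &
        samples$t < blinks$onset[i] + blinks$duration[i]
      samples$x_l[idx] <- NA_real_; samples$y_l[idx] <- NA_real_
      samples$x_r[idx] <- NA_real_; samples$y_r[idx] <- NA_real_
      samples$pupil_l[idx] <- NA_real_; samples$pupil_r[idx] <- NA_real_
      samples$valid_l[idx] <- FALSE; samples$valid_r[idx] <- FALSE
      samples$status[idx] <- "missing"
      truth[[length(truth) + 1L]] <- tibble::tibble(
        kind = "blink", onset = blinks$onset[i],
        offset = blinks$onset[i] + blinks$duration[i],
        x = NA_real_, y = NA_real_, amplitude_deg = NA_real_,
        peak_vel = NA_real_
      )
    }
  }
  truth <- dplyr::bind_rows(truth)
  truth <- truth[order(truth$onset), , drop = FALSE]
  list(samples = samples, truth = truth)
}

#' Simulate one trial's pupil trace
#'
#' Builds a smooth (C1) pupil-diameter profile: a flat baseline equal to
#' `bps_true` over the first 500 ms, a luminance-adaptation bump (raised
#' sine-squared, amplitude `bump_mm`) over the rest of the attention-grabber
#' and intro phases, a smoothstep dilation from cueing onset reaching
#' `sepr_true` above baseline at 4.5 s, a plateau across the 4.5-5.5 s
#' response window, and a smooth return afterwards. At zero noise the
#' feature chain recovers `bps_true` and `sepr_true` exactly. Both eyes
#' receive the same underlying signal plus independent Gaussian noise.
#'
#' @param paradigm A [paradigm_spec()].
#' @param bps_true Baseline pupil size, mm; must lie in (2, 8) or the trial
#'   would be deleted by the plausibility filter.
#' @param sepr_true Evoked response, mm (may be negative).
#' @param noise_sd Per-eye Gaussian noise SD, mm.
#' @param bump_mm Amplitude of the luminance-adaptation bump, mm.
#' @param seed Integer RNG seed.
#' @return A tibble with `t`, `pupil_l`, `pupil_r`.
#' @export
simulate_trial_pupil <- function(paradigm = paradigm_spec(), bps_true = 4.2,
                                 sepr_true = 0.1, noise_sd = 0,
                                 bump_mm = 0.3, seed = 1) {
  if (bps_true <= 2 || bps_true >= 8) {
    stop("bps_true must lie inside (2, 8) mm")
  }
  fs <- paradigm$sampling_rate
  n <- round(paradigm$trial_duration * fs)
  t <- (seq_len(n) - 1L) / fs
  cue_on <- unname(paradigm$phase_onsets["cueing"])
  smoothstep <- function(u) {
    u <- pmin(pmax(u, 0), 1)
    u^2 * (3 - 2 * u)
  }
  p <- rep(bps_true, n)
  # luminance adaptation after the first half of the attention grabber
  bump_idx <- t >= 0.5 & t < cue_on
  p[bump_idx] <- p[bump_idx] +
    bump_mm * sin(pi * (t[bump_idx] - 0.5) / (cue_on - 0.5))^2
  # dilation ramp to the response plateau
  ramp_idx <- t >= cue_on & t < 4.5
  p[ramp_idx] <- p[ramp_idx] +
    sepr_true * smoothstep((t[ramp_idx] - cue_on) / (4.5 - cue_on))
  plateau_idx <- t >= 4.5 & t < 5.5
  p[plateau_idx] <- p[plateau_idx] + sepr_true
  decay_idx <- t >= 5.5
  p[decay_idx] <- p[decay_idx] +
    sepr_true * smoothstep(1 - (t[decay_idx] - 5.5) / 3)
  with_local_seed(seed, {
    tibble::tibble(
      t = t,
      pupil_l = p + stats::rnorm(n, 0, noise_sd),
      pupil_r = p + stats::rnorm(n, 0, noise_sd)
    )
  })
}

#' Plan a trial realizing a wanted RJA outcome
#'
#' Produces a fixation plan that, scored at zero noise, yields the given
#' RJA flag: attention-grabber fixation at the head location, head fixation
#' through the early cueing phase, then either a saccade to the cued target
#' (RJA true) or to the distractor-side object (RJA false), and a return to
#' the head. Small uniform jitters on dwell times keep trials from being
#' identical.
#'
#' @param rja Logical wanted outcome.
#' @param target_side `"left"` or `"right"`.
#' @param aois AOI tibble (see [aoi_default()]).
#' @param paradigm A [paradigm_spec()].
#' @param seed Integer RNG seed (drives the jitters).
#' @return A [trial_plan()].
#' @export
plan_rja_trial <- function(rja, target_side, aois = aoi_default(),
                           paradigm = paradigm_spec(), seed = 1) {
  head_c <- aoi_center(aois, "head")
  target_c <- aoi_center(aois, paste0("target_", target_side))
  other <- if (target_side == "left") "right" else "left"
  distractor_c <- aoi_center(aois, paste0("target_", other))
  with_local_seed(seed, {
    leave_head <- 3.4 + stats::runif(1, 0, 0.4)
    dwell_obj <- 1.5 + stats::runif(1, 0, 1)
    obj <- if (rja) target_c else distractor_c
    trial_plan(
      x = c(head_c["x"], obj["x"], head_c["x"]),
      y = c(head_c["y"], obj["y"], head_c["y"]),
      duration = c(leave_head, dwell_obj, 1.0)
    )
  })
}

#' Cohort-level generative specification
#'
#' Encodes the generative structure the statistical layer assumes: a
#' binomial-logit model for per-trial RJA with crossed participant and
#' trial random intercepts, group-by-timepoint fixed effects on the
#' log-odds scale, and an arousal (BPS) pathway in which group shifts
#' baseline pupil size and BPS in turn shifts the RJA log-odds -- the
#' mediation mechanism. SEPR is inversely coupled to BPS.
#'
#' Default fixed effects place marginal RJA rates near the magnitudes seen
#' in preschool gaze-following cohorts (autistic groups around 0.06-0.35
#' across timepoints, non-autistic around 0.4-0.6) and default random-
#' intercept SDs (participant 1.2, trial 0.3 on the log-odds scale) give a
#' conditional R-squared several times the marginal one, as such data show.
#'
#' @param group_sizes Named integer vector of participants per group.
#' @param timepoints Named list: which timepoints each group attends.
#' @param fixed_logodds Tibble (`group`, `timepoint`, `logodds`).
#' @param sd_participant,sd_trial Random-intercept SDs, log-odds scale.
#' @param bps_mean Population mean BPS, mm.
#' @param bps_group_shift Named per-group shift of mean BPS, mm.
#' @param bps_sd_participant,bps_sd_trial Between-participant and
#'   within-participant (trial-to-trial) BPS SDs, mm.
#' @param bps_rja_slope Effect of BPS on the RJA log-odds, per mm.
#' @param direct_logodds Named per-group direct effect on the RJA log-odds
#'   (the unmediated pathway in mediation experiments).
#' @param sepr_mean Population mean SEPR, mm.
#' @param sepr_bps_slope Coupling of SEPR to BPS (negative: larger evoked
#'   responses at lower baselines), per mm.
#' @param sepr_sd Residual SEPR SD, mm.
#' @param noise_deg Positional gaze noise SD, degrees.
#' @param pupil_noise_sd Per-eye pupil noise SD, mm.
#' @param blink_rate Expected blinks per trial.
#' @param missing_rate Probability of an additional long tracking-loss gap
#'   per trial.
#' @param seed Integer seed; fully determines the cohort.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(group_sizes = c("A-FFIP" = 32, "EIAU" = 28,
                                        "non-autistic" = 52),
                        timepoints = list(
                          "A-FFIP" = c("BL", "ET", "FU"),
                          "EIAU" = c("BL", "ET", "FU"),
                          "non-autistic" = c("BL", "FU")),
                        fixed_logodds = NULL,
                        sd_participant = 1.2, sd_trial = 0.3,
                        bps_mean = 4.3,
                        bps_group_shift = c("A-FFIP" = -0.1, "EIAU" = 0.1,
                                            "non-autistic" = 0),
                        bps_sd_participant = 0.4, bps_sd_trial = 0.15,
                        bps_rja_slope = -0.5,
                        direct_logodds = c("A-FFIP" = 0, "EIAU" = 0,
                                           "non-autistic" = 0),
                        sepr_mean = 0.06, sepr_bps_slope = -0.15,
                        sepr_sd = 0.1,
                        noise_deg = 0.25, pupil_noise_sd = 0.05,
                        blink_rate = 2, missing_rate = 0.05,
                        seed = 1) {
  if (is.null(fixed_logodds)) {
    fixed_logodds <- tibble::tribble(
      ~group,          ~timepoint, ~logodds,
      "A-FFIP",        "BL",       -1.8,
      "A-FFIP",        "ET",       -1.4,
      "A-FFIP",        "FU",       -0.95,
      "EIAU",          "BL",       -2.7,
      "EIAU",          "ET",       -2.3,
      "EIAU",          "FU",       -2.2,
      "non-autistic",  "BL",       -0.5,
      "non-autistic",  "FU",        0.35
    )
  }
  stopifnot(sd_participant >= 0, sd_trial >= 0, bps_sd_participant >= 0,
            bps_sd_trial >= 0, sepr_sd >= 0, blink_rate >= 0,
            missing_rate >= 0, missing_rate <= 1)
  structure(as.list(environment()), class = "cohort_spec")
}

#' Draw per-trial RJA outcomes and pupil ground truth for a cohort
#'
#' The statistical core of the cohort generator: participant and trial
#' random intercepts are drawn once, per-trial BPS values follow the group
#' shift plus participant and trial noise, and the per-trial RJA flag is
#' Bernoulli with logit equal to the group-by-timepoint fixed effect plus
#' the direct group effect, the random intercepts, and
#' `bps_rja_slope * (BPS - bps_mean)`. SEPR couples inversely to BPS.
#'
#' @param cohort A [cohort_spec()].
#' @param paradigm A [paradigm_spec()].
#' @return A tibble with one row per participant x timepoint x trial:
#'   identifiers, condition labels, `bps_true`, `sepr_true`, `eta`,
#'   `p_true`, and the drawn `rja`.
#' @export
simulate_rja_outcomes <- function(cohort, paradigm = paradigm_spec()) {
  conditions <- trial_conditions(paradigm)
  with_local_seed(cohort$seed, {
    participants <- purrr::imap_dfr(
      as.list(cohort$group_sizes),
      function(n, g) tibble::tibble(
        participant = sprintf("%s_%02d", gsub("[^A-Za-z]", "", g),
                              seq_len(n)),
        group = g
      )
    )
    participants$u <- stats::rnorm(nrow(participants), 0,
                                   cohort$sd_participant)
    participants$bps_p <- cohort$bps_mean +
      unname(cohort$bps_group_shift[participants$group]) +
      stats::rnorm(nrow(participants), 0, cohort$bps_sd_participant)
    v_trial <- stats::rnorm(paradigm$n_trials, 0, cohort$sd_trial)
    grid <- purrr::pmap_dfr(
      participants,
      function(participant, group, u, bps_p) {
        tps <- cohort$timepoints[[group]]
        tidyr::expand_grid(
          participant = participant, group = group, timepoint = tps,
          trial = seq_len(paradigm$n_trials)
        )
      }
    )
    grid <- dplyr::left_join(grid, participants, by = c("participant", "group"))
    grid <- dplyr::left_join(grid, conditions, by = "trial")
    grid <- dplyr::left_join(grid, cohort$fixed_logodds,
                             by = c("group", "timepoint"))
    if (anyNA(grid$logodds)) {
      stop("fixed_logodds lacks a (group, timepoint) combination present in the design")
    }
    n <- nrow(grid)
    grid$bps_true <- grid$bps_p + stats::rnorm(n, 0, cohort$bps_sd_trial)
    grid$sepr_true <- cohort$sepr_mean +
      cohort$sepr_bps_slope * (grid$bps_true - cohort$bps_mean) +
      stats::rnorm(n, 0, cohort$sepr_sd)
    grid$eta <- grid$logodds +
      unname(cohort$direct_logodds[grid$group]) +
      grid$u + v_trial[grid$trial] +
      cohort$bps_rja_slope * (grid$bps_true - cohort$bps_mean)
    grid$p_true <- stats::plogis(grid$eta)
    grid$rja <- stats::runif(n) < grid$p_true
    tibble::as_tibble(grid[, c("participant", "group", "timepoint", "trial",
                               "cueing", "stimulus", "target_side",
                               "bps_true", "sepr_true", "eta", "p_true",
                               "rja")])
  })
}

# render one session's stream (16 trials, 12 s spacing) from drawn outcomes
render_session <- function(outcomes_session, cohort, paradigm, aois,
                           seed) {
  fs <- paradigm$sampling_rate
  spacing <- paradigm$trial_duration + 1
  streams <- vector("list", nrow(outcomes_session))
  truths <- vector("list", nrow(outcomes_session))
  blink_plans <- with_local_seed(seed, {
    lapply(seq_len(nrow(outcomes_session)), function(i) {
      n_blinks <- stats::rpois(1, cohort$blink_rate)
      bl <- NULL
      if (n_blinks > 0) {
        bl <- tibble::tibble(
          onset = sort(stats::runif(n_blinks, 0.8, 10.3)),
          duration = stats::runif(n_blinks, 0.1, 0.2)
        )
      }
      if (stats::runif(1) < cohort$missing_rate) {
        gap <- tibble::tibble(onset = stats::runif(1, 0.8, 9.5),
                              duration = stats::runif(1, 0.3, 0.8))
        bl <- dplyr::bind_rows(bl, gap)
      }
      bl
    })
  })
  for (i in seq_len(nrow(outcomes_session))) {
    row <- outcomes_session[i, ]
    plan <- plan_rja_trial(row$rja, row$target_side, aois, paradigm,
                           seed = seed + 13L * i)
    gaze <- simulate_trial_gaze(plan, paradigm,
                                noise_sd_deg = cohort$noise_deg,
                                blinks = blink_plans[[i]],
                                seed = seed + 17L * i)
    pupil <- simulate_trial_pupil(paradigm, row$bps_true, row$sepr_true,
                                  noise_sd = cohort$pupil_noise_sd,
                                  seed = seed + 19L * i)
    s <- gaze$samples
    keep_pupil <- s$valid_l
    s$pupil_l <- ifelse(keep_pupil, pupil$pupil_l, NA_real_)
    s$pupil_r <- ifelse(s$valid_r, pupil$pupil_r, NA_real_)
    s$t <- s$t + (row$trial - 1) * spacing
    streams[[i]] <- s
    tr <- gaze$truth
    tr$trial <- row$trial
    truths[[i]] <- tr
  }
  list(
    stream = dplyr::bind_rows(streams),
    truth = dplyr::bind_rows(truths),
    trial_log = tibble::tibble(
      trial = outcomes_session$trial,
      onset_s = (outcomes_session$trial - 1) * spacing,
      cueing = outcomes_session$cueing,
      stimulus = outcomes_session$stimulus,
      target_side = outcomes_session$target_side
    )
  )
}

#' Simulate a full cohort and write its session files
#'
#' Draws per-trial outcomes with [simulate_rja_outcomes()], renders each
#' participant-timepoint session as a 300 Hz stream (16 trials at 12 s
#' spacing), and writes everything in the dialects the readers consume:
#' per-session gaze TSVs, a trial-log CSV per session, one AOI CSV, a
#' participant CSV, and a ground-truth registry CSV holding the true
#' parameters and per-trial outcomes. Identical spec and seed give
#' byte-identical files.
#'
#' @param cohort A [cohort_spec()].
#' @param paradigm A [paradigm_spec()].
#' @param dir Output directory (created if needed).
#' @param aois AOI tibble.
#' @return Invisibly, a list with the `outcomes` tibble, per-session file
#'   paths, and the directory.
#' @export
simulate_cohort <- function(cohort, paradigm = paradigm_spec(),
                            dir, aois = aoi_default(paradigm$geometry)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  outcomes <- simulate_rja_outcomes(cohort, paradigm)
  sessions <- dplyr::distinct(outcomes[, c("participant", "group",
                                           "timepoint")])
  paths <- character(nrow(sessions))
  for (i in seq_len(nrow(sessions))) {
    sess <- outcomes[outcomes$participant == sessions$participant[i] &
                       outcomes$timepoint == sessions$timepoint[i], ]
    rendered <- render_session(sess, cohort, paradigm, aois,
                               seed = cohort$seed + 1000L * i)
    stem <- sprintf("%s_%s", sessions$participant[i], sessions$timepoint[i])
    gaze_path <- file.path(dir, paste0(stem, "_gaze.tsv"))
    write_gaze_file(rendered$stream, gaze_path)
    readr::write_csv(rendered$trial_log,
                     file.path(dir, paste0(stem, "_trials.csv")))
    paths[i] <- gaze_path
  }
  readr::write_csv(aois, file.path(dir, "aoi.csv"))
  readr::write_csv(sessions, file.path(dir, "participants.csv"))
  readr::write_csv(outcomes, file.path(dir, "ground_truth.csv"))
  invisible(list(outcomes = outcomes, sessions = sessions, paths = paths,
                 dir = dir))
}
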