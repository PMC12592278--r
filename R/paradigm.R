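#' Specification of the gaze-following trial paradigm
#'
#' The paradigm is a 16-trial gaze-following task. Every trial lasts 11 s
#' and moves through four phases: an attention grabber at the future face
#' location (0-1 s), an intro in which the model looks into the camera while
#' two target objects appear (1-3 s), target cueing in which the model cues
#' one object by gaze, facial expression, or pointing (3-9 s), and an outro
#' with direct gaze again (9-11 s). Trials cross four cueing conditions
#' (neutral, mild, intense, neutral + pointing) with four object stimuli
#' (rabbit, truck, ball, flower); the cued side is counterbalanced so each
#' side is the target in 8 of the 16 trials.
#'
#' @param n_trials Number of trials (default 16).
#' @param trial_duration Trial length in seconds (default 11).
#' @param phase_onsets Named numeric vector of phase onsets in trial-local
#'   seconds; must be strictly increasing and below `trial_duration`.
#' @param sampling_rate Nominal tracker sampling rate in Hz (default 300).
#' @param geometry A [screen_geometry()].
#' @return A list of class `paradigm_spec`.
#' @export
paradigm_spec <- function(n_trials = 16,
                          trial_duration = 11,
                          phase_onsets = c(attention_grabber = 0, intro = 1,
                                           cueing = 3, outro = 9),
                          sampling_rate = 300,
                          geometry = screen_geometry()) {
  stopifnot(n_trials > 0, trial_duration > 0, sampling_rate > 0)
  if (any(diff(phase_onsets) <= 0) || any(phase_onsets >= trial_duration)) {
    stop("phase onsets must be strictly increasing and < trial_duration")
  }
  structure(
    list(
      n_trials = n_trials,
      trial_duration = trial_duration,
      phase_onsets = phase_onsets,
      sampling_rate = sampling_rate,
      geometry = geometry
    ),
    class = "paradigm_spec"
  )
}

#' @export
print.paradigm_spec <- function(x, ...) {
  cat(sprintf(
    "<paradigm_spec> %d trials x %.0f s at %.0f Hz; phases: %s\n",
    x$n_trials, x$trial_duration, x$sampling_rate,
    paste(sprintf("%s=%g", names(x$phase_onsets), x$phase_onsets), collapse = ", ")
  ))
  invisible(x)
}

#' The 16-trial condition design
#'
#' Fully crosses cueing condition with object stimulus (16 combinations) and
#' counterbalances the target side so each side is cued 8 times. The
#' presentation order is a fixed pseudorandom permutation in two blocks of
#' eight, optionally reshuffled under a seed.
#'
#' @param paradigm A [paradigm_spec()].
#' @param seed Optional integer; when given, the within-block order is
#'   permuted reproducibly. The default order is a fixed published-style
#'   permutation.
#' @return A tibble with one row per trial: `trial`, `cueing`, `stimulus`,
#'   `target_side`.
#' @export
trial_conditions <- function(paradigm = paradigm_spec(), seed = NULL) {
  cueing <- c("neutral", "mild", "intense", "neutral+pointing")
  stimulus <- c("rabbit", "truck", "ball", "flower")
  design <- tidyr::expand_grid(cueing = cueing, stimulus = stimulus)
  # alternate sides down the crossed design: 8 left, 8 right, balanced
  # within each cueing condition
  design$target_side <- rep(c("left", "right"), length.out = nrow(design))
  # fixed pseudorandom order, two blocks of eight
  order_fixed <- c(3, 14, 8, 1, 12, 6, 15, 10, 5, 16, 2, 11, 7, 13, 4, 9)
  if (!is.null(seed)) {
    order_fixed <- reshuffle_blocks(seed)
  }
  design <- design[order_fixed, , drop = FALSE]
  design$trial <- seq_len(nrow(design))
  tibble::as_tibble(design[, c("trial", "cueing", "stimulus", "target_side")])
}

# Permute the 16-trial order within two blocks of eight, seed-controlled,
# without disturbing the caller's RNG state.
reshuffle_blocks <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  c(sample(1:8), sample(9:16))
}

#' Default area-of-interest layout
#'
#' Axis-aligned screen regions used by the scorer: the model's head in the
#' upper-middle of the screen and a target object region on each side. The
#' layout is constant across trial phases. Boundaries are half-open:
#' a point on the minimum edge is inside, one on the maximum edge is not.
#'
#' @param geometry A [screen_geometry()].
#' @return A tibble with columns `aoi`, `x0`, `y0`, `x1`, `y1` (px) and
#'   `active_phase` (here always `"all"`).
#' @export
aoi_default <- function(geometry = screen_geometry()) {
  w <- geometry$width_px
  h <- geometry$height_px
  tibble::tibble(
    aoi = c("head", "target_left", "target_right"),
    x0 = c(w * 0.375, w * 0.02, w * 0.72),
    y0 = c(h * 0.05, h * 0.45, h * 0.45),
    x1 = c(w * 0.625, w * 0.28, w * 0.98),
    y1 = c(h * 0.55, h * 0.95, h * 0.95),
    active_phase = "all"
  )
}

#' Centre of an AOI region
#' @param aois AOI tibble as from [aoi_default()].
#' @param name AOI name.
#' @return Numeric `c(x, y)` in pixels.
#' @export
aoi_center <- function(aois, name) {
  row <- aois[aois$aoi == name, , drop = FALSE]
  if (nrow(row) != 1) stop("unknown AOI: ", name)
  c(x = (row$x0 + row$x1) / 2, y = (row$y0 + row$y1) / 2)
}
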