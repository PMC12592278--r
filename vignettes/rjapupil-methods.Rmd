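---
title: "From raw gaze samples to mediation: the rjapupil pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From raw gaze samples to mediation: the rjapupil pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(rjapupil)
```

## The scientific problem

Reactive joint attention (RJA) — re-orienting one's gaze to a target that
another person has just cued — is a foundational social-communication skill
and a common target of early autism interventions. A screen-based
gaze-following paradigm makes it measurable in preschoolers: in each of 16
eleven-second trials, an attention grabber (0–1 s) is followed by a model
looking into the camera while two objects appear (1–3 s), cueing one object
by gaze, facial expression, or pointing (3–9 s), and a direct-gaze outro
(9–11 s). A remote eye tracker samples binocular gaze and pupil diameter at
300 Hz while the child watches without head restraint.

`rjapupil` implements the full analysis chain for such data: cleaning and
event detection, per-trial RJA scoring against area-of-interest (AOI)
geometry, pupillometric arousal measures, and a statistical layer of mixed
models, contrasts, cascade models, dropout ANOVA with power, and causal
mediation. Because raw cohort recordings of this kind are typically not
redistributable, the package also contains a first-class synthetic-session
generator with known ground truth; every stage of the pipeline is validated
against it.

## Preprocessing model and its parameters

A session stream is a tibble of timestamped binocular samples. Cleaning
proceeds per trial, in a fixed order; each step only ever invalidates
samples, never revalidates them:

1. **Segmentation** into half-open 11 s windows `[onset, onset + 11)`,
   with trial-local time zero at attention-grabber onset.
2. **Blink correction**: contiguous tracking-loss runs lasting 75–250 ms
   are blinks; the samples within 25 ms before and after (7 samples at
   300 Hz) are excluded with them. Shorter or longer gaps remain plain
   missing data.
3. **Plausibility filter** on the raw combined gaze signal:
   sample-to-sample velocity above 1000 °/s or acceleration above
   10000 °/s² is physiologically impossible and marks the arriving sample.
4. **Savitzky–Golay smoothing**, 70 ms window (21 samples), polynomial
   order 3, applied per contiguous valid run and never across gaps. The
   order is the standard choice for gaze traces; the window length is the
   published value.
5. **Velocity** by central differences of the smoothed angular position;
   undefined at run edges. Pixel displacements become degrees of visual
   angle via `atan(d_px · pitch / distance)` per axis, combined as the
   Euclidean norm. The screen is 27″ at 1920×1080 (597.7 × 336.2 mm,
   0.311 mm pitch); the viewing distance is not a property of the screen
   and defaults to 650 mm, a typical child-to-remote-tracker distance —
   set it explicitly in `screen_geometry()` when it differs.
6. **Adaptive saccade threshold**: starting from 100 °/s, the peak
   threshold iterates to `mean + 6·SD` of sub-threshold velocities until it
   moves less than 1 °/s (≤ 50 iterations); onsets/offsets extend to the
   `mean + 3·SD` crossing. These are the canonical constants of the
   data-driven scheme; all are exposed in `cleaning_config()`. A
   zero-variance trace (possible only in synthetic data) falls back to a
   10 °/s floor.
7. **Saccades**: maximal suprathreshold runs, extended to the onset
   threshold, merged when closer than 40 ms (smoothing can split one
   movement into a peak with shoulders, and real saccades cannot follow
   each other that quickly), discarded below 10 ms.
8. **Fixations**: maximal valid runs outside saccades that satisfy a
   stability criterion for at least 100 ms. Two criteria are provided
   because the printed rule ("position change smaller than 1 °/s") mixes
   units: `velocity` mode (the default, as printed: smoothed angular
   velocity < 1 °/s) and `dispersion` mode (position range < 1° within a
   100 ms sliding window). Velocity mode is extremely strict for
   unrestrained preschooler data — any realistic noise level keeps the
   smoothed velocity above 1 °/s essentially everywhere — so analyses of
   noisy data should use dispersion mode; the choice is a logged
   configuration, not a branch in the science.
9. **Trial quality**: a trial retaining less than half of its samples is
   dropped ("less than" exactly: a trial at precisely 50% is kept).

The gaze channel is the average of the two eyes where both are valid, the
single valid eye otherwise — stated binocular averaging exists only for the
pupil, and this choice maximizes retention without biasing position.

## RJA scoring

Fixations are assigned to AOIs by centroid, with half-open boundaries
(minimum edge inside). A trial is RJA-positive when a fixation on the cued
target object starts during or after the cueing phase (≥ 3 s trial-local)
and a head fixation ended within the 500 ms before it (gap ∈ [0, 0.5] s,
offset-to-onset). Distractor-side fixations neither qualify nor disqualify,
and the rule has no condition-dependent branches (no separate hand AOI in
the pointing condition). RJA latency is the first qualifying target
fixation's onset minus cueing onset; RJA duration is that fixation's
duration (a config flag switches to the sum over all qualifying target
fixations — the quantity is not pinned down by the originating study). The
scorer is checked against a brute-force all-pairs oracle on random
configurations.

## Pupillometry

Per eye, in order: blink samples removed; diameters outside the open
interval (2, 8) mm removed; samples deviating more than 3 rolling MADs from
a 150 ms rolling median removed ("linear filter" is read as this rolling
outlier rejector, the usual construction in the cited preprocessing
lineage); gaps up to 150 ms linearly interpolated, longer gaps left
missing. Eyes are cleaned first and averaged afterwards. Baseline pupil
size (BPS) is the mean over the first 500 ms of the trial; every sample is
then baseline-corrected, and the stimulus-evoked pupillary response (SEPR)
is the mean corrected diameter over 4.5–5.5 s trial-local (during cueing;
the window is anchored at trial onset, which is consistent with cueing
starting at 3 s, and is configurable). Both features require at least 50%
valid samples in their window — echoing the trial-level rule — and are
reported absent otherwise, never imputed.

## The synthetic-session generator

The generator is the package's ground-truth instrument, and its defaults
are the study conditions: 16 trials of 11 s at 300 Hz, four cueing
conditions crossed with four stimuli, sides counterbalanced 8/8.

* **Gaze**: fixation plans (targets + dwells) connected by saccades with a
  raised-cosine velocity profile and main-sequence peak velocity
  `Vp = 500·(1 − exp(−A/15))` °/s — a standard smooth profile; the
  detection literature prescribes no generator. Blinks are missing-data
  gaps in all channels.
* **Positional noise** is band-limited: white noise convolved with a
  Gaussian kernel (correlation length ≈ 83 ms), marginal SD as configured
  (0.25° by default). This is a modelling decision forced by physics:
  white noise above ~0.02° at 300 Hz would violate the 10000 °/s²
  plausibility filter at nearly every sample, so raw tracker error must be
  smooth, and drift-dominated error is exactly what remote tracking of
  unrestrained preschoolers produces. The kernel width is the value at
  which the acceleration filter, the 1° dispersion criterion, and saccade
  detectability are simultaneously consistent.
* **Pupil**: a C¹ profile — flat baseline equal to the true BPS over
  [0, 0.5) s, a luminance-adaptation bump (0.3 mm) across the rest of the
  grabber/intro phases, a smoothstep dilation reaching the true SEPR at
  4.5 s, a plateau to 5.5 s, and a smooth decay. Smoothness matters: a
  kink inside a feature window would be clipped by the MAD filter and
  break exact zero-noise recovery.
* **Cohorts**: per-trial RJA is Bernoulli with logit = group-by-timepoint
  fixed effect + participant intercept + trial intercept + slope·(BPS −
  mean), the generative counterpart of the analysis GLMM. Default fixed
  effects place marginal rates where preschool cohorts sit (≈ 0.06–0.35
  for autistic groups across timepoints, ≈ 0.4–0.6 for non-autistic);
  random-intercept SDs default to 1.2 (participant) and 0.3 (trial) on the
  log-odds scale, giving a conditional R² several times the marginal one,
  as such data show. BPS defaults: mean 4.3 mm, group shifts of ∓0.1 mm,
  between-participant SD 0.4 mm, within-participant SD 0.15 mm. SEPR is
  inversely coupled to BPS (−0.15 mm/mm, residual SD 0.1 mm), mean
  0.06 mm. Ground-truth RJA is defined as the scoring rule applied to the
  noiseless plan, avoiding double bookkeeping.

What the generator does *not* emulate: smooth pursuit, microsaccades, head
motion and its parallax, luminance-driven pupil changes beyond the single
adaptation bump, condition-dependent behaviour (the originating study
found none), and missingness that correlates with behaviour. Passing tests
therefore demonstrate correctness of the algorithms under controlled
conditions, not robustness to every pathology of real recordings.

## Statistical layer

* `fit_rja_glmm()` fits binomial-logit GLMMs (Laplace) or Gaussian LMMs
  with crossed random intercepts for participant and trial index (1–16)
  via `lme4`; convergence and singularity are reported honestly and
  contrasts refuse non-converged fits.
* `nakagawa_r2()` implements the variance-partition R²: with σ²_f the
  variance of the fixed-effect predictor, σ²_r the summed random-intercept
  variances, and residual π²/3 (binomial-logit, latent scale) or σ²_ε
  (Gaussian), mR² = σ²_f/(σ²_f+σ²_r+resid) and cR² = (σ²_f+σ²_r)/(same).
* `marginal_contrasts()` evaluates cell means with random effects at zero
  (the conditional-mode convention; which convention the original software
  used is not stated) and forms pairwise odds ratios (binomial) or mean
  differences (Gaussian), with Wald z/p and percentile 95% intervals from
  a nonparametric cluster bootstrap resampling participants (k = 1000 by
  default, seed-controlled).
* `condition_screen()` adds each task-condition factor to a base model and
  reports the likelihood-ratio test.
* `cascade_lm()` regresses developmental change scores on early change
  scores with standardized coefficients; `change_scores()` aggregates
  per-trial flags to participant-level likelihoods.
* `dropout_anova()` is the Type-II two-way ANOVA of group × retention;
  `anova_power()` is its noncentral-F power: f² = η²/(1−η²), λ = f²·N,
  df₂ = N − cells. Under this standard convention η² = 0.12 with N = 60
  gives power 0.80; a printed value of 0.82 for this design corresponds to
  η² ≈ 0.125, i.e. a rounded effect-size input.
* `mediate_rja()` implements quasi-Bayesian causal mediation: a
  participant-level linear mediator model and a trial-level logistic
  outcome model; k = 1000 draws from the coefficient sampling
  distributions; counterfactual mediators simulated with residual noise;
  ACME, ADE, and total effect averaged over the sample on the probability
  scale, with percentile intervals and tail-proportion p-values. The
  averaged decomposition makes ACME + ADE equal the total effect exactly
  in every draw. A baseline covariate of the mediator can enter both
  models (the moderated-mediation control). Mediators enter at participant
  level; possible separation in the outcome model flags the result
  unreliable rather than failing silently.
* No multiplicity correction is applied anywhere: the intended use is a
  small set of planned contrasts, and this is documented rather than
  hidden.

## Numerical choices and degenerate inputs

Durations are quantized to the sampling grid, so duration-band comparisons
carry a half-sample float tolerance (a 75-sample gap at 300 Hz *is* 250 ms
and is a blink). Event boundaries inherit the smoothing physics: a 70 ms
filter genuinely spreads motion by up to ±35 ms, so detected boundaries
are validated to half the window, while event *counts*, RJA flags, and
pupil features are validated exactly (zero noise) or at ≥95% (realistic
noise). Zero-variance velocity input floors the adaptive threshold at
10 °/s (onset 5 °/s). Fits on constant outcomes return zero F statistics
rather than 0/0. All simulation entry points take explicit integer seeds
and restore the caller's RNG state.

## Validation scale

The shipped test-and-acceptance suite validates at sizes chosen to
exercise the statistics meaningfully on a single CPU: 50 zero-noise trials
for the exact round trip, 200 noisy trials for event recovery, 100
simulated cohorts of 60 participants × 16 trials for GLMM recovery of a
0.9 log-odds group effect, mediation toys of n = 2000 with k = 1000
draws, and 1000 random fixation configurations against the brute-force
scorer oracle.

## Known limitations

The velocity-mode fixation criterion is faithful to the printed rule but
unusable on realistic noise; dispersion mode is the practical default for
real data. Marginal means fix random effects at zero rather than
integrating over them (a population-averaged option is flagged but the
conditional convention is the default). The mediator enters mediation at
the participant level, discarding within-participant trial variation. The
generator's behaviour plans are schematic (one object visit per trial);
they span the RJA rule's logic but not the full diversity of preschooler
scan paths.
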