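# Shared fixtures: a default paradigm/geometry pair and builders for small
# synthetic sample streams used across the unit tests.

pg <- paradigm_spec()
geom <- pg$geometry
aois <- aoi_default(geom)

# a constant-position stream of n samples at 300 Hz
make_stream <- function(n, x = 960, y = 540, pupil = 4, t0 = 0) {
  tibble::tibble(
    t = t0 + (seq_len(n) - 1) / 300,
    x_l = x, y_l = y, x_r = x, y_r = y,
    pupil_l = pupil, pupil_r = pupil,
    valid_l = TRUE, valid_r = TRUE,
    status = "valid"
  )
}

# knock out samples idx (tracking loss in all channels)
drop_samples <- function(s, idx) {
  s$x_l[idx] <- NA; s$y_l[idx] <- NA
  s$x_r[idx] <- NA; s$y_r[idx] <- NA
  s$pupil_l[idx] <- NA; s$pupil_r[idx] <- NA
  s$valid_l[idx] <- FALSE; s$valid_r[idx] <- FALSE
  s$status[idx] <- "missing"
  s
}

# brute-force RJA oracle: scan every (head fixation, target fixation) pair
oracle_rja <- function(fx, aois, side, cueing_onset = 3, max_gap = 0.5) {
  head_r <- aois[aois$aoi == "head", ]
  targ_r <- aois[aois$aoi == paste0("target_", side), ]
  inside <- function(cx, cy, r) {
    cx >= r$x0 && cx < r$x1 && cy >= r$y0 && cy < r$y1
  }
  n <- nrow(fx)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (!inside(fx$cx_px[j], fx$cy_px[j], targ_r)) next
      if (fx$onset[j] < cueing_onset) next
      if (!inside(fx$cx_px[i], fx$cy_px[i], head_r)) next
      gap <- fx$onset[j] - fx$offset[i]
      if (gap >= 0 && gap <= max_gap) return(TRUE)
    }
  }
  FALSE
}

# random fixation configuration generator for the oracle comparison
random_fixations <- function(k, seed) {
  set.seed(seed)
  onset <- sort(runif(k, 0, 10.5))
  tibble::tibble(
    onset = onset,
    offset = onset + runif(k, 0.1, 0.5),
    cx_px = runif(k, 0, 1920),
    cy_px = runif(k, 0, 1080)
  )
}
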