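# --- blink correction -------------------------------------------------------

test_that("blink-band gaps are relabelled with their 25 ms margins", {
  # 150 ms gap (45 samples) inside a valid trace
  s <- make_stream(600)
  s <- drop_samples(s, 301:345)
  out <- correct_blinks(s)
  pad <- 7  # samples at most 25 ms from the gap at 300 Hz
  expect_true(all(out$status[(301 - pad):(345 + pad)] == "blink"))
  expect_true(all(out$status[1:(300 - pad)] == "valid"))
  expect_true(all(out$status[(346 + pad):600] == "valid"))
})

test_that("gaps outside the 75-250 ms band are left as missing", {
  s <- make_stream(600)
  s <- drop_samples(s, 301:315)       # 50 ms: below the band
  out <- correct_blinks(s)
  expect_true(all(out$status[301:315] == "missing"))
  expect_true(all(out$status[300] == "valid"))

  s2 <- make_stream(600)
  s2 <- drop_samples(s2, 301:376)     # 253 ms: above the band
  out2 <- correct_blinks(s2)
  expect_true(all(out2$status[301:376] == "missing"))
})

test_that("blink band boundaries are handled exactly", {
  # 23 samples = 76.7 ms: inside; 22 samples = 73.3 ms: outside
  s_in <- correct_blinks(drop_samples(make_stream(600), 301:323))
  expect_true(all(s_in$status[301:323] == "blink"))
  s_out <- correct_blinks(drop_samples(make_stream(600), 301:322))
  expect_true(all(s_out$status[301:322] == "missing"))
  # 75 samples = 250 ms: inside; 76 samples: outside
  s_hi <- correct_blinks(drop_samples(make_stream(600), 301:375))
  expect_true(all(s_hi$status[301:375] == "blink"))
  s_over <- correct_blinks(drop_samples(make_stream(600), 301:376))
  expect_true(all(s_over$status[301:376] == "missing"))
})

test_that("a fully valid segment passes through blink correction unchanged", {
  s <- make_stream(600)
  expect_identical(correct_blinks(s), s)
})

# --- plausibility filter ----------------------------------------------------

test_that("implausible velocities and accelerations are flagged on raw data", {
  s <- combine_gaze(make_stream(600))
  expect_true(all(drop_implausible(s, geometry = geom)$status == "valid"))

  # single-sample step of 10 deg: 3000 deg/s at 300 Hz
  jump_px <- deg_to_px(10, geom)
  s2 <- make_stream(600)
  s2$x_l[301:600] <- s2$x_l[301:600] + jump_px
  s2$x_r <- s2$x_l
  out <- drop_implausible(combine_gaze(s2), geometry = geom)
  expect_equal(out$status[301], "implausible")
  expect_true(all(out$status[1:300] == "valid"))

  # smooth 20 deg/s drift passes
  s3 <- make_stream(600)
  drift <- deg_to_px(20, geom) / 300 * (seq_len(600) - 1)
  s3$x_l <- s3$x_l + drift; s3$x_r <- s3$x_l
  out3 <- drop_implausible(combine_gaze(s3), geometry = geom)
  expect_true(all(out3$status == "valid"))
})

# --- smoothing --------------------------------------------------------------

test_that("Savitzky-Golay smoothing preserves polynomial traces", {
  s <- combine_gaze(make_stream(600))
  out <- smooth_gaze(s)
  expect_equal(out$x, s$x, tolerance = 1e-9)

  ramp <- combine_gaze(make_stream(600))
  ramp$x <- ramp$x + 0.5 * seq_len(600)
  expect_equal(smooth_gaze(ramp)$x, ramp$x, tolerance = 1e-9)
})

test_that("smoothing attenuates an isolated spike and respects gaps", {
  s <- combine_gaze(make_stream(600))
  s$x[300] <- s$x[300] + 30
  out <- smooth_gaze(s)
  expect_lt(max(abs(out$x - 960)), 30)

  # runs shorter than the window are left unsmoothed
  short <- combine_gaze(drop_samples(make_stream(30), 11:30))
  short$x[1:10] <- short$x[1:10] + c(rep(0, 9), 25)
  out2 <- smooth_gaze(short)
  expect_equal(out2$x[1:10], short$x[1:10])
})

# --- velocity ---------------------------------------------------------------

test_that("velocity is zero when stationary and correct under uniform motion", {
  s <- compute_velocity(smooth_gaze(combine_gaze(make_stream(600))), geom)
  v <- s$vel_deg_s
  expect_true(all(abs(v[is.finite(v)]) < 1e-9))

  # 1 deg per 10 ms = 100 deg/s (small-angle regime near screen centre)
  step_px <- deg_to_px(100 / 300, geom)
  s2 <- combine_gaze(make_stream(600, x = 400))
  s2$x <- 400 + step_px * (seq_len(600) - 1)
  s2 <- compute_velocity(s2, geom)
  mid <- s2$vel_deg_s[100:500]
  expect_equal(mean(mid), 100, tolerance = 0.02)
})

test_that("velocity is undefined at run edges and never crosses gaps", {
  s <- combine_gaze(drop_samples(make_stream(600), 301:345))
  s <- compute_velocity(s, geom)
  expect_true(is.na(s$vel_deg_s[1]))
  expect_true(is.na(s$vel_deg_s[300]))  # edge before the gap
  expect_true(is.na(s$vel_deg_s[346]))  # edge after the gap
})

# --- adaptive threshold -----------------------------------------------------

test_that("adaptive threshold converges to mean + 6 SD of the noise", {
  set.seed(42)
  v <- rnorm(3000, mean = 5, sd = 2)
  th <- adaptive_saccade_threshold(v)
  expect_equal(th$peak, mean(v) + 6 * sd(v), tolerance = 0.3)
  expect_equal(th$onset, mean(v) + 3 * sd(v), tolerance = 0.3)
  expect_false(th$degenerate)
})

test_that("degenerate all-zero velocities fall back to the configured floor", {
  th <- adaptive_saccade_threshold(rep(0, 2000))
  expect_true(th$degenerate)
  expect_equal(th$peak, cleaning_config()$pt_floor)
})

test_that("embedded saccades are excluded from the threshold estimate", {
  set.seed(7)
  v <- abs(rnorm(2000, 10, 4))
  v[sample(2000, 60)] <- 300  # saccade samples
  th <- adaptive_saccade_threshold(v)
  expect_lt(th$peak, 300)
  expect_gt(th$peak, max(abs(rnorm(2000, 10, 4))) * 0.5)
  # saccade samples excluded: threshold near noise-only closed form
  noise_only <- v[v < 100]
  expect_equal(th$peak, mean(noise_only) + 6 * sd(noise_only),
               tolerance = 2)
})

test_that("doubling simulated noise strictly increases the peak threshold", {
  plan <- plan_rja_trial(TRUE, "left", aois, pg, seed = 5)
  pts <- sapply(c(0.15, 0.3, 0.6), function(ns) {
    mean(sapply(1:5, function(i) {
      sim <- simulate_trial_gaze(plan, pg, noise_sd_deg = ns, seed = 70 + i)
      detect_gaze_events(sim$samples, cleaning_config(), geom)$thresholds$peak
    }))
  })
  expect_true(all(diff(pts) > 0))
})

# --- saccade and fixation detection -----------------------------------------

test_that("saccade detection finds isolated events and keeps 50 ms-separated pairs", {
  cfg <- cleaning_config()
  s <- combine_gaze(make_stream(900))
  s <- compute_velocity(smooth_gaze(s), geom)
  th <- list(peak = 50, onset = 20, degenerate = FALSE)
  expect_equal(nrow(detect_saccades(s, th, cfg, geom)), 0)

  # two 8-deg saccades at main-sequence speed (77 ms) separated by a
  # 50 ms fixation plateau
  d8 <- 2 * 8 / (500 * (1 - exp(-8 / 15)))
  plan <- trial_plan(
    x = c(960, 960 + deg_to_px(8, geom), 960),
    y = c(540, 540, 540),
    duration = c(1.0, 0.05, 0.5),
    onset = c(0, 1.0 + d8, 1.0 + 2 * d8 + 0.05)
  )
  sim <- simulate_trial_gaze(plan, pg, noise_sd_deg = 0, seed = 1)
  det <- detect_gaze_events(sim$samples, cfg, geom)
  sacc <- det$events[det$events$kind == "saccade", ]
  expect_equal(nrow(sacc), 2)
  expect_equal(sacc$amplitude_deg, c(8, 8), tolerance = 0.05)
})

test_that("synthetic saccade peak velocity is recovered within 5%", {
  # amplitude chosen so the main-sequence peak velocity is 300 deg/s
  amp <- -15 * log(1 - 300 / 500)
  plan <- trial_plan(x = c(960, 960 + deg_to_px(amp, geom)), y = c(540, 540),
                     duration = c(2, 2))
  sim <- simulate_trial_gaze(plan, pg, noise_sd_deg = 0, seed = 1)
  true_peak <- sim$truth$peak_vel[sim$truth$kind == "saccade"]
  det <- detect_gaze_events(sim$samples, cleaning_config(), geom)
  got <- det$events$peak_vel[det$events$kind == "saccade"]
  expect_equal(length(got), 1)
  expect_equal(got, true_peak, tolerance = 0.05)
})

test_that("fixation classification enforces the 100 ms minimum duration", {
  cfg <- cleaning_config()
  # constant 200 ms run -> one fixation at that position
  s <- combine_gaze(make_stream(60, x = 700, y = 300))
  s <- compute_velocity(s, geom)
  fx <- detect_fixations(s, detect_saccades(
    s, list(peak = 50, onset = 20), cfg, geom), cfg, geom)
  expect_equal(nrow(fx), 1)
  expect_equal(c(fx$cx_px, fx$cy_px), c(700, 300))

  # stable 80 ms run -> nothing
  s2 <- combine_gaze(make_stream(24))
  s2 <- compute_velocity(s2, geom)
  fx2 <- detect_fixations(s2, fx[0, ], cfg, geom)
  expect_equal(nrow(fx2), 0)
})

test_that("a planned fixation-saccade-fixation trial yields exactly 2 fixations", {
  plan <- trial_plan(x = c(500, 1400), y = c(540, 540), duration = c(4, 4))
  sim <- simulate_trial_gaze(plan, pg, noise_sd_deg = 0, seed = 2)
  det <- detect_gaze_events(sim$samples, cleaning_config(), geom)
  expect_equal(sum(det$events$kind == "fixation"), 2)
  expect_equal(sum(det$events$kind == "saccade"), 1)
})

# --- trial quality ----------------------------------------------------------

test_that("trials are dropped below 50% retained data, kept at exactly 50%", {
  s <- make_stream(3300)
  q <- trial_quality(s)
  expect_equal(q$missing_fraction, 0)
  expect_false(q$dropped)

  s60 <- drop_samples(make_stream(3300), 1:1980)  # 60% missing
  expect_true(trial_quality(s60)$dropped)

  s50 <- drop_samples(make_stream(3300), 1:1650)  # exactly half
  q50 <- trial_quality(s50)
  expect_equal(q50$missing_fraction, 0.5)
  expect_false(q50$dropped)
})

# --- properties -------------------------------------------------------------

test_that("cleaning is monotone: no stage revalidates a sample", {
  for (seed in 1:5) {
    plan <- plan_rja_trial(seed %% 2 == 0, "right", aois, pg, seed = seed)
    blinks <- tibble::tibble(onset = c(2.0, 6.5), duration = c(0.12, 0.18))
    sim <- simulate_trial_gaze(plan, pg, noise_sd_deg = 0.25,
                               blinks = blinks, seed = seed)
    s <- combine_gaze(sim$samples)
    bad0 <- which(s$status != "valid")
    s1 <- correct_blinks(s)
    bad1 <- which(s1$status != "valid")
    expect_true(all(bad0 %in% bad1))
    s2 <- drop_implausible(s1, geometry = geom)
    expect_true(all(bad1 %in% which(s2$status != "valid")))
  }
})

test_that("saccades and fixations never overlap and fixations avoid blinks", {
  for (seed in 1:5) {
    plan <- plan_rja_trial(TRUE, "left", aois, pg, seed = seed)
    blinks <- tibble::tibble(onset = 7.0, duration = 0.15)
    sim <- simulate_trial_gaze(plan, pg, noise_sd_deg = 0.2,
                               blinks = blinks, seed = seed)
    cfg <- cleaning_config(fixation_criterion = "dispersion")
    det <- detect_gaze_events(sim$samples, cfg, geom)
    sacc <- det$events[det$events$kind == "saccade", ]
    fx <- det$events[det$events$kind == "fixation", ]
    for (i in seq_len(nrow(fx))) {
      if (nrow(sacc)) {
        expect_true(all(fx$offset[i] <= sacc$onset + 1e-9 |
                          fx$onset[i] >= sacc$offset - 1e-9))
      }
      inside <- det$samples$t >= fx$onset[i] & det$samples$t < fx$offset[i]
      expect_true(all(det$samples$status[inside] == "valid"))
    }
  }
})

test_that("event counts are recovered and boundaries agree within the filter span", {
  cfg <- cleaning_config(fixation_criterion = "dispersion")
  ok <- 0
  n <- 25
  for (i in seq_len(n)) {
    plan <- plan_rja_trial(i %% 2 == 0, if (i %% 4 < 2) "left" else "right",
                           aois, pg, seed = i)
    sim <- simulate_trial_gaze(plan, pg, noise_sd_deg = 0.2, seed = 300 + i)
    det <- detect_gaze_events(sim$samples, cfg, geom)
    same <- sum(sim$truth$kind == "saccade") ==
      sum(det$events$kind == "saccade") &&
      sum(sim$truth$kind == "fixation") ==
        sum(det$events$kind == "fixation")
    if (same) {
      ok <- ok + 1
      fx_true <- sim$truth[sim$truth$kind == "fixation", ]
      fx_det <- det$events[det$events$kind == "fixation", ]
      # boundaries within half the 70 ms smoothing window
      expect_true(all(abs(fx_true$onset - fx_det$onset) <= 0.040))
      expect_true(all(abs(fx_true$offset - fx_det$offset) <= 0.040))
    }
  }
  expect_gte(ok, round(0.9 * n))
})
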