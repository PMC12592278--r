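flat_cohort <- function(logodds, n = 30, seed = 1, sd_p = 0, sd_t = 0) {
  cohort_spec(
    group_sizes = c("A-FFIP" = n, "EIAU" = n),
    timepoints = list("A-FFIP" = "BL", "EIAU" = "BL"),
    fixed_logodds = tibble::tibble(group = c("A-FFIP", "EIAU"),
                                   timepoint = "BL", logodds = logodds),
    sd_participant = sd_p, sd_trial = sd_t, bps_rja_slope = 0,
    bps_sd_participant = 0, bps_sd_trial = 0, seed = seed
  )
}

test_that("an intercept-only binomial fit matches the logit of the rate", {
  f <- simulate_rja_outcomes(flat_cohort(c(-1.1, -1.1), seed = 11))
  fit <- fit_rja_glmm(f, outcome = "rja", fixed = ~1)
  # a residual crumb of trial variance can shift the intercept slightly
  expect_lt(abs(unname(lme4::fixef(fit$fit))[1] - qlogis(mean(f$rja))),
            5e-3)
  g <- glance(fit)
  expect_lt(g$sigma2_participant, 0.05)
  expect_equal(g$mR2, 0)
})

test_that("a gaussian null fit on BPS shows no effects and near-zero mR2", {
  co <- flat_cohort(c(0, 0), seed = 12)
  f <- simulate_rja_outcomes(co)
  set.seed(2)
  f$bps <- 4.3 + rnorm(nrow(f), 0, 0.3)
  fit <- fit_rja_glmm(f, outcome = "bps", fixed = ~ group,
                      family = "gaussian")
  td <- tidy(fit)
  expect_lt(abs(td$estimate[td$term == "groupEIAU"]), 0.05)
  expect_lt(glance(fit)$mR2, 0.01)
})

test_that("variance-partition R2 reproduces the closed-form cases", {
  r0 <- nakagawa_r2(sigma_f2 = 0, sigma_random2 = 0, family = "binomial")
  expect_equal(r0$mR2, 0)
  expect_equal(r0$cR2, 0)
  rb <- nakagawa_r2(sigma_f2 = 1, sigma_random2 = 2, family = "binomial")
  expect_equal(rb$mR2, 1 / (3 + pi^2 / 3))
  expect_equal(rb$cR2, 3 / (3 + pi^2 / 3))
  expect_equal(round(rb$mR2, 3), 0.159)
  expect_equal(round(rb$cR2, 3), 0.477)
  rg <- nakagawa_r2(sigma_f2 = 1, sigma_random2 = 1, sigma_resid2 = 2,
                    family = "gaussian")
  expect_equal(rg$mR2, 0.25)
  expect_equal(rg$cR2, 0.5)
})

test_that("fitted models keep 0 <= mR2 <= cR2 <= 1", {
  for (seed in c(3, 4)) {
    f <- simulate_rja_outcomes(flat_cohort(c(-0.4, -1.3), seed = seed,
                                           sd_p = 0.8, sd_t = 0.2))
    fit <- fit_rja_glmm(f, outcome = "rja", fixed = ~ group)
    r2 <- nakagawa_r2(fit)
    expect_gte(r2$mR2, 0)
    expect_lte(r2$mR2, r2$cR2)
    expect_lte(r2$cR2, 1)
  }
})

test_that("marginal contrasts expose odds ratios on the link scale", {
  f <- simulate_rja_outcomes(flat_cohort(c(-0.3, -1.2), seed = 5,
                                         sd_p = 0.6))
  fit <- fit_rja_glmm(f, outcome = "rja", fixed = ~ group)
  cells <- tibble::tibble(group = c("A-FFIP", "EIAU"))
  mc <- marginal_contrasts(fit, cells, boot_k = 0)
  beta <- lme4::fixef(fit$fit)
  expect_equal(mc$cells$mean, unname(plogis(c(beta[1], beta[1] + beta[2]))))
  expect_equal(mc$contrasts$estimate, unname(exp(-beta[2])))
  expect_gt(mc$contrasts$estimate, 0)
  # identical cells give OR exactly 1
  mc_same <- marginal_contrasts(fit, tibble::tibble(group = c("A-FFIP",
                                                              "A-FFIP")),
                                boot_k = 0)
  expect_equal(mc_same$contrasts$estimate, 1)
})

test_that("odds-ratio contrasts are invariant to the factor reference level", {
  f <- simulate_rja_outcomes(flat_cohort(c(-0.3, -1.2), seed = 6,
                                         sd_p = 0.6))
  fit1 <- fit_rja_glmm(f, outcome = "rja", fixed = ~ group)
  f2 <- f
  f2$group <- factor(f2$group, levels = c("EIAU", "A-FFIP"))
  fit2 <- fit_rja_glmm(f2, outcome = "rja", fixed = ~ group)
  cells <- tibble::tibble(group = c("A-FFIP", "EIAU"))
  or1 <- marginal_contrasts(fit1, cells, boot_k = 0)$contrasts$estimate
  or2 <- marginal_contrasts(fit2, cells, boot_k = 0)$contrasts$estimate
  expect_equal(or1, or2, tolerance = 1e-4)
})

test_that("bootstrap intervals contain the point estimate; empty cells error", {
  f <- simulate_rja_outcomes(flat_cohort(c(-0.3, -1.2), n = 15, seed = 7,
                                         sd_p = 0.5))
  fit <- fit_rja_glmm(f, outcome = "rja", fixed = ~ group)
  cells <- tibble::tibble(group = c("A-FFIP", "EIAU"))
  mc <- marginal_contrasts(fit, cells, boot_k = 25, seed = 2)
  expect_true(mc$contrasts$conf.low <= mc$contrasts$estimate)
  expect_true(mc$contrasts$conf.high >= mc$contrasts$estimate)
  expect_error(
    marginal_contrasts(fit, tibble::tibble(group = c("A-FFIP", "none"))),
    "no data")
})

test_that("condition screening finds a target-side effect and skips degenerate factors", {
  co <- flat_cohort(c(-0.5, -0.5), n = 30, seed = 8, sd_p = 0.4)
  f <- simulate_rja_outcomes(co)
  # inject a strong target-side effect
  set.seed(81)
  flip <- f$target_side == "left" & runif(nrow(f)) < 0.35
  f$rja[flip] <- TRUE
  res <- condition_screen(f, outcome = "rja")
  expect_lt(res$p.value[res$factor == "target_side"], 0.05)
  f_one <- f
  f_one$stimulus <- "ball"
  expect_message(res2 <- condition_screen(f_one, outcome = "rja",
                                          factors = "stimulus"),
                 "single-level")
  expect_true(is.na(res2$statistic))
})

test_that("null condition factors stay near the null expectation", {
  f <- simulate_rja_outcomes(flat_cohort(c(-0.8, -0.8), n = 25, seed = 9,
                                         sd_p = 0.4))
  res <- condition_screen(f, outcome = "rja")
  expect_true(all(res$p.value > 0.01, na.rm = TRUE))
})

test_that("cascade models recover exact, null, and noisy linear relations", {
  d <- tibble::tibble(dx = rnorm(50), dy = NA_real_)
  d$dy <- -1.0 * d$dx
  fit <- suppressWarnings(cascade_lm(d, "dy", "dx"))
  co <- fit$coefficients
  expect_equal(unname(co$estimate[co$term == "dx"]), -1.0,
               tolerance = 1e-9)
  expect_equal(fit$r.squared, 1, tolerance = 1e-9)

  set.seed(10)
  d2 <- tibble::tibble(dx = rnorm(200), dy = rnorm(200))
  fit2 <- cascade_lm(d2, "dy", "dx")
  expect_lt(abs(fit2$coefficients$estimate[2]), 0.15)

  expect_error(cascade_lm(d2[1:3, ], "dy", "dx"), "too few")

  # standardized slope recovery under noise
  set.seed(11)
  x <- rnorm(100)
  y <- -1.2 * x + rnorm(100, 0, 1.45)  # R2 about 0.4
  d3 <- tibble::tibble(dx = x, dy = y)
  fit3 <- cascade_lm(d3, "dy", "dx")
  beta_std <- -1.2 * sd(x) / sd(y)
  est <- fit3$coefficients[fit3$coefficients$term == "dx", ]
  expect_true(est$conf.low <= beta_std && beta_std <= est$conf.high)
})

test_that("change scores aggregate per-trial flags to participant level", {
  f <- tibble::tibble(
    participant = rep(c("a", "b"), each = 4),
    timepoint = rep(c("BL", "BL", "ET", "ET"), 2),
    rja = c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)
  )
  cs <- change_scores(f, "rja", "BL", "ET")
  expect_equal(cs$change, c(0.5, 0.5))
})

test_that("dropout ANOVA matches a hand-computed balanced 2x2 table", {
  d <- tibble::tibble(
    group = rep(c("A", "B"), each = 4),
    retained = rep(c(TRUE, FALSE), 4),
    y = c(10, 12, 14, 16, 20, 22, 24, 26)
  )
  tab <- dropout_anova(d, "y", "group", "retained")
  # hand computation: grand mean 18; group means 13, 23 -> SS_group = 200
  gm <- mean(d$y)
  ss_group <- sum(4 * (tapply(d$y, d$group, mean) - gm)^2)
  ss_ret <- sum(4 * (tapply(d$y, d$retained, mean) - gm)^2)
  expect_equal(tab$sumsq[tab$term == "group"], ss_group)
  expect_equal(tab$sumsq[tab$term == "retained"], ss_ret)
  expect_equal(ss_group, 200)

  # constant outcome: all F reported as zero
  d0 <- d; d0$y <- 5
  tab0 <- dropout_anova(d0, "y", "group", "retained")
  expect_true(all(tab0$statistic[1:3] == 0))

  # near-empty cell errors with the cell named
  d_bad <- d[-c(2, 4), ]
  expect_error(dropout_anova(d_bad, "y", "group", "retained"), "fewer than 2")
})

test_that("dropout ANOVA detects a true group difference at scale", {
  set.seed(12)
  d <- tibble::tibble(
    group = rep(c("A", "B"), each = 200),
    retained = rep(c(TRUE, FALSE), 200),
    y = rnorm(400) + rep(c(0, 1), each = 200)
  )
  tab <- dropout_anova(d, "y", "group", "retained")
  expect_lt(tab$p.value[tab$term == "group"], 1e-6)
})

test_that("noncentral-F power is alpha at zero effect and monotone", {
  expect_equal(anova_power(0, 60, 1), 0.05, tolerance = 1e-9)
  expect_gt(anova_power(0.12, 600, 1), 0.999)
  powers <- sapply(c(40, 60, 100, 200), function(n) anova_power(0.12, n, 1))
  expect_true(all(diff(powers) > 0))
})

test_that("closed-form power agrees with a simulation oracle", {
  # two-level factor in a balanced 2x2, eta2 = 0.12 -> lambda = f2 * N
  set.seed(13)
  n <- 60
  eff <- sqrt(0.12 / 0.88)  # so that sum over obs of eff^2 = f2 * N = lambda
  g <- rep(c(-1, 1), each = n / 2)
  r <- rep(c(-1, 1), times = n / 2)
  reps <- 1500
  rej <- 0
  for (i in seq_len(reps)) {
    y <- eff * g + rnorm(n)
    f <- anova(lm(y ~ factor(g) * factor(r)))
    if (f$`Pr(>F)`[1] < 0.05) rej <- rej + 1
  }
  sim_power <- rej / reps
  expect_equal(anova_power(0.12, 60, 1), sim_power, tolerance = 0.035)
})
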