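#' Quasi-Bayesian causal mediation of a group difference
#'
#' Tests whether a between-group difference in a per-trial outcome (RJA
#' likelihood by default) is mediated by an arousal measure (BPS or SEPR),
#' following the simulation-based potential-outcomes approach. Two models
#' are fit: a participant-level linear mediator model (mediator on
#' treatment, plus the baseline mediator value when supplied -- the
#' moderated-mediation control) and a trial-level outcome model (logistic
#' for a binary outcome) on treatment, mediator, and baseline. `k`
#' quasi-Bayesian draws are then taken from the asymptotic normal sampling
#' distributions of both coefficient vectors; each draw simulates the
#' counterfactual mediator under both treatments (including the mediator
#' model's residual noise) and averages potential outcomes over the sample
#' to yield the average causal mediation effect (ACME), the average direct
#' effect (ADE), and the total effect on the outcome-probability scale.
#' By construction ACME + ADE equals the total effect in every draw.
#' Point estimates are means over draws; intervals are the [2.5%, 97.5%]
#' percentiles; p-values are two-sided tail proportions.
#'
#' @param features Per-trial feature tibble.
#' @param mediator Column holding the per-trial mediator (aggregated to
#'   participant means internally).
#' @param treatment Column holding the group label.
#' @param treat_levels Length-2 character vector `c(control, treated)`.
#' @param outcome Outcome column (binary unless
#'   `outcome_family = "gaussian"`).
#' @param baseline Optional participant-level tibble with columns
#'   `participant` and `baseline` (for example the baseline-timepoint
#'   mediator mean), entered in both models.
#' @param outcome_family `"binomial"` or `"gaussian"`.
#' @param k Number of quasi-Bayesian draws (1000 as published).
#' @param seed Integer RNG seed.
#' @return An object of class `rja_mediation` with per-draw effects and a
#'   summary; see [tidy.rja_mediation()].
#' @export
mediate_rja <- function(features, mediator = "bps", treatment = "group",
                        treat_levels, outcome = "rja", baseline = NULL,
                        outcome_family = c("binomial", "gaussian"),
                        k = 1000, seed = 1) {
  outcome_family <- match.arg(outcome_family)
  stopifnot(length(treat_levels) == 2)
  d <- features[features[[treatment]] %in% treat_levels, , drop = FALSE]
  d <- d[!is.na(d[[mediator]]) & !is.na(d[[outcome]]), , drop = FALSE]
  d$treat <- as.integer(d[[treatment]] == treat_levels[2])
  # participant-level mediator (internal column name avoids collisions)
  med_p <- d %>%
    dplyr::group_by(.data$participant) %>%
    dplyr::summarise(m_part = mean(.data[[mediator]]),
                     treat = .data$treat[1], .groups = "drop")
  if (!is.null(baseline)) {
    med_p <- dplyr::inner_join(med_p, baseline, by = "participant")
    d <- dplyr::inner_join(
      d, baseline, by = "participant")
  }
  d <- dplyr::left_join(d, med_p[, c("participant", "m_part")],
                        by = "participant")
  has_base <- !is.null(baseline)
  m_form <- if (has_base) m_part ~ treat + baseline else m_part ~ treat
  med_fit <- stats::lm(m_form, data = med_p)
  y_form <- if (has_base) {
    stats::as.formula(paste(outcome, "~ treat + m_part + baseline"))
  } else {
    stats::as.formula(paste(outcome, "~ treat + m_part"))
  }
  if (outcome_family == "binomial") {
    d[[outcome]] <- as.integer(as.logical(d[[outcome]]))
    out_fit <- stats::glm(y_form, data = d, family = stats::binomial())
    separation <- any(abs(stats::coef(out_fit)) > 15) || !out_fit$converged
    invlink <- stats::plogis
  } else {
    out_fit <- stats::glm(y_form, data = d, family = stats::gaussian())
    separation <- FALSE
    invlink <- identity
  }
  bm <- stats::coef(med_fit)
  Vm <- stats::vcov(med_fit)
  sm <- stats::sigma(med_fit)
  by <- stats::coef(out_fit)
  Vy <- stats::vcov(out_fit)
  n <- nrow(d)
  base_vec <- if (has_base) d$baseline else NULL
  draws <- with_local_seed(seed, {
    Lm <- chol(Vm)
    Ly <- chol(Vy)
    out <- matrix(NA_real_, nrow = k, ncol = 4,
                  dimnames = list(NULL, c("acme", "ade", "total", "prop")))
    for (s in seq_len(k)) {
      bms <- bm + drop(t(Lm) %*% stats::rnorm(length(bm)))
      bys <- by + drop(t(Ly) %*% stats::rnorm(length(by)))
      eps <- stats::rnorm(n, 0, sm)
      mhat <- function(tr) {
        mu <- bms["(Intercept)"] + bms["treat"] * tr
        if (has_base) mu <- mu + bms["baseline"] * base_vec
        mu + eps
      }
      m0 <- mhat(0)
      m1 <- mhat(1)
      yhat <- function(tr, m) {
        eta <- bys["(Intercept)"] + bys["treat"] * tr + bys["m_part"] * m
        if (has_base) eta <- eta + bys["baseline"] * base_vec
        mean(invlink(eta))
      }
      y11 <- yhat(1, m1); y10 <- yhat(1, m0)
      y01 <- yhat(0, m1); y00 <- yhat(0, m0)
      acme <- ((y11 - y10) + (y01 - y00)) / 2
      ade <- ((y11 - y01) + (y10 - y00)) / 2
      total <- y11 - y00
      out[s, ] <- c(acme, ade, total,
                    if (abs(total) > 1e-12) acme / total else NA_real_)
    }
    out
  })
  summarise_eff <- function(v) {
    v <- v[is.finite(v)]
    tibble::tibble(
      estimate = mean(v),
      conf.low = stats::quantile(v, 0.025, names = FALSE),
      conf.high = stats::quantile(v, 0.975, names = FALSE),
      p.value = 2 * min(mean(v <= 0), mean(v >= 0))
    )
  }
  summary_tbl <- dplyr::bind_rows(
    acme = summarise_eff(draws[, "acme"]),
    ade = summarise_eff(draws[, "ade"]),
    total = summarise_eff(draws[, "total"]),
    prop_mediated = summarise_eff(draws[, "prop"]),
    .id = "effect"
  )
  structure(
    list(draws = tibble::as_tibble(draws), summary = summary_tbl,
         mediator = mediator, treat_levels = treat_levels, k = k,
         n_trials = n, n_participants = nrow(med_p),
         mediator_fit = med_fit, outcome_fit = out_fit,
         unreliable = separation),
    class = "rja_mediation"
  )
}

#' @export
print.rja_mediation <- function(x, ...) {
  cat(sprintf(
    "<rja_mediation> mediator %s, %s vs %s; k = %d (%d participants)%s\n",
    x$mediator, x$treat_levels[2], x$treat_levels[1], x$k,
    x$n_participants,
    if (x$unreliable) " [flagged unreliable: possible separation]" else ""))
  print(x$summary)
  invisible(x)
}

#' Tidy a mediation result
#'
#' @param x An `rja_mediation` object.
#' @param ... Unused.
#' @return A tibble with one row per effect (ACME, ADE, total effect,
#'   proportion mediated): `effect`, `estimate`, `conf.low`, `conf.high`,
#'   `p.value`.
#' @export
tidy.rja_mediation <- function(x, ...) x$summary

#' @export
glance.rja_mediation <- function(x, ...) {
  tibble::tibble(k = x$k, n_participants = x$n_participants,
                 n_trials = x$n_trials, unreliable = x$unreliable)
}
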