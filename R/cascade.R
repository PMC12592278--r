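#' Cascade model: do early changes drive later development?
#'
#' Ordinary least squares of a change score (later minus baseline) in a
#' developmental outcome on a change score in a key variable (per-
#' participant RJA likelihood, BPS, or SEPR), reported as standardized
#' coefficients with confidence intervals. An optional covariate (for
#' example the baseline value of the predictor) gives the adjusted
#' variant.
#'
#' @param data Participant-level tibble of change scores.
#' @param outcome,predictor Column names of the change scores.
#' @param covariate Optional covariate column name.
#' @param conf Confidence level.
#' @return A list of class `rja_cascade` with the `lm` fit and a tidy
#'   coefficient table (standardized estimates).
#' @export
cascade_lm <- function(data, outcome, predictor, covariate = NULL,
                       conf = 0.95) {
  vars <- c(outcome, predictor, covariate)
  stopifnot(all(vars %in% names(data)))
  d <- stats::na.omit(as.data.frame(data[, vars]))
  n_pred <- length(vars) - 1
  if (nrow(d) <= n_pred + 2) {
    stop("too few complete observations (n = ", nrow(d), ") for ",
         n_pred, " predictor(s)")
  }
  dz <- as.data.frame(lapply(d, function(v) {
    s <- stats::sd(v)
    if (s == 0) v - mean(v) else (v - mean(v)) / s
  }))
  form <- stats::as.formula(
    paste(outcome, "~", paste(c(predictor, covariate), collapse = " + ")))
  fit <- stats::lm(form, data = dz)
  ci <- stats::confint(fit, level = conf)
  sm <- summary(fit)
  coefs <- tibble::tibble(
    term = rownames(sm$coefficients),
    estimate = sm$coefficients[, 1],
    std.error = sm$coefficients[, 2],
    statistic = sm$coefficients[, 3],
    p.value = sm$coefficients[, 4],
    conf.low = ci[, 1],
    conf.high = ci[, 2]
  )
  structure(list(fit = fit, coefficients = coefs,
                 r.squared = sm$r.squared, n = nrow(d)),
            class = "rja_cascade")
}

#' @export
print.rja_cascade <- function(x, ...) {
  cat(sprintf("<rja_cascade> n = %d, R2 = %.3f\n", x$n, x$r.squared))
  print(x$coefficients)
  invisible(x)
}

#' @export
tidy.rja_cascade <- function(x, ...) x$coefficients

#' @export
glance.rja_cascade <- function(x, ...) {
  tibble::tibble(r.squared = x$r.squared, n = x$n)
}

#' Per-participant change scores from the per-trial feature table
#'
#' Aggregates per-trial features to the participant-timepoint level (RJA
#' likelihood as the mean of the per-trial flags; BPS/SEPR as means) and
#' forms later-minus-baseline change scores.
#'
#' @param features Per-trial feature tibble with `participant`,
#'   `timepoint` and the variable.
#' @param var Variable to aggregate (`"rja"`, `"bps"`, or `"sepr"`).
#' @param from,to Timepoint labels (change = `to` minus `from`).
#' @return Tibble with `participant`, the two aggregated values, and
#'   `change`.
#' @export
change_scores <- function(features, var = "rja", from = "BL", to = "ET") {
  agg <- features %>%
    dplyr::group_by(.data$participant, .data$timepoint) %>%
    dplyr::summarise(value = mean(as.numeric(.data[[var]]), na.rm = TRUE),
                     .groups = "drop")
  wide <- tidyr::pivot_wider(agg, names_from = "timepoint",
                             values_from = "value")
  stopifnot(all(c(from, to) %in% names(wide)))
  wide$change <- wide[[to]] - wide[[from]]
  wide[!is.na(wide$change), c("participant", from, to, "change")]
}

#' Dropout analysis: two-way ANOVA of group by retention status
#'
#' Type-II sums-of-squares two-way ANOVA with interaction, testing whether
#' participants lost to follow-up differed from retained ones (and
#' differentially by treatment group) on a baseline variable. Every cell
#' of the 2 x 2 design must contain at least two observations.
#'
#' @param data Participant-level tibble.
#' @param outcome Outcome column name.
#' @param group,retention Two-level factor column names.
#' @return A tibble with one row per term: `term`, `sumsq`, `df`,
#'   `statistic` (F), `p.value`, and `eta.sq` (share of total SS).
#' @export
dropout_anova <- function(data, outcome, group = "group",
                          retention = "retained") {
  d <- as.data.frame(data[, c(outcome, group, retention)])
  d[[group]] <- factor(d[[group]])
  d[[retention]] <- factor(d[[retention]])
  stopifnot(nlevels(d[[group]]) == 2, nlevels(d[[retention]]) == 2)
  counts <- table(d[[group]], d[[retention]])
  if (any(counts < 2)) {
    bad <- which(counts < 2, arr.ind = TRUE)[1, ]
    stop(sprintf("cell %s x %s has fewer than 2 observations",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]))
  }
  form <- stats::as.formula(paste(outcome, "~", group, "*", retention))
  fit <- stats::lm(form, data = d)
  if (stats::var(d[[outcome]]) < 1e-24) {
    # constant outcome: every effect explains nothing
    terms <- c(group, retention, paste0(group, ":", retention), "Residuals")
    return(tibble::tibble(term = terms, sumsq = 0,
                          df = c(1L, 1L, 1L, nrow(d) - 4L),
                          statistic = c(0, 0, 0, NA),
                          p.value = c(1, 1, 1, NA), eta.sq = 0))
  }
  tab <- car::Anova(fit, type = 2)
  ss <- tab$`Sum Sq`
  total_ss <- sum(ss)
  fstat <- tab$`F value`
  fstat[!is.na(fstat) & !is.finite(fstat) & ss < 1e-24] <- 0
  fstat[is.nan(fstat)] <- 0  # degenerate 0/0 when the outcome is constant
  tibble::tibble(
    term = rownames(tab),
    sumsq = ss,
    df = tab$Df,
    statistic = fstat,
    p.value = tab$`Pr(>F)`,
    eta.sq = if (total_ss > 0) ss / total_ss else rep(0, length(ss))
  )
}

#' Power of a fixed-effects ANOVA contrast
#'
#' Noncentral-F power for an effect of size eta-squared in a fixed-effects
#' ANOVA: with Cohen's `f2 = eta2 / (1 - eta2)`, the noncentrality is
#' `lambda = f2 * n_total` and power is the probability that a noncentral
#' F(df1, n_total - n_cells, lambda) exceeds the central critical value at
#' `alpha`. A pure function of its arguments.
#'
#' @param eta2 Effect size (proportion of variance), in `[0, 1)`.
#' @param n_total Total sample size.
#' @param df1 Numerator degrees of freedom.
#' @param n_cells Number of design cells (4 for a 2 x 2 with interaction).
#' @param alpha Type-I error rate.
#' @return Power in `[0, 1]`.
#' @examples
#' anova_power(eta2 = 0.12, n_total = 60, df1 = 1)
#' @export
anova_power <- function(eta2, n_total, df1 = 1, n_cells = 4, alpha = 0.05) {
  stopifnot(eta2 >= 0, eta2 < 1, n_total > df1 + n_cells)
  f2 <- eta2 / (1 - eta2)
  lambda <- f2 * n_total
  df2 <- n_total - n_cells
  crit <- stats::qf(1 - alpha, df1, df2)
  1 - stats::pf(crit, df1, df2, ncp = lambda)
}
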