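#' Fit a mixed model for a per-trial outcome
#'
#' Binomial-logit GLMM (Laplace approximation, via [lme4::glmer()]) or
#' Gaussian LMM ([lme4::lmer()], REML) with crossed random intercepts for
#' participant and trial index -- the structure used for RJA likelihood,
#' BPS, and SEPR. Fixed effects default to group, timepoint, and their
#' interaction. Convergence and singularity are reported honestly on the
#' returned object; downstream contrasts refuse to run on non-converged
#' fits.
#'
#' @param features Per-trial feature tibble; must contain the outcome, the
#'   fixed-effect variables, and the grouping factors.
#' @param outcome Outcome column name (binary for the binomial family).
#' @param fixed One-sided formula of fixed effects
#'   (default `~ group * timepoint`).
#' @param family `"binomial"` or `"gaussian"`.
#' @param random Character vector of random-intercept grouping factors.
#' @return An object of class `rja_glmm`: a list with the `lme4` `fit`,
#'   the model frame, family, and `converged`/`singular` flags.
#' @examples
#' \donttest{
#' cohort <- cohort_spec(group_sizes = c("A-FFIP" = 8, "EIAU" = 8),
#'                       timepoints = list("A-FFIP" = "BL", "EIAU" = "BL"))
#' feats <- simulate_rja_outcomes(cohort)
#' fit <- fit_rja_glmm(feats, outcome = "rja", fixed = ~ group)
#' glance(fit)
#' }
#' @export
fit_rja_glmm <- function(features, outcome = "rja",
                         fixed = ~ group * timepoint,
                         family = c("binomial", "gaussian"),
                         random = c("participant", "trial")) {
  family <- match.arg(family)
  stopifnot(outcome %in% names(features))
  data <- as.data.frame(features)
  for (g in random) {
    if (!g %in% names(data)) stop("missing grouping factor: ", g)
    data[[g]] <- factor(data[[g]])
    if (nlevels(data[[g]]) < 2) stop("grouping factor with < 2 levels: ", g)
  }
  if (family == "binomial") {
    data[[outcome]] <- as.integer(as.logical(data[[outcome]]))
  }
  re_terms <- paste(sprintf("(1 | %s)", random), collapse = " + ")
  rhs <- paste(deparse(fixed[[2]]), re_terms, sep = " + ")
  form <- stats::as.formula(paste(outcome, "~", rhs))
  fit <- if (family == "binomial") {
    lme4::glmer(form, data = data, family = stats::binomial(),
                control = lme4::glmerControl(calc.derivs = FALSE))
  } else {
    lme4::lmer(form, data = data)
  }
  msgs <- fit@optinfo$conv$lme4$messages
  converged <- is.null(msgs) ||
    !any(grepl("failed to converge", unlist(msgs), ignore.case = TRUE))
  structure(
    list(
      fit = fit,
      data = data,
      outcome = outcome,
      fixed = fixed,
      family = family,
      random = random,
      converged = converged,
      singular = lme4::isSingular(fit)
    ),
    class = "rja_glmm"
  )
}

#' @export
print.rja_glmm <- function(x, ...) {
  cat(sprintf("<rja_glmm> %s %s, %d obs; converged: %s%s\n",
              x$outcome, x$family, nrow(x$data), x$converged,
              if (x$singular) " (singular fit)" else ""))
  print(lme4::fixef(x$fit))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy fixed effects of a mixed-model fit
#'
#' @param x An `rja_glmm` object.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value` (Wald).
#' @export
tidy.rja_glmm <- function(x, ...) {
  beta <- lme4::fixef(x$fit)
  se <- sqrt(diag(as.matrix(stats::vcov(x$fit))))
  z <- beta / se
  tibble::tibble(
    term = names(beta),
    estimate = unname(beta),
    std.error = unname(se),
    statistic = unname(z),
    p.value = 2 * stats::pnorm(-abs(z))
  )
}

#' One-row model summary with variance components and R-squared
#'
#' @param x An `rja_glmm` object.
#' @param ... Unused.
#' @return A tibble with random-intercept variances, log-likelihood,
#'   marginal and conditional R-squared, and convergence flags.
#' @export
glance.rja_glmm <- function(x, ...) {
  vc <- lme4::VarCorr(x$fit)
  vars <- vapply(vc, function(m) m[1, 1], numeric(1))
  r2 <- nakagawa_r2(x)
  tibble::tibble(
    sigma2_participant = unname(vars[x$random[1]]),
    sigma2_trial = unname(vars[x$random[2]]),
    logLik = as.numeric(stats::logLik(x$fit)),
    mR2 = r2$mR2,
    cR2 = r2$cR2,
    converged = x$converged,
    singular = x$singular
  )
}

#' Marginal and conditional coefficient of determination
#'
#' Variance-partition R-squared for mixed models: with `s2_f` the variance
#' of the fixed-effect linear predictor over the data, `s2_r` the summed
#' random-intercept variances, and a residual variance of `pi^2/3` for the
#' binomial-logit family (latent-scale convention) or the residual variance
#' for Gaussian fits, the marginal R2 is `s2_f / (s2_f + s2_r + resid)` and
#' the conditional R2 is `(s2_f + s2_r) / (s2_f + s2_r + resid)`.
#'
#' @param x An `rja_glmm` object, or NULL when supplying components
#'   directly.
#' @param sigma_f2,sigma_random2,sigma_resid2 Optional explicit variance
#'   components (used instead of `x`); `sigma_resid2` defaults to `pi^2/3`
#'   when `family = "binomial"`.
#' @param family Used with explicit components.
#' @return A list with `mR2` and `cR2`.
#' @examples
#' nakagawa_r2(sigma_f2 = 1, sigma_random2 = 2, family = "binomial")
#' @export
nakagawa_r2 <- function(x = NULL, sigma_f2 = NULL, sigma_random2 = NULL,
                        sigma_resid2 = NULL,
                        family = c("binomial", "gaussian")) {
  if (!is.null(x)) {
    stopifnot(inherits(x, "rja_glmm"))
    eta_fixed <- as.vector(
      stats::model.matrix(x$fit) %*% lme4::fixef(x$fit))
    sigma_f2 <- stats::var(eta_fixed) * (length(eta_fixed) - 1) /
      length(eta_fixed)
    vc <- lme4::VarCorr(x$fit)
    sigma_random2 <- sum(vapply(vc, function(m) m[1, 1], numeric(1)))
    sigma_resid2 <- if (x$family == "binomial") pi^2 / 3 else
      stats::sigma(x$fit)^2
  } else {
    family <- match.arg(family)
    if (is.null(sigma_resid2)) {
      sigma_resid2 <- if (family == "binomial") pi^2 / 3 else
        stop("sigma_resid2 required for gaussian components")
    }
  }
  denom <- sigma_f2 + sigma_random2 + sigma_resid2
  list(mR2 = if (denom == 0) 0 else sigma_f2 / denom,
       cR2 = if (denom == 0) 0 else (sigma_f2 + sigma_random2) / denom)
}

# design row for a cell (factor combination) on the fixed-effect scale;
# factor levels are taken from the fit data so contrasts match the fit
cell_design <- function(x, cells) {
  for (v in intersect(all.vars(x$fixed), names(cells))) {
    col <- x$data[[v]]
    if (is.character(col) || is.factor(col)) {
      lv <- levels(factor(col))
      cells[[v]] <- factor(cells[[v]], levels = lv)
      if (anyNA(cells[[v]])) stop("unknown factor level in cells for ", v)
    }
  }
  X <- stats::model.matrix(x$fixed, data = cells)
  X[, names(lme4::fixef(x$fit)), drop = FALSE]
}

#' Marginal means and pairwise contrasts with cluster-bootstrap intervals
#'
#' Cell means are the inverse-link of fixed-effect predictions with random
#' effects at zero (conditional-mode convention). Pairwise contrasts
#' between the supplied cells are odds ratios for binomial fits and mean
#' differences (delta-beta) for Gaussian fits, with Wald z/p from the
#' fixed-effect covariance and percentile 95% confidence intervals over
#' `boot_k` nonparametric cluster-bootstrap refits that resample
#' participants with replacement.
#'
#' @param x A converged `rja_glmm`.
#' @param cells Tibble of factor combinations (e.g. columns `group`,
#'   `timepoint`), one row per cell; every cell must be observed in the
#'   data.
#' @param boot_k Number of bootstrap refits (0 skips the bootstrap and
#'   returns Wald intervals).
#' @param seed Integer seed for the bootstrap resampling.
#' @param conf Confidence level.
#' @return A list of class `rja_contrasts`: `cells` (marginal means) and
#'   `contrasts` (estimate, CI, z, p per cell pair).
#' @export
marginal_contrasts <- function(x, cells, boot_k = 1000, seed = 1,
                               conf = 0.95) {
  stopifnot(inherits(x, "rja_glmm"))
  if (!x$converged) stop("model did not converge; contrasts refused")
  cells <- tibble::as_tibble(cells)
  # every cell must have data
  key_data <- do.call(paste, c(x$data[names(cells)], sep = "/"))
  key_cells <- do.call(paste, c(cells, sep = "/"))
  absent <- setdiff(key_cells, unique(key_data))
  if (length(absent)) stop("cell(s) with no data: ",
                           paste(absent, collapse = ", "))
  X <- cell_design(x, cells)
  beta <- lme4::fixef(x$fit)
  V <- as.matrix(stats::vcov(x$fit))
  eta <- as.vector(X %*% beta)
  invlink <- if (x$family == "binomial") stats::plogis else identity
  cell_out <- dplyr::bind_cols(
    cells,
    tibble::tibble(eta = eta, mean = invlink(eta))
  )
  pairs <- utils::combn(nrow(cells), 2)
  est_fun <- function(e) if (x$family == "binomial") exp(e) else e
  contrast_rows <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    cvec <- X[i1, ] - X[i2, ]
    diff <- sum(cvec * beta)
    se <- sqrt(as.numeric(t(cvec) %*% V %*% cvec))
    z <- diff / se
    tibble::tibble(
      label = paste(key_cells[i1], "vs", key_cells[i2]),
      estimate = est_fun(diff),
      z = z,
      p = 2 * stats::pnorm(-abs(z))
    )
  })
  if (boot_k > 0) {
    boots <- with_local_seed(seed, {
      part <- x$data[[x$random[1]]]
      ids <- unique(part)
      replicate(boot_k, {
        take <- sample(ids, length(ids), replace = TRUE)
        pieces <- lapply(seq_along(take), function(b) {
          d <- x$data[part == take[b], , drop = FALSE]
          d[[x$random[1]]] <- paste0("b", b)
          d
        })
        bd <- do.call(rbind, pieces)
        bfit <- tryCatch(
          suppressMessages(suppressWarnings(
            fit_rja_glmm(bd, x$outcome, x$fixed, x$family, x$random))),
          error = function(e) NULL)
        if (is.null(bfit)) return(rep(NA_real_, ncol(pairs)))
        bX <- cell_design(bfit, cells)
        beta_b <- lme4::fixef(bfit$fit)
        vapply(seq_len(ncol(pairs)), function(j) {
          sum((bX[pairs[1, j], ] - bX[pairs[2, j], ]) * beta_b)
        }, numeric(1))
      })
    })
    boots <- matrix(boots, nrow = ncol(pairs))
    qs <- apply(boots, 1, stats::quantile,
                probs = c((1 - conf) / 2, 1 - (1 - conf) / 2),
                na.rm = TRUE)
    contrast_rows$conf.low <- est_fun(qs[1, ])
    contrast_rows$conf.high <- est_fun(qs[2, ])
    contrast_rows$boot_k <- boot_k
  } else {
    zq <- stats::qnorm(1 - (1 - conf) / 2)
    lo <- purrr::map_dbl(seq_len(ncol(pairs)), function(j) {
      cvec <- X[pairs[1, j], ] - X[pairs[2, j], ]
      sum(cvec * beta) - zq * sqrt(as.numeric(t(cvec) %*% V %*% cvec))
    })
    hi <- purrr::map_dbl(seq_len(ncol(pairs)), function(j) {
      cvec <- X[pairs[1, j], ] - X[pairs[2, j], ]
      sum(cvec * beta) + zq * sqrt(as.numeric(t(cvec) %*% V %*% cvec))
    })
    contrast_rows$conf.low <- est_fun(lo)
    contrast_rows$conf.high <- est_fun(hi)
    contrast_rows$boot_k <- 0L
  }
  structure(list(cells = cell_out, contrasts = contrast_rows,
                 family = x$family),
            class = "rja_contrasts")
}

#' @export
print.rja_contrasts <- function(x, ...) {
  cat("<rja_contrasts> marginal means:\n")
  print(x$cells)
  cat("contrasts (", if (x$family == "binomial") "OR" else "delta-beta",
      "):\n", sep = "")
  print(x$contrasts)
  invisible(x)
}

#' @export
tidy.rja_contrasts <- function(x, ...) x$contrasts

#' Screen task-condition factors for effects on the outcome
#'
#' Adds each condition factor (cueing, stimulus, target side) in turn to a
#' base mixed model and reports the likelihood-ratio test. Factors with a
#' single observed level are skipped with a message.
#'
#' @param features Per-trial feature tibble.
#' @param outcome Outcome column (default `"rja"`).
#' @param base Base fixed-effect formula (default intercept-only `~ 1`).
#' @param factors Condition factors to screen.
#' @param family Model family.
#' @return A tibble with `factor`, `statistic` (LR chi-squared), `df`,
#'   `p.value` (NA rows for skipped factors).
#' @export
condition_screen <- function(features, outcome = "rja", base = ~ 1,
                             factors = c("cueing", "stimulus",
                                         "target_side"),
                             family = "binomial") {
  purrr::map_dfr(factors, function(f) {
    if (!f %in% names(features) ||
        length(unique(features[[f]])) < 2) {
      message("skipping single-level factor: ", f)
      return(tibble::tibble(factor = f, statistic = NA_real_,
                            df = NA_integer_, p.value = NA_real_))
    }
    base_fit <- fit_rja_glmm(features, outcome, base, family)
    aug <- stats::update(base, stats::as.formula(paste("~ . +", f)))
    aug_fit <- fit_rja_glmm(features, outcome, aug, family)
    lrt <- stats::anova(base_fit$fit, aug_fit$fit)
    tibble::tibble(
      factor = f,
      statistic = lrt$Chisq[2],
      df = as.integer(lrt$Df[2]),
      p.value = lrt$`Pr(>Chisq)`[2]
    )
  })
}
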