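#' Linear heating model with per-predictor partial R-squared
#'
#' Fits the additive ordinary-least-squares model
#' `response ~ absorptivity + size + side` (no interactions) and reports,
#' for each term, the extra-sum-of-squares partial R-squared: the increase
#' in residual sum of squares when the term is removed from the full model,
#' as a percentage of the total sum of squares. The platform side enters as
#' a two-level fixed effect (reference level `"left"`) so the absorptivity
#' and size estimates already account for it. Residual normality is
#' summarised (Shapiro-Wilk) because the model assumes Gaussian residuals
#' with mean zero and constant variance.
#'
#' Partial R-squared values of different terms add up to the overall
#' R-squared only when the predictors are orthogonal; in observational
#' data the sum falls short of (never exceeds) the overall value.
#'
#' @param data data.frame with columns `response` (heating metric),
#'   `absorptivity` (percent), `size` (cm) and `side` (factor or character
#'   with levels left/right).
#' @param response_name label for the response (e.g. `"delta_t5"`).
#' @param band_name label for the spectral band (e.g. `"TOTAL"`).
#' @return A list of class `elytherm_heating_model`: `response`, `band`,
#'   `coefficients` (data.frame term/estimate/std_error/p_value),
#'   `overall_R2` and `partial_R2` in percent, `n`,
#'   `residual_diagnostics` (list with `shapiro_p`, `residual_mean`), and
#'   the underlying `fit`.
#' @export
fit_heating_model <- function(data, response_name = "delta_t5",
                              band_name = "TOTAL") {
  need <- c("response", "absorptivity", "size", "side")
  if (!all(need %in% names(data))) {
    stop("data must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  data <- data[, need]
  if (anyNA(data)) stop("missing values in model columns", call. = FALSE)
  if (nrow(data) < 5L) stop("need at least 5 rows", call. = FALSE)
  data$side <- stats::relevel(factor(data$side), ref = "left")
  full <- stats::lm(response ~ absorptivity + size + side, data = data)
  if (any(is.na(stats::coef(full)))) {
    bad <- names(stats::coef(full))[is.na(stats::coef(full))]
    stop("rank-deficient design; collinear term(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  ss_total <- sum((data$response - mean(data$response))^2)
  ss_full <- sum(stats::residuals(full)^2)
  terms <- c("absorptivity", "size", "side")
  partial <- vapply(terms, function(tm) {
    reduced <- stats::update(full, stats::as.formula(paste(". ~ . -", tm)))
    100 * (sum(stats::residuals(reduced)^2) - ss_full) / ss_total
  }, numeric(1))
  sm <- summary(full)$coefficients
  coefs <- data.frame(term = rownames(sm), estimate = sm[, 1],
                      std_error = sm[, 2], p_value = sm[, 4],
                      row.names = NULL, stringsAsFactors = FALSE)
  res <- stats::residuals(full)
  shapiro_p <- if (length(res) >= 3 && length(res) <= 5000 &&
                   stats::sd(res) > 0) {
    stats::shapiro.test(res)$p.value
  } else NA_real_
  structure(list(
    response = response_name, band = band_name, coefficients = coefs,
    overall_R2 = 100 * summary(full)$r.squared,
    partial_R2 = partial, n = nrow(data),
    residual_diagnostics = list(shapiro_p = shapiro_p,
                                residual_mean = mean(res)),
    fit = full), class = "elytherm_heating_model")
}

#' @export
print.elytherm_heating_model <- function(x, ...) {
  cat(sprintf("Heating model: %s ~ absorptivity + size + side [%s band]\n",
              x$response, x$band))
  cat(sprintf("  n = %d, overall R2 = %.2f%%\n", x$n, x$overall_R2))
  df <- x$coefficients
  df$partial_R2 <- NA_real_
  for (tm in names(x$partial_R2)) {
    df$partial_R2[grepl(paste0("^", tm), df$term)] <- x$partial_R2[[tm]]
  }
  print(df, digits = 4)
  invisible(x)
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' Product-moment correlation with a 95% confidence interval from the
#' Fisher z-transform and a two-sided p-value from
#' `t = r sqrt((n - 2) / (1 - r^2))`. With perfectly collinear input the
#' interval is degenerate at r and flagged.
#'
#' @param x,y numeric vectors of equal length, n >= 4, finite values.
#' @param conf_level confidence level (default 0.95).
#' @return A list of class `elytherm_pearson`: `r`, `ci_95` (lo, hi),
#'   `p_value`, `n`, `degenerate` (logical).
#' @export
pearson_with_ci <- function(x, y, conf_level = 0.95) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (length(x) < 4L) stop("need n >= 4", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("non-finite values", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in x or y", call. = FALSE)
  }
  r <- stats::cor(x, y)
  if (abs(r) >= 1 - 1e-15) {
    return(structure(list(r = sign(r), ci_95 = c(sign(r), sign(r)),
                          p_value = 0, n = length(x), degenerate = TRUE),
                     class = "elytherm_pearson"))
  }
  ct <- stats::cor.test(x, y, method = "pearson", conf.level = conf_level)
  structure(list(r = unname(ct$estimate), ci_95 = as.numeric(ct$conf.int),
                 p_value = ct$p.value, n = length(x), degenerate = FALSE),
            class = "elytherm_pearson")
}

#' @export
print.elytherm_pearson <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f, 95%% CI (%.3f, %.3f), p = %.3g, n = %d%s\n",
              x$r, x$ci_95[[1]], x$ci_95[[2]], x$p_value, x$n,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Gaussian repeatability (intraclass correlation) with parametric bootstrap
#'
#' Fits a Gaussian random-intercept model (`value ~ 1 + (1 | group)`) and
#' reports the repeatability `R = sigma2_group / (sigma2_group +
#' sigma2_residual)`: the fraction of variance attributable to consistent
#' differences between groups. The point estimate uses REML, which on
#' balanced data coincides with the ANOVA variance-component estimator.
#' The 95% interval is a percentile parametric bootstrap: `n_boot` data
#' sets are simulated from the fitted model and the model refitted to
#' each. The p-value tests `sigma2_group = 0` by a likelihood-ratio test
#' of maximum-likelihood fits, with the null distribution taken as the
#' boundary mixture `0.5 * chi2_0 + 0.5 * chi2_1` because the null pins the
#' variance at the edge of its parameter space.
#'
#' Groups with a single observation carry no information about
#' within-group variance and are dropped with a warning.
#'
#' @param values numeric vector of measurements.
#' @param group_ids grouping labels (e.g. species), same length.
#' @param n_boot number of parametric-bootstrap resamples (default 1000).
#' @param seed integer seed; required for reproducible intervals.
#' @return A list of class `elytherm_repeatability`: `R_point`, `ci_95`,
#'   `p_lrt`, `n_groups`, `n_obs`, `n_boot`, `seed`, `boot_R` (the
#'   bootstrap draws).
#' @export
gaussian_repeatability <- function(values, group_ids, n_boot = 1000,
                                   seed = 1L) {
  if (length(values) != length(group_ids)) {
    stop("values and group_ids lengths differ", call. = FALSE)
  }
  keep <- is.finite(values) & !is.na(group_ids)
  values <- values[keep]
  group <- factor(group_ids[keep])
  sizes <- table(group)
  if (any(sizes < 2)) {
    if (all(sizes < 2)) stop("all groups have a single observation",
                             call. = FALSE)
    warning(sum(sizes < 2), " singleton group(s) dropped", call. = FALSE)
    ok <- group %in% names(sizes)[sizes >= 2]
    values <- values[ok]
    group <- droplevels(group[ok])
  }
  if (nlevels(group) < 2L) stop("need at least 2 groups", call. = FALSE)
  df <- data.frame(value = values, group = group)

  fit_R <- function(fit) {
    vc <- as.data.frame(lme4::VarCorr(fit))
    v_g <- vc$vcov[vc$grp == "group"]
    v_e <- vc$vcov[vc$grp == "Residual"]
    v_g / (v_g + v_e)
  }
  # tight optimizer tolerances: on balanced data the REML optimum has a
  # closed form and the fit should agree with it to ~1e-8
  ctrl <- lme4::lmerControl(
    check.conv.singular = "ignore",
    optCtrl = list(xtol_abs = 1e-12, ftol_abs = 1e-14))
  reml_fit <- suppressMessages(lme4::lmer(value ~ 1 + (1 | group), data = df,
                                          REML = TRUE, control = ctrl))
  R_point <- fit_R(reml_fit)

  # LRT of sigma2_group = 0 from ML fits, boundary-corrected null
  ml_fit <- suppressMessages(lme4::lmer(value ~ 1 + (1 | group), data = df,
                                        REML = FALSE, control = ctrl))
  null_fit <- stats::lm(value ~ 1, data = df)
  lr <- max(0, 2 * (as.numeric(stats::logLik(ml_fit)) -
                    as.numeric(stats::logLik(null_fit))))
  p_lrt <- if (lr <= 0) 1 else 0.5 * stats::pchisq(lr, df = 1,
                                                   lower.tail = FALSE)

  boot_R <- numeric(0)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    set.seed(seed)
    sims <- stats::simulate(reml_fit, nsim = n_boot)
    boot_R <- vapply(seq_len(n_boot), function(b) {
      bf <- suppressMessages(suppressWarnings(
        lme4::refit(reml_fit, newresp = sims[[b]])))
      fit_R(bf)
    }, numeric(1))
    ci <- unname(stats::quantile(boot_R, c(0.025, 0.975)))
  }
  structure(list(R_point = R_point, ci_95 = ci, p_lrt = p_lrt,
                 n_groups = nlevels(group), n_obs = nrow(df),
                 n_boot = n_boot, seed = seed, boot_R = boot_R),
            class = "elytherm_repeatability")
}

#' @export
print.elytherm_repeatability <- function(x, ...) {
  cat(sprintf(
    "Repeatability R = %.3f, 95%% CI (%.3f, %.3f), LRT p = %.3g\n",
    x$R_point, x$ci_95[[1]], x$ci_95[[2]], x$p_lrt))
  cat(sprintf("  %d groups, %d observations, %d bootstrap draws (seed %d)\n",
              x$n_groups, x$n_obs, x$n_boot, x$seed))
  invisible(x)
}

#' Paired bootstrap test for the elytra insulation difference
#'
#' For each individual measured with elytra closed and open, forms the
#' difference `D_i = closed_i - open_i` in the 5-min temperature change of
#' the body, so that negative values mean the body heats more when the
#' elytra are NOT covering it. The individuals are resampled with
#' replacement `n_boot` times and the 2.5/97.5 percentile interval of the
#' resampled mean difference is reported; an interval excluding zero on
#' the negative side indicates an insulating effect of the elytra.
#'
#' @param open_dt5 per-individual 5-min temperature change, elytra open.
#' @param closed_dt5 same individuals, elytra closed (paired order).
#' @param n_boot bootstrap resamples (default 10000).
#' @param seed integer seed.
#' @param band optional band label carried into the result.
#' @return A list of class `elytherm_paired_boot`: `mean_D`, `ci_95`,
#'   `n_individuals`, `n_boot`, `seed`, `band`, `boot_means`.
#' @export
paired_bootstrap_dt <- function(open_dt5, closed_dt5, n_boot = 10000,
                                seed = 1L, band = "TOTAL") {
  if (length(open_dt5) != length(closed_dt5)) {
    stop("open and closed vectors must be paired (equal length)",
         call. = FALSE)
  }
  n <- length(open_dt5)
  if (n < 3L) stop("need at least 3 paired individuals", call. = FALSE)
  D <- closed_dt5 - open_dt5
  set.seed(seed)
  idx <- sample.int(n, n * n_boot, replace = TRUE)
  boot_means <- colMeans(matrix(D[idx], nrow = n, ncol = n_boot))
  ci <- unname(stats::quantile(boot_means, c(0.025, 0.975)))
  structure(list(mean_D = mean(D), ci_95 = ci, n_individuals = n,
                 n_boot = n_boot, seed = seed, band = band,
                 boot_means = boot_means),
            class = "elytherm_paired_boot")
}

#' @export
print.elytherm_paired_boot <- function(x, ...) {
  concl <- if (x$ci_95[[2]] < 0) {
    "body heats MORE without elytra (interval < 0)"
  } else if (x$ci_95[[1]] > 0) {
    "body heats LESS without elytra (interval > 0)"
  } else "no clear effect (interval spans 0)"
  cat(sprintf(
    "Paired D_dT [%s]: mean %.3f degC, 95%% CI (%.3f, %.3f), n = %d\n  %s\n",
    x$band, x$mean_D, x$ci_95[[1]], x$ci_95[[2]], x$n_individuals, concl))
  invisible(x)
}
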