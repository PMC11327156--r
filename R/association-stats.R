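#' Fixed-effects OLS with day-clustered standard errors
#'
#' Regresses the daily outcome on one neurophysiologic predictor plus the
#' sick and male controls and a full set of day indicator variables (one per
#' calendar day, first dropped). Because the event statistic is built from
#' within-person deviations, day fixed effects absorb shared day-level
#' shocks; standard errors allow arbitrary within-day error correlation via
#' the cluster-robust sandwich with the CR1 small-sample factor
#' `G/(G-1) * (N-1)/(N-K)`. Confidence intervals use the normal
#' approximation (`coefficient +/- 1.96 SE`), and p-values are two-sided
#' normal. Rows with a missing predictor or outcome are dropped listwise, so
#' each model reports its own n.
#'
#' @param table The analysis table from [build_daily_features()].
#' @param outcome `"mood"` or `"energy"` (or any numeric column).
#' @param predictor Name of the neurophysiologic predictor column.
#' @param controls Control columns (default sick and male).
#' @return An object of class `fe_ols_result`: predictor coefficient, its
#'   clustered SE, 95% CI and p-value, the control coefficients with
#'   clustered SEs, n, R-squared, adjusted R-squared, the number of day
#'   clusters, and the underlying `lm` fit.
#' @export
fit_fe_ols <- function(table, outcome = c("mood", "energy"), predictor,
                       controls = c("sick", "male")) {
  outcome <- if (is.character(outcome)) match.arg(outcome) else outcome
  stopifnot(predictor %in% names(table))
  cols <- c(outcome, predictor, controls, "day_index")
  dat <- as.data.frame(table)[, cols]
  dat <- dat[complete.cases(dat), ]
  if (nrow(dat) == 0) stop("fit_fe_ols: no complete rows")
  if (length(unique(dat$day_index)) < 2)
    stop("fit_fe_ols: need at least 2 days for day fixed effects")
  if (sd(dat[[predictor]]) == 0)
    stop("fit_fe_ols: predictor '", predictor, "' is constant")
  for (cc in controls) dat[[cc]] <- as.numeric(dat[[cc]])
  constant <- controls[vapply(controls, function(cc) sd(dat[[cc]]) == 0, logical(1))]
  controls <- setdiff(controls, constant)
  dat$.day <- droplevels(factor(dat$day_index))

  fml <- stats::as.formula(paste(outcome, "~",
                                 paste(c(predictor, controls, ".day"), collapse = " + ")))
  fit <- lm(fml, data = dat)
  if (any(is.na(coef(fit)))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop("fit_fe_ols: singular design; aliased terms: ",
         paste(bad, collapse = ", "))
  }

  vc <- cluster_vcov(fit, dat$.day)
  se <- sqrt(diag(vc))
  b <- coef(fit)
  smry <- summary(fit)

  ctrl <- lapply(controls, function(cc)
    list(coef = unname(b[cc]), se = unname(se[cc]),
         p = 2 * pnorm(-abs(b[cc] / se[cc]))))
  names(ctrl) <- controls

  structure(list(
    outcome = outcome, predictor = predictor,
    coef = unname(b[predictor]), se = unname(se[predictor]),
    ci = unname(b[predictor] + c(-1, 1) * 1.96 * se[predictor]),
    p = unname(2 * pnorm(-abs(b[predictor] / se[predictor]))),
    controls = ctrl, dropped_controls = constant,
    n = nrow(dat), n_days = length(levels(dat$.day)),
    r_squared = smry$r.squared, adj_r_squared = smry$adj.r.squared,
    fit = fit, vcov = vc), class = "fe_ols_result")
}

# CR1 cluster-robust covariance: (X'X)^-1 (sum_g X_g' u_g u_g' X_g) (X'X)^-1
# scaled by G/(G-1) * (N-1)/(N-K). The meat comes from the sandwich package;
# the small-sample factor is applied explicitly so the estimator is exactly
# the conventional CR1.
cluster_vcov <- function(fit, cluster) {
  n <- length(residuals(fit))
  k <- length(coef(fit))
  g <- length(unique(cluster))
  raw <- sandwich::vcovCL(fit, cluster = cluster, type = "HC0", cadjust = FALSE)
  raw * g / (g - 1) * (n - 1) / (n - k)
}

#' @export
print.fe_ols_result <- function(x, ...) {
  star <- function(p) if (p < .001) "***" else if (p < .01) "**" else if (p < .05) "*" else ""
  cat(sprintf("<fe_ols_result> %s ~ %s + sick + male + day FE (n = %d, %d day clusters)\n",
              x$outcome, x$predictor, x$n, x$n_days))
  cat(sprintf("  %-22s % .4f (%.4f)%s  CI [% .4f, % .4f], p = %.4g\n",
              x$predictor, x$coef, x$se, star(x$p), x$ci[1], x$ci[2], x$p))
  for (nm in names(x$controls)) {
    cc <- x$controls[[nm]]
    cat(sprintf("  %-22s % .4f (%.4f)%s\n", nm, cc$coef, cc$se, star(cc$p)))
  }
  cat(sprintf("  R2 = %.3f, adj. R2 = %.3f\n", x$r_squared, x$adj_r_squared))
  invisible(x)
}

#' Association table across the six neurophysiologic predictors
#'
#' Fits [fit_fe_ols()] once per predictor (each evaluated separately to
#' avoid multicollinearity, all controlling for sick and sex) and collects
#' the results into one tibble, mirroring the conventional regression-table
#' layout.
#'
#' @param table Analysis table from [build_daily_features()].
#' @param outcome `"mood"` or `"energy"`.
#' @param predictors Predictor columns (default: the six event summaries).
#' @return A tibble with coefficient, clustered SE, CI, p, n, and fit
#'   statistics per predictor.
#' @export
association_table <- function(table, outcome = c("mood", "energy"),
                              predictors = c("n_troughs", "n_peaks",
                                             "avg_trough_time_min",
                                             "avg_peak_time_min",
                                             "avg_trough_depth",
                                             "avg_peak_height")) {
  outcome <- match.arg(outcome)
  dplyr::bind_rows(lapply(predictors, function(p) {
    f <- fit_fe_ols(table, outcome, p)
    tibble::tibble(outcome = outcome, predictor = p, coef = f$coef, se = f$se,
                   ci_lo = f$ci[1], ci_hi = f$ci[2], p = f$p,
                   coef_sick = f$controls$sick$coef %||% NA_real_,
                   se_sick = f$controls$sick$se %||% NA_real_,
                   coef_male = f$controls$male$coef %||% NA_real_,
                   se_male = f$controls$male$se %||% NA_real_,
                   n = f$n, r_squared = f$r_squared,
                   adj_r_squared = f$adj_r_squared)
  }))
}

#' Pearson correlation with two-sided p-value
#'
#' @param x,y Numeric vectors (pairwise complete observations are used).
#' @return A list with `r`, `p` and `n`.
#' @export
correlate <- function(x, y) {
  ok <- complete.cases(x, y)
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0)
    stop("correlate: constant input")
  ct <- cor.test(x[ok], y[ok], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Welch two-sample t-test with Cohen's d
#'
#' Welch-Satterthwaite degrees of freedom; Cohen's d uses the pooled SD.
#'
#' @param a,b Numeric vectors (>= 2 observations each).
#' @return A `group_comparison` tibble row: statistic, df, p, effect size.
#' @export
welch_t <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2 || (sd(a) == 0 && sd(b) == 0))
    stop("welch_t: degenerate groups")
  tt <- t.test(a, b, var.equal = FALSE)
  sp <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
               (length(a) + length(b) - 2))
  comparison_row("welch_t", unname(tt$statistic), unname(tt$parameter), NA,
                 tt$p.value, (mean(a) - mean(b)) / sp, "cohen_d")
}

#' Variance-ratio F test
#'
#' @param a,b Numeric vectors (>= 2 observations each).
#' @return A `group_comparison` tibble row; the effect column holds the
#'   variance ratio `var(a)/var(b)`.
#' @export
var_ratio_f <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2 || sd(b) == 0)
    stop("var_ratio_f: degenerate groups")
  vt <- var.test(a, b)
  comparison_row("var_F", unname(vt$statistic), unname(vt$parameter[1]),
                 unname(vt$parameter[2]), vt$p.value,
                 unname(vt$estimate), "var_ratio")
}

#' One-way ANOVA with eta-squared
#'
#' `eta2 = SS_between / SS_total` from the standard one-way decomposition.
#'
#' @param values Numeric outcome vector.
#' @param groups Grouping vector (coerced to factor; >= 2 non-degenerate
#'   groups).
#' @return A `group_comparison` tibble row.
#' @export
oneway_anova_eta2 <- function(values, groups) {
  ok <- complete.cases(values, groups)
  values <- values[ok]; groups <- factor(groups[ok])
  if (nlevels(groups) < 2 || any(table(groups) < 2))
    stop("oneway_anova_eta2: need >= 2 groups with >= 2 observations each")
  fit <- aov(values ~ groups)
  tab <- summary(fit)[[1]]
  ss_b <- tab["groups", "Sum Sq"]
  ss_t <- sum(tab[, "Sum Sq"])
  comparison_row("anova_F", tab["groups", "F value"], tab["groups", "Df"],
                 tab["Residuals", "Df"], tab["groups", "Pr(>F)"],
                 ss_b / ss_t, "eta2")
}

comparison_row <- function(kind, statistic, df1, df2, p, effect, effect_kind) {
  structure(tibble::tibble(kind = kind, statistic = statistic, df1 = df1,
                           df2 = df2, p = p, effect = effect,
                           effect_kind = effect_kind),
            class = c("group_comparison", class(tibble::tibble())))
}
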