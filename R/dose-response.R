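#' Fit a linear effect versus log10(dose) curve
#'
#' Ordinary least squares of percent antinociception on log10(dose), the
#' classical working model for effective-dose estimation over a log-spaced
#' dose range. Accepts either a group-mean `dose_effect` table (one row per
#' dose) or a per-animal data frame with columns `dose` and `effect_pct`
#' (several rows per dose); both run through the same unweighted OLS, so the
#' per-animal mode implicitly weights doses by their animal counts.
#'
#' @param rows A `dose_effect` data frame from [read_dose_effect_table()],
#'   or any data frame with columns `dose` (> 0) and `effect_pct`.
#' @param label Optional label describing the fitted arm.
#'
#' @return An object of class `dr_fit`: `intercept` (% at log10(dose) = 0),
#'   `slope` (% per log10 unit), `cov` (2x2 covariance of (intercept,
#'   slope)), `residual_df`, `r2`, `n_points`, the fitted dose range, and
#'   the underlying `lm` fit.
#' @export
#' @examples
#' tabs <- popex_asa_tables()
#' fit <- fit_dose_response(tabs$drug_a, label = "ASA")
#' fit$slope
fit_dose_response <- function(rows, label = "") {
  if (!is.data.frame(rows) || !all(c("dose", "effect_pct") %in% names(rows)))
    stop("rows must be a data frame with columns dose and effect_pct",
         call. = FALSE)
  if (any(!is.finite(rows$dose)) || any(rows$dose <= 0))
    stop("all doses must be finite and > 0", call. = FALSE)
  if (length(unique(rows$dose)) < 3L)
    stop("need at least 3 distinct doses to fit a line", call. = FALSE)
  d <- data.frame(x = log10(rows$dose), y = rows$effect_pct)
  fit <- stats::lm(y ~ x, data = d)
  # summary.lm warns on an exactly collinear (perfect) fit; zero residual
  # variance is a legitimate input here (closed-form test cases)
  sm <- suppressWarnings(summary(fit))
  structure(
    list(intercept = unname(stats::coef(fit)[1L]),
         slope = unname(stats::coef(fit)[2L]),
         cov = unname(sm$sigma^2 * sm$cov.unscaled),
         residual_df = fit$df.residual,
         r2 = sm$r.squared,
         n_points = nrow(d),
         dose_range = range(rows$dose),
         label = label,
         lm = fit),
    class = "dr_fit")
}

#' @export
print.dr_fit <- function(x, ...) {
  cat(sprintf("<dr_fit>%s effect%% = %.3f + %.3f * log10(dose), R2 = %.3f, %d points, %d residual df\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              x$intercept, x$slope, x$r2, x$n_points, x$residual_df))
  invisible(x)
}

#' Predicted effect and its standard error at given log10 doses
#'
#' @param fit A `dr_fit`.
#' @param log10_dose Numeric vector of log10(mg/kg) values.
#' @return Data frame with `log10_dose`, `effect`, `se`.
#' @export
predict_effect <- function(fit, log10_dose) {
  stopifnot(inherits(fit, "dr_fit"))
  X <- cbind(1, log10_dose)
  eff <- as.numeric(X %*% c(fit$intercept, fit$slope))
  se <- sqrt(rowSums((X %*% fit$cov) * X))
  data.frame(log10_dose = log10_dose, effect = eff, se = se)
}

#' Effective dose by inverse prediction with delta-method uncertainty
#'
#' Inverts the fitted line at a target effect level: `log10(ED) = (level -
#' intercept) / slope`, `ED = 10^log10(ED)`. The variance of log10(ED)
#' follows from the delta method through the inverse prediction (gradient
#' `(-1/slope, -log10(ED)/slope)` applied to the coefficient covariance);
#' the dose-scale SE adds the antilog Jacobian `ED * ln(10)`. The confidence
#' interval is a t-interval on the log10 scale, antilogged (asymmetric on
#' the dose scale). A warning is raised when the ED falls outside the fitted
#' dose range (extrapolation).
#'
#' @param fit A `dr_fit` with positive slope.
#' @param level Target percent effect, in (0, 100). Default 30.
#' @param alpha Level of the (1 - alpha) confidence interval. Default 0.05.
#'
#' @return An object of class `ed_estimate`: `level`, `dose` (mg/kg), `se`
#'   (mg/kg), `ci_low`, `ci_high`, `df`, `log10_dose`, `se_log10`,
#'   `source_label`, `extrapolated`.
#' @export
#' @examples
#' tabs <- popex_asa_tables()
#' ed_x(fit_dose_response(tabs$drug_a), level = 30)
ed_x <- function(fit, level = 30, alpha = 0.05) {
  stopifnot(inherits(fit, "dr_fit"))
  if (!(level > 0 && level < 100))
    stop("level must be in (0, 100)", call. = FALSE)
  if (!is.finite(fit$slope) || fit$slope <= 0)
    stop("slope must be positive: no positive dose reaches the level in-model",
         call. = FALSE)
  z <- (level - fit$intercept) / fit$slope
  ed <- 10^z
  grad <- c(-1 / fit$slope, -z / fit$slope)
  var_z <- as.numeric(t(grad) %*% fit$cov %*% grad)
  se_z <- sqrt(max(var_z, 0))
  se_dose <- ed * log(10) * se_z
  tq <- stats::qt(1 - alpha / 2, fit$residual_df)
  ci <- 10^(z + c(-1, 1) * tq * se_z)
  extrap <- ed < fit$dose_range[1L] || ed > fit$dose_range[2L]
  if (extrap)
    warning(sprintf("ED%g = %.4g mg/kg lies outside the fitted dose range [%.4g, %.4g] (extrapolation)",
                    level, ed, fit$dose_range[1L], fit$dose_range[2L]),
            call. = FALSE)
  structure(
    list(level = level, dose = ed, se = se_dose,
         ci_low = ci[1L], ci_high = ci[2L],
         df = fit$residual_df,
         log10_dose = z, se_log10 = se_z,
         source_label = fit$label, extrapolated = extrap),
    class = "ed_estimate")
}

#' Construct an effective-dose estimate directly
#'
#' For working with published point estimates (dose and SE) that did not
#' come from a fit in this session, e.g. reproducing a printed worked
#' example.
#'
#' @param dose Effective dose in mg/kg (> 0).
#' @param se Standard error in mg/kg (>= 0).
#' @param level Effect level in percent. Default 30.
#' @param df Degrees of freedom for t-based inference. Default `Inf`.
#' @param alpha CI level. Default 0.05.
#' @param source_label Label.
#' @return An `ed_estimate`.
#' @export
ed_estimate <- function(dose, se, level = 30, df = Inf, alpha = 0.05,
                        source_label = "") {
  if (!is.finite(dose) || dose <= 0) stop("dose must be > 0", call. = FALSE)
  if (!is.finite(se) && !is.infinite(df)) stop("se must be finite", call. = FALSE)
  if (se < 0) stop("se must be >= 0", call. = FALSE)
  tq <- stats::qt(1 - alpha / 2, df)
  structure(
    list(level = level, dose = dose, se = se,
         ci_low = max(dose - tq * se, 0), ci_high = dose + tq * se,
         df = df, log10_dose = log10(dose),
         se_log10 = se / (dose * log(10)),
         source_label = source_label, extrapolated = FALSE),
    class = "ed_estimate")
}

#' @export
print.ed_estimate <- function(x, ...) {
  cat(sprintf("<ed_estimate>%s ED%g = %.4g mg/kg (SE %.4g, %g%% CI [%.4g, %.4g], df %g)%s\n",
              if (nzchar(x$source_label)) paste0(" [", x$source_label, "]") else "",
              x$level, x$dose, x$se, 95, x$ci_low, x$ci_high, x$df,
              if (isTRUE(x$extrapolated)) " [extrapolated]" else ""))
  invisible(x)
}

#' Compare two fitted dose-response curves at shared doses
#'
#' Evaluates both fitted lines at a set of shared log10 doses inside the
#' overlap of their fitted ranges, tests the per-dose difference in
#' predicted effect with a two-sided t-test (SE combining both fits'
#' prediction variances, df summed), and Bonferroni-adjusts over the doses
#' compared.
#'
#' @param fit_a,fit_b `dr_fit` objects with overlapping dose ranges.
#' @param log10_doses Optional log10 doses to compare at; default is a
#'   5-point grid spanning the overlap.
#' @param alpha Test level. Default 0.05.
#'
#' @return A list with a `comparisons` data frame (log10_dose, effects,
#'   difference, SE, t, raw and adjusted p, significance) and a `verdict`
#'   string summarizing which curve predicts higher effects where.
#' @export
compare_curves <- function(fit_a, fit_b, log10_doses = NULL, alpha = 0.05) {
  stopifnot(inherits(fit_a, "dr_fit"), inherits(fit_b, "dr_fit"))
  lo <- max(log10(fit_a$dose_range[1L]), log10(fit_b$dose_range[1L]))
  hi <- min(log10(fit_a$dose_range[2L]), log10(fit_b$dose_range[2L]))
  if (lo > hi) stop("dose ranges do not overlap", call. = FALSE)
  if (is.null(log10_doses)) log10_doses <- seq(lo, hi, length.out = 5L)
  pa <- predict_effect(fit_a, log10_doses)
  pb <- predict_effect(fit_b, log10_doses)
  diff <- pa$effect - pb$effect
  se <- sqrt(pa$se^2 + pb$se^2)
  df <- fit_a$residual_df + fit_b$residual_df
  tv <- ifelse(se > 0, diff / se, ifelse(diff == 0, 0, sign(diff) * Inf))
  p_raw <- 2 * stats::pt(-abs(tv), df)
  m <- length(log10_doses)
  p_adj <- pmin(1, m * p_raw)
  comp <- data.frame(log10_dose = log10_doses,
                     effect_a = pa$effect, effect_b = pb$effect,
                     difference = diff, se = se, t_stat = tv,
                     p_raw = p_raw, p_adj = p_adj,
                     significant = p_adj < alpha)
  n_sig_a <- sum(comp$significant & comp$difference > 0)
  n_sig_b <- sum(comp$significant & comp$difference < 0)
  verdict <- if (n_sig_a > 0 && n_sig_b == 0)
    "curve A predicts significantly higher effects at the significant doses"
  else if (n_sig_b > 0 && n_sig_a == 0)
    "curve B predicts significantly higher effects at the significant doses"
  else if (n_sig_a == 0 && n_sig_b == 0)
    "no significant differences at the compared doses"
  else "mixed: each curve is significantly higher at some doses"
  list(comparisons = comp, verdict = verdict, df = df)
}
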