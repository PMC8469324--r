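#' Fixed-ratio combination design
#'
#' Builds the halving dilution series of a fixed-ratio combination arm. The
#' top level contains `f * ED_A` of drug A and `(1 - f) * ED_B` of drug B,
#' so the top total equals the theoretical additive effective dose; each
#' subsequent level halves both components. Totals are carried at full
#' precision; rounding is display-only.
#'
#' @param ed_a,ed_b [ed_x()] estimates for drug A and drug B at the same
#'   effect level.
#' @param f Fraction of drug A's ED in the combination, in (0, 1).
#'   Default 0.5.
#' @param n_levels Number of halving levels (>= 2). Default 6.
#'
#' @return An object of class `fixed_ratio_design` with `f`, `ed_a`,
#'   `ed_b`, and a `levels` data frame (level, dose_a, dose_b, total).
#' @export
#' @examples
#' da <- ed_estimate(8, 1);  db <- ed_estimate(60, 8)
#' build_fixed_ratio_design(da, db)$levels$total  # 34, 17, 8.5, ...
build_fixed_ratio_design <- function(ed_a, ed_b, f = 0.5, n_levels = 6L) {
  stopifnot(inherits(ed_a, "ed_estimate"), inherits(ed_b, "ed_estimate"))
  if (ed_a$dose <= 0 || ed_b$dose <= 0)
    stop("component EDs must be positive", call. = FALSE)
  if (!(f > 0 && f < 1)) stop("f must be in (0, 1)", call. = FALSE)
  if (n_levels < 2L) stop("need at least 2 levels", call. = FALSE)
  top_a <- f * ed_a$dose
  top_b <- (1 - f) * ed_b$dose
  halving <- 2^(-(seq_len(n_levels) - 1L))
  lv <- data.frame(level = seq_len(n_levels),
                   dose_a = top_a * halving,
                   dose_b = top_b * halving)
  lv$total <- lv$dose_a + lv$dose_b
  structure(list(f = f, ed_a = ed_a, ed_b = ed_b, levels = lv),
            class = "fixed_ratio_design")
}

#' @export
print.fixed_ratio_design <- function(x, ...) {
  cat(sprintf("<fixed_ratio_design> f = %g, component EDs %.4g / %.4g mg/kg\n",
              x$f, x$ed_a$dose, x$ed_b$dose))
  print(transform(x$levels, dose_a = round(dose_a, 2),
                  dose_b = round(dose_b, 2), total = round(total, 2)),
        row.names = FALSE)
  invisible(x)
}

#' Theoretical additive effective dose (Loewe additivity)
#'
#' The total combination dose predicted under Loewe additivity for a fixed
#' ratio: `Zadd = f * ED_A + (1 - f) * ED_B`, with variance
#' `f^2 Var(ED_A) + (1 - f)^2 Var(ED_B)` and degrees of freedom summed over
#' the two component fits.
#'
#' @param ed_a,ed_b Component `ed_estimate`s at the same effect level.
#' @param f Fraction of drug A, in (0, 1\]. Default 0.5.
#' @param alpha CI level. Default 0.05.
#'
#' @return An `ed_estimate` for the additive total dose.
#' @export
additive_ed <- function(ed_a, ed_b, f = 0.5, alpha = 0.05) {
  stopifnot(inherits(ed_a, "ed_estimate"), inherits(ed_b, "ed_estimate"))
  if (ed_a$level != ed_b$level)
    stop("component EDs must be at the same effect level", call. = FALSE)
  if (!(f > 0 && f <= 1)) stop("f must be in (0, 1]", call. = FALSE)
  z <- f * ed_a$dose + (1 - f) * ed_b$dose
  v <- f^2 * ed_a$se^2 + (1 - f)^2 * ed_b$se^2
  df <- ed_a$df + ed_b$df
  se <- sqrt(v)
  tq <- stats::qt(1 - alpha / 2, df)
  structure(
    list(level = ed_a$level, dose = z, se = se,
         ci_low = max(z - tq * se, 0), ci_high = z + tq * se,
         df = df, log10_dose = log10(z),
         se_log10 = se / (z * log(10)),
         source_label = "theoretical additive", extrapolated = FALSE),
    class = "ed_estimate")
}

#' Student's t-test between theoretical and experimental EDs
#'
#' Two-sided t-test of the difference between the theoretical additive ED
#' and the experimentally estimated combination ED:
#' `t = (ED_T - ED_E) / sqrt(SE_T^2 + SE_E^2)`, with degrees of freedom
#' summed over the two estimates.
#'
#' @param ed_t Theoretical additive `ed_estimate`.
#' @param ed_e Experimental combination `ed_estimate`.
#' @param alpha Test level. Default 0.05.
#'
#' @return A list with `t_stat`, `df`, `p_value`, `significant`.
#' @export
test_additivity <- function(ed_t, ed_e, alpha = 0.05) {
  stopifnot(inherits(ed_t, "ed_estimate"), inherits(ed_e, "ed_estimate"))
  if (!is.finite(ed_t$se) || !is.finite(ed_e$se) || ed_t$se < 0 || ed_e$se < 0)
    stop("both SEs must be finite and >= 0", call. = FALSE)
  se <- sqrt(ed_t$se^2 + ed_e$se^2)
  if (se == 0) stop("both SEs are zero: no test possible", call. = FALSE)
  t_stat <- (ed_t$dose - ed_e$dose) / se
  df <- ed_t$df + ed_e$df
  p <- 2 * stats::pt(-abs(t_stat), df)
  list(t_stat = t_stat, df = df, p_value = p, significant = p < alpha)
}

#' Interaction index of a drug combination
#'
#' The ratio of the experimental to the theoretical additive effective
#' dose, `gamma = ED_E / ED_T`: near 1 additive, below 1 synergistic
#' (potentiation), above 1 antagonistic (infra-additive). The SE follows
#' first-order ratio propagation,
#' `gamma * sqrt((SE_E/ED_E)^2 + (SE_T/ED_T)^2)`.
#'
#' @param ed_e Experimental `ed_estimate`.
#' @param ed_t Theoretical additive `ed_estimate`.
#'
#' @return A list with `gamma` and `gamma_se`.
#' @export
#' @examples
#' interaction_index(ed_estimate(0.927, 0.63), ed_estimate(34, 8.11))
interaction_index <- function(ed_e, ed_t) {
  stopifnot(inherits(ed_e, "ed_estimate"), inherits(ed_t, "ed_estimate"))
  if (ed_t$dose <= 0) stop("theoretical ED must be > 0", call. = FALSE)
  g <- ed_e$dose / ed_t$dose
  g_se <- g * sqrt((ed_e$se / ed_e$dose)^2 + (ed_t$se / ed_t$dose)^2)
  list(gamma = g, gamma_se = g_se)
}

#' Classify a combination interaction
#'
#' Conservative rule combining the interaction index with the
#' additivity test: synergistic when `gamma < 1` AND the t-test rejects,
#' antagonistic when `gamma > 1` AND the t-test rejects, additive
#' otherwise. The index alone never classifies.
#'
#' @param gamma Interaction index (> 0).
#' @param p_value p-value of the ED_T vs ED_E t-test.
#' @param alpha Test level. Default 0.05.
#'
#' @return One of `"synergistic"`, `"additive"`, `"antagonistic"`.
#' @export
classify_interaction <- function(gamma, p_value, alpha = 0.05) {
  if (!is.finite(gamma) || gamma <= 0) stop("gamma must be > 0", call. = FALSE)
  if (gamma < 1 && p_value < alpha) "synergistic"
  else if (gamma > 1 && p_value < alpha) "antagonistic"
  else "additive"
}

#' Full isobolographic interaction analysis
#'
#' Combines the component and combination ED estimates into the standard
#' fixed-ratio isobolographic result: theoretical additive ED, t-test
#' against the experimental ED, interaction index with SE, and the
#' interaction classification.
#'
#' @param ed_a,ed_b Component `ed_estimate`s.
#' @param ed_e Experimental combination `ed_estimate`.
#' @param f Fraction of drug A. Default 0.5.
#' @param alpha Test level. Default 0.05.
#'
#' @return An object of class `interaction_result` with `ed_theoretical`,
#'   `ed_experimental`, `gamma`, `gamma_se`, `t_stat`, `df`, `p_value`,
#'   `classification`, `f`, `alpha`, plus the component estimates.
#' @export
analyze_interaction <- function(ed_a, ed_b, ed_e, f = 0.5, alpha = 0.05) {
  ed_t <- additive_ed(ed_a, ed_b, f = f, alpha = alpha)
  tt <- test_additivity(ed_t, ed_e, alpha = alpha)
  gi <- interaction_index(ed_e, ed_t)
  structure(
    list(ed_a = ed_a, ed_b = ed_b,
         ed_theoretical = ed_t, ed_experimental = ed_e,
         gamma = gi$gamma, gamma_se = gi$gamma_se,
         t_stat = tt$t_stat, df = tt$df, p_value = tt$p_value,
         classification = classify_interaction(gi$gamma, tt$p_value, alpha),
         f = f, alpha = alpha),
    class = "interaction_result")
}

#' @export
print.interaction_result <- function(x, ...) {
  cat("<interaction_result>\n")
  cat(sprintf("  ED%g theoretical (additive): %.4g mg/kg (SE %.4g)\n",
              x$ed_theoretical$level, x$ed_theoretical$dose,
              x$ed_theoretical$se))
  cat(sprintf("  ED%g experimental:           %.4g mg/kg (SE %.4g)\n",
              x$ed_experimental$level, x$ed_experimental$dose,
              x$ed_experimental$se))
  cat(sprintf("  t = %.3f on %g df, p = %.3g\n", x$t_stat, x$df, x$p_value))
  cat(sprintf("  interaction index gamma = %.4g (SE %.4g) -> %s\n",
              x$gamma, x$gamma_se, x$classification))
  invisible(x)
}

#' Isobologram coordinates
#'
#' Coordinates for the classical isobologram in (dose_B, dose_A) axes: the
#' additivity-line endpoints at the single-drug EDs, the theoretical
#' additive point (which lies on the line by construction), and the
#' experimental point, obtained by splitting the experimental total along
#' the fixed-ratio ray. CI bounds on the total dose accompany the two
#' combination points.
#'
#' @param ed_a,ed_b Component `ed_estimate`s (A on the y-axis, B on the
#'   x-axis).
#' @param ed_t Theoretical additive `ed_estimate`.
#' @param ed_e Experimental `ed_estimate`.
#' @param f Fraction of drug A. Default 0.5.
#'
#' @return A data frame with columns `role`, `dose_b_mg_kg`,
#'   `dose_a_mg_kg`, `ci_low_total`, `ci_high_total`.
#' @export
isobologram_coordinates <- function(ed_a, ed_b, ed_t, ed_e, f = 0.5) {
  stopifnot(inherits(ed_a, "ed_estimate"), inherits(ed_b, "ed_estimate"),
            inherits(ed_t, "ed_estimate"), inherits(ed_e, "ed_estimate"))
  # component shares along the fixed ray
  tot_a <- f * ed_a$dose
  tot_b <- (1 - f) * ed_b$dose
  share_a <- tot_a / (tot_a + tot_b)
  out <- data.frame(
    role = c("axis_drug_b", "axis_drug_a", "theoretical", "experimental"),
    dose_b_mg_kg = c(ed_b$dose, 0, tot_b, ed_e$dose * (1 - share_a)),
    dose_a_mg_kg = c(0, ed_a$dose, tot_a, ed_e$dose * share_a),
    ci_low_total = c(NA, NA, ed_t$ci_low, ed_e$ci_low),
    ci_high_total = c(NA, NA, ed_t$ci_high, ed_e$ci_high))
  out
}
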