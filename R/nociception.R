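#' Trapezoidal AUC of a flinch time course over a window
#'
#' Integrates the piecewise-linear interpolant of the flinches/min record
#' over `[t0, t1]` by the composite trapezoidal rule. Window endpoints that
#' fall between grid points are handled by linear interpolation, so
#' integrals over adjacent windows sharing a boundary add exactly.
#'
#' @param times Observation minutes (strictly increasing).
#' @param counts Flinches/min at each time.
#' @param window Length-2 numeric `c(t0, t1)` with `t0 < t1`, inside the
#'   observed range.
#'
#' @return The AUC in flinch-minutes.
#' @export
#' @examples
#' trapezoid_auc(seq(0, 60, 5), rep(2, 13), c(0, 60))  # 120
trapezoid_auc <- function(times, counts, window) {
  if (length(window) != 2L || !is.numeric(window))
    stop("window must be numeric c(t0, t1)", call. = FALSE)
  t0 <- window[1L]; t1 <- window[2L]
  if (t1 <= t0) stop("window inverted: t1 must exceed t0", call. = FALSE)
  if (length(times) < 2L)
    stop("need at least 2 observations to integrate", call. = FALSE)
  if (t0 < times[1L] || t1 > times[length(times)])
    stop("window must lie within the observed time range", call. = FALSE)
  inside <- times > t0 & times < t1
  y0 <- stats::approx(times, counts, xout = t0)$y
  y1 <- stats::approx(times, counts, xout = t1)$y
  x <- c(t0, times[inside], t1)
  y <- c(y0, counts[inside], y1)
  sum(diff(x) * (y[-length(y)] + y[-1L]) / 2)
}

#' Phase-split AUCs of a flinch time course
#'
#' Computes the trapezoidal AUC over phase 1 (`[0, boundary]`, nociceptive
#' pain), phase 2 (`[boundary, end]`, inflammatory pain) and the overall
#' window `[0, end]`. The boundary observation contributes to both phases,
#' so `phase1 + phase2 == overall` exactly.
#'
#' @param tc A [flinch_timecourse()].
#' @param boundary Phase boundary in minutes (default 15).
#' @param end End of observation in minutes (default 60).
#'
#' @return A list of class `auc_result` with `phase1`, `phase2`, `overall`.
#' @export
split_phase_aucs <- function(tc, boundary = 15, end = 60) {
  stopifnot(inherits(tc, "flinch_timecourse"))
  structure(
    list(phase1 = trapezoid_auc(tc$times, tc$counts, c(0, boundary)),
         phase2 = trapezoid_auc(tc$times, tc$counts, c(boundary, end)),
         overall = trapezoid_auc(tc$times, tc$counts, c(0, end))),
    class = "auc_result")
}

#' Percent antinociception
#'
#' The effect scale of the formalin test: the fractional reduction of the
#' treated AUC relative to the vehicle mean AUC, times 100. Negative values
#' (hyperalgesia, treated AUC above vehicle) are retained.
#'
#' @param auc_vehicle_mean Mean vehicle AUC (flinch-minutes, > 0).
#' @param auc_treated Treated AUC (flinch-minutes).
#'
#' @return Percent antinociception; at most 100, unbounded below.
#' @export
#' @examples
#' percent_antinociception(600, 420)  # 30
percent_antinociception <- function(auc_vehicle_mean, auc_treated) {
  if (!is.finite(auc_vehicle_mean) || auc_vehicle_mean <= 0)
    stop("vehicle AUC must be positive (degenerate vehicle group?)",
         call. = FALSE)
  (auc_vehicle_mean - auc_treated) / auc_vehicle_mean * 100
}

#' Summarize a treatment group against the vehicle arm
#'
#' Computes per-animal AUCs by phase, converts each to percent
#' antinociception against the phase-matched vehicle mean AUC, and averages
#' over animals (mean with SEM). Phase-specific vehicle denominators are
#' used: phase-1 effects are relative to the vehicle phase-1 mean AUC,
#' phase-2 effects to the phase-2 mean.
#'
#' @param group A [treatment_group()] to summarize.
#' @param vehicle The vehicle [treatment_group()] (must be flagged).
#' @param config A [run_config()]; supplies phase boundary and window end.
#'
#' @return A list of class `antinociception_summary` with group label, total
#'   dose, per-phase and overall mean effects, the SEM of the overall
#'   effect, `n`, the vehicle reference AUCs, the treated mean AUCs, and a
#'   `per_animal` data frame of per-animal effects.
#' @export
summarize_group <- function(group, vehicle, config = run_config()) {
  stopifnot(inherits(group, "treatment_group"),
            inherits(vehicle, "treatment_group"))
  if (!vehicle$is_vehicle)
    stop("the reference group must be flagged as vehicle", call. = FALSE)
  b <- config$phase_boundary; e <- config$observation_end
  veh_aucs <- lapply(vehicle$members, split_phase_aucs, boundary = b, end = e)
  ref <- list(phase1 = mean(vapply(veh_aucs, `[[`, numeric(1L), "phase1")),
              phase2 = mean(vapply(veh_aucs, `[[`, numeric(1L), "phase2")),
              overall = mean(vapply(veh_aucs, `[[`, numeric(1L), "overall")))
  grp_aucs <- lapply(group$members, split_phase_aucs, boundary = b, end = e)
  per <- data.frame(
    animal_id = vapply(group$members, `[[`, character(1L), "animal_id"),
    effect_phase1 = vapply(grp_aucs, function(a)
      percent_antinociception(ref$phase1, a$phase1), numeric(1L)),
    effect_phase2 = vapply(grp_aucs, function(a)
      percent_antinociception(ref$phase2, a$phase2), numeric(1L)),
    effect_overall = vapply(grp_aucs, function(a)
      percent_antinociception(ref$overall, a$overall), numeric(1L)))
  n <- nrow(per)
  sem <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else NA_real_
  structure(
    list(group_label = group$label,
         dose = group$dose_a + group$dose_b,
         dose_a = group$dose_a, dose_b = group$dose_b,
         effect_phase1 = mean(per$effect_phase1),
         effect_phase2 = mean(per$effect_phase2),
         effect_overall = mean(per$effect_overall),
         se_overall = sem(per$effect_overall),
         n = n,
         auc_vehicle_ref = ref,
         auc_mean = mean(vapply(grp_aucs, `[[`, numeric(1L), "overall")),
         per_animal = per),
    class = "antinociception_summary")
}

#' @export
print.antinociception_summary <- function(x, ...) {
  cat(sprintf("<antinociception_summary> '%s' (total dose %g mg/kg, n = %d)\n",
              x$group_label, x$dose, x$n))
  cat(sprintf("  effect %%: phase1 %.2f, phase2 %.2f, overall %.2f (SEM %.2f)\n",
              x$effect_phase1, x$effect_phase2, x$effect_overall,
              x$se_overall))
  invisible(x)
}

#' One-way ANOVA with Bonferroni-adjusted comparisons versus control
#'
#' Fits a one-way ANOVA on the per-animal overall effects of the supplied
#' group summaries, then compares each non-control group against the control
#' by a t-test on the pooled residual mean square (the classic Bonferroni
#' post-hoc), multiplying each raw p-value by the number of comparisons and
#' capping at 1.
#'
#' @param summaries List of [summarize_group()] results (each carrying
#'   `per_animal` effects).
#' @param control_label Label of the control group the others are compared
#'   against.
#'
#' @return A list with the ANOVA `f_stat`, `p_value`, `df`, and a
#'   `comparisons` data frame (group, estimate of mean difference, t, raw
#'   and Bonferroni-adjusted p).
#' @export
anova_bonferroni <- function(summaries, control_label) {
  if (length(summaries) < 2L)
    stop("need at least 2 groups", call. = FALSE)
  labs <- vapply(summaries, `[[`, character(1L), "group_label")
  if (!control_label %in% labs)
    stop("control group '", control_label, "' not among the summaries",
         call. = FALSE)
  ns <- vapply(summaries, `[[`, numeric(1L), "n")
  if (any(ns < 2L))
    stop("every group needs n >= 2 for the ANOVA", call. = FALSE)
  df <- do.call(rbind, lapply(summaries, function(s)
    data.frame(group = s$group_label, effect = s$per_animal$effect_overall)))
  df$group <- factor(df$group)
  fit <- stats::aov(effect ~ group, data = df)
  an <- stats::anova(fit)
  mse <- an["Residuals", "Mean Sq"]
  df_res <- an["Residuals", "Df"]
  others <- setdiff(labs, control_label)
  m <- length(others)
  ctl <- df$effect[df$group == control_label]
  comp <- do.call(rbind, lapply(others, function(g) {
    x <- df$effect[df$group == g]
    est <- mean(x) - mean(ctl)
    se <- sqrt(mse * (1 / length(x) + 1 / length(ctl)))
    tv <- if (se > 0) est / se else ifelse(est == 0, 0, sign(est) * Inf)
    p_raw <- 2 * stats::pt(-abs(tv), df_res)
    data.frame(group = g, estimate = est, t_stat = tv,
               p_raw = p_raw, p_adj = min(1, m * p_raw))
  }))
  rownames(comp) <- NULL
  list(f_stat = an["group", "F value"], p_value = an["group", "Pr(>F)"],
       df = c(an["group", "Df"], df_res), comparisons = comp)
}
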