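#' Simulation parameters for synthetic formalin-test studies
#'
#' Ground-truth model for the generator: a biphasic vehicle flinch
#' intensity (exponential early spike plus a Gaussian bump for the
#' inflammatory phase), log-linear single-drug suppression on the percent
#' scale, Loewe-additive combination behavior modulated by a single synergy
#' factor `psi`, and Poisson observation noise.
#'
#' The default single-drug lines place drug A (fast, potent over a low dose
#' range) and drug B (shallower onset, higher doses) in the regime of a
#' typical NSAID-plus-extract formalin study, so default simulations probe
#' the same dose decades the analysis pipeline is meant for.
#'
#' @param a1 Phase-1 peak intensity, flinches/min. Default 6.
#' @param tau1 Phase-1 exponential decay constant, min. Default 4.
#' @param a2 Phase-2 peak intensity, flinches/min. Default 4.
#' @param mu2 Phase-2 peak time, min. Default 35.
#' @param sigma2 Phase-2 Gaussian width, min. Default 12.
#' @param slope_a,intercept_a Drug A's percent-effect line vs log10(mg/kg).
#' @param slope_b,intercept_b Drug B's percent-effect line vs log10(mg/kg).
#' @param psi Synergy factor (> 0): 1 additive, < 1 synergistic (the
#'   combination needs only `psi` times the additive dose), > 1 antagonistic.
#' @param n_per_group Animals per group. Default 6.
#' @param grid Observation minutes. Default `seq(0, 60, by = 5)`.
#' @param seed Optional integer seed used by [simulate_study()].
#'
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(a1 = 6, tau1 = 4, a2 = 4, mu2 = 35, sigma2 = 12,
                       slope_a = 22.791, intercept_a = 9.698,
                       slope_b = 35.261, intercept_b = -31.853,
                       psi = 1, n_per_group = 6L,
                       grid = seq(0, 60, by = 5), seed = NULL) {
  if (any(c(a1, tau1, a2, sigma2) <= 0) || mu2 < 0)
    stop("intensity parameters must be positive", call. = FALSE)
  if (psi <= 0) stop("psi must be > 0", call. = FALSE)
  if (slope_a <= 0 || slope_b <= 0)
    stop("dose-effect slopes must be positive", call. = FALSE)
  if (n_per_group < 1L) stop("n_per_group must be >= 1", call. = FALSE)
  grid <- as.numeric(grid)
  if (any(diff(grid) <= 0) || grid[1L] < 0 || grid[length(grid)] > 60)
    stop("grid must be strictly increasing within [0, 60]", call. = FALSE)
  structure(
    list(a1 = a1, tau1 = tau1, a2 = a2, mu2 = mu2, sigma2 = sigma2,
         slope_a = slope_a, intercept_a = intercept_a,
         slope_b = slope_b, intercept_b = intercept_b,
         psi = psi, n_per_group = as.integer(n_per_group),
         grid = grid, seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "sim_params")
}

#' Vehicle flinch intensity
#'
#' The deterministic biphasic intensity underlying the vehicle arm:
#' `lambda(t) = a1 exp(-t/tau1) + a2 exp(-(t - mu2)^2 / (2 sigma2^2))`,
#' in flinches/min — an immediate nociceptive spike decaying over the first
#' minutes, a quiescent period, then a broad inflammatory second phase.
#'
#' @param t Time(s) in minutes, within \[0, 60\].
#' @param params A [sim_params()].
#' @return Intensity value(s), flinches/min.
#' @export
vehicle_intensity <- function(t, params = sim_params()) {
  if (any(t < 0 | t > 60))
    stop("t must lie within [0, 60] minutes", call. = FALSE)
  params$a1 * exp(-t / params$tau1) +
    params$a2 * exp(-(t - params$mu2)^2 / (2 * params$sigma2^2))
}

# single-drug effect fraction from its percent line, clamped to [0, 0.99]
.single_effect <- function(dose, slope, intercept) {
  if (dose <= 0) return(0)
  pmin(pmax(intercept + slope * log10(dose), 0), 99) / 100
}

# dose of one drug achieving effect fraction e under its line
.single_ed <- function(e, slope, intercept) {
  10^((100 * e - intercept) / slope)
}

#' Ground-truth suppression fraction of a dose pair
#'
#' The generator's true effect surface. Single drugs follow their percent
#' line, clamped to \[0, 99\]% . A combination follows a Loewe construction:
#' the effect `E` solves `dose_a / D_A(E) + dose_b / D_B(E) = psi`, where
#' `D_X(E)` is the single-drug dose achieving `E`; `psi < 1` means smaller
#' doses suffice (synergy). Solved by root bracketing on the effect scale.
#'
#' @param dose_a,dose_b Doses in mg/kg (>= 0).
#' @param params A [sim_params()].
#' @return Effect fraction in \[0, 0.99\].
#' @export
effect_fraction <- function(dose_a, dose_b, params = sim_params()) {
  if (dose_a < 0 || dose_b < 0) stop("doses must be >= 0", call. = FALSE)
  if (dose_b == 0) return(.single_effect(dose_a, params$slope_a, params$intercept_a))
  if (dose_a == 0) return(.single_effect(dose_b, params$slope_b, params$intercept_b))
  h <- function(e) {
    dose_a / .single_ed(e, params$slope_a, params$intercept_a) +
      dose_b / .single_ed(e, params$slope_b, params$intercept_b) - params$psi
  }
  lo <- 1e-9; hi <- 0.99
  if (h(lo) <= 0) return(0)      # doses too small for any measurable effect
  if (h(hi) >= 0) return(0.99)   # ceiling of the suppression model
  r <- stats::uniroot(h, c(lo, hi), tol = 1e-12)
  if (abs(h(r$root)) > 1e-6)
    stop("Loewe effect solve did not converge", call. = FALSE)
  r$root
}

#' Ground-truth effective dose of the simulation model
#'
#' Closed-form inversion of the true suppression model for a single drug,
#' or a root solve on the total dose along the fixed-ratio ray for the
#' combination (the ray mixes the drugs in the proportion
#' `f * ED_A : (1 - f) * ED_B` of their true effective doses).
#'
#' @param params A [sim_params()].
#' @param drug One of `"A"`, `"B"`, `"combination"`.
#' @param level Target percent effect, in (0, 100). Default 30.
#' @param f Fraction of drug A in the combination ray. Default 0.5.
#' @return Dose in mg/kg.
#' @export
ground_truth_ed <- function(params = sim_params(), drug = c("A", "B", "combination"),
                            level = 30, f = 0.5) {
  drug <- match.arg(drug)
  if (!(level > 0 && level < 100))
    stop("level must be in (0, 100)", call. = FALSE)
  if (level >= 99)
    stop("level is above the model's effect ceiling", call. = FALSE)
  if (drug == "A") return(.single_ed(level / 100, params$slope_a, params$intercept_a))
  if (drug == "B") return(.single_ed(level / 100, params$slope_b, params$intercept_b))
  ed_a <- .single_ed(level / 100, params$slope_a, params$intercept_a)
  ed_b <- .single_ed(level / 100, params$slope_b, params$intercept_b)
  top <- f * ed_a + (1 - f) * ed_b
  ra <- f * ed_a / top
  g <- function(total)
    effect_fraction(total * ra, total * (1 - ra), params) - level / 100
  # additive total times psi brackets the root on both sides
  r <- stats::uniroot(g, c(top * params$psi * 0.01, top * params$psi * 100),
                      tol = 1e-10)
  r$root
}

#' Default dose groups emulating the study layout
#'
#' The arm structure of a fixed-ratio isobolographic formalin study: a
#' vehicle arm, six log-increment doses per single drug, and a six-level
#' halving combination series along the fixed ray. Every arm is anchored at
#' its ground-truth effective dose so all design points fall in the
#' informative (unclamped) region of the generator's effect surface: the
#' single-drug doses are `ED * 10^seq(-0.4, 1.6, 0.4)` and the combination
#' totals halve downward from `2^2.5` times the true combination ED,
#' placing that ED at the geometric centre of the series.
#'
#' @param params A [sim_params()].
#' @param level Target percent effect anchoring the design. Default 30.
#' @param f Fraction of drug A. Default 0.5.
#' @param n_levels Combination levels. Default 6.
#' @return Data frame with columns `label`, `dose_a`, `dose_b`, `vehicle`.
#' @export
default_dose_groups <- function(params = sim_params(), level = 30, f = 0.5,
                                n_levels = 6L) {
  ed_a <- ground_truth_ed(params, "A", level)
  ed_b <- ground_truth_ed(params, "B", level)
  doses_a <- ed_a * 10^seq(-0.4, 1.6, by = 0.4)
  doses_b <- ed_b * 10^seq(-0.4, 1.6, by = 0.4)
  ed_c <- ground_truth_ed(params, "combination", level, f = f)
  tot <- ed_c * 2^seq((n_levels - 1) / 2, -(n_levels - 1) / 2, by = -1)
  share_a <- f * ed_a / (f * ed_a + (1 - f) * ed_b)
  rbind(
    data.frame(label = "vehicle", dose_a = 0, dose_b = 0, vehicle = TRUE),
    data.frame(label = sprintf("A_%d", seq_along(doses_a)),
               dose_a = doses_a, dose_b = 0, vehicle = FALSE),
    data.frame(label = sprintf("B_%d", seq_along(doses_b)),
               dose_a = 0, dose_b = doses_b, vehicle = FALSE),
    data.frame(label = sprintf("combo_%d", seq_len(n_levels)),
               dose_a = tot * share_a,
               dose_b = tot * (1 - share_a), vehicle = FALSE))
}

#' Simulate a formalin-test study
#'
#' Draws, for each animal and observation time, a Poisson flinch count with
#' mean `lambda(t) * (1 - E(dose_a, dose_b))` — the biphasic vehicle
#' intensity thinned by the ground-truth suppression fraction. Reproducible
#' under `params$seed`.
#'
#' @param params A [sim_params()].
#' @param dose_groups Data frame with columns `label`, `dose_a`, `dose_b`
#'   and optionally `vehicle` (logical); must include a vehicle arm with
#'   both doses 0. Default [default_dose_groups()].
#' @return A named list of [treatment_group()] objects.
#' @export
simulate_study <- function(params = sim_params(),
                           dose_groups = default_dose_groups(params)) {
  stopifnot(is.data.frame(dose_groups),
            all(c("label", "dose_a", "dose_b") %in% names(dose_groups)))
  if (!"vehicle" %in% names(dose_groups))
    dose_groups$vehicle <- dose_groups$dose_a == 0 & dose_groups$dose_b == 0
  if (sum(dose_groups$vehicle) != 1L)
    stop("exactly one vehicle arm is required", call. = FALSE)
  if (!is.null(params$seed)) set.seed(params$seed)
  lam0 <- vehicle_intensity(params$grid, params)
  out <- lapply(seq_len(nrow(dose_groups)), function(i) {
    g <- dose_groups[i, ]
    E <- effect_fraction(g$dose_a, g$dose_b, params)
    mu <- lam0 * (1 - E)
    members <- lapply(seq_len(params$n_per_group), function(j) {
      flinch_timecourse(sprintf("%s_rat%02d", g$label, j), g$label,
                        g$dose_a, g$dose_b, params$grid,
                        stats::rpois(length(mu), mu))
    })
    treatment_group(g$label, members, is_vehicle = isTRUE(g$vehicle))
  })
  names(out) <- dose_groups$label
  out
}
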