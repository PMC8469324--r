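#' Run the full fixed-ratio isobolographic analysis
#'
#' Orchestrates the whole pipeline in either of two input modes.
#'
#' **Table mode** (`drug_a`, `drug_b`, `combination` given): each input is a
#' group-level dose-effect table (path or data frame accepted by
#' [read_dose_effect_table()]). Each arm is fitted by OLS of percent effect
#' on log10(dose), the single-drug fits are inverted at the target level,
#' the theoretical additive ED is formed with fraction `f`, the combination
#' fit is inverted for the experimental ED, and the interaction is tested
#' and classified.
#'
#' **Time-course mode** (`timecourses` given): a long-format CSV path or a
#' list of [treatment_group()]s. Groups are summarized against the vehicle
#' arm, partitioned into drug-A-only, drug-B-only, and combination arms by
#' their component doses, and per-animal overall effects feed the three
#' dose-response fits.
#'
#' @param drug_a,drug_b,combination Dose-effect tables (table mode).
#' @param timecourses Long CSV path or list of treatment groups
#'   (time-course mode).
#' @param config A [run_config()].
#'
#' @return An object of class `isobolab_analysis`: the three `dr_fit`s, the
#'   three `ed_estimate`s, the `interaction_result`, the fixed-ratio
#'   design, isobologram coordinates, and (in time-course mode) the group
#'   summaries.
#' @export
#' @examples
#' tabs <- popex_asa_tables()
#' res <- run_full_analysis(drug_a = tabs$drug_a, drug_b = tabs$drug_b,
#'                          combination = tabs$combination)
#' res$result$classification
run_full_analysis <- function(drug_a = NULL, drug_b = NULL,
                              combination = NULL, timecourses = NULL,
                              config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  summaries <- NULL
  if (!is.null(timecourses)) {
    groups <- if (is.list(timecourses) && !is.data.frame(timecourses) &&
                  all(vapply(timecourses, inherits, logical(1L), "treatment_group")))
      timecourses else read_timecourses(timecourses)
    veh <- Filter(function(g) g$is_vehicle, groups)
    if (length(veh) != 1L)
      stop("time-course mode needs exactly one vehicle arm", call. = FALSE)
    veh <- veh[[1L]]
    treated <- Filter(function(g) !g$is_vehicle, groups)
    summaries <- lapply(treated, summarize_group, vehicle = veh,
                        config = config)
    per_animal_table <- function(keep) {
      sel <- Filter(keep, summaries)
      if (length(sel) == 0L) return(NULL)
      do.call(rbind, lapply(sel, function(s)
        data.frame(dose = s$dose, effect_pct = s$per_animal$effect_overall)))
    }
    drug_a <- per_animal_table(function(s) s$dose_a > 0 & s$dose_b == 0)
    drug_b <- per_animal_table(function(s) s$dose_a == 0 & s$dose_b > 0)
    combination <- per_animal_table(function(s) s$dose_a > 0 & s$dose_b > 0)
  }
  for (arm in c("drug_a", "drug_b", "combination"))
    if (is.null(get(arm)))
      stop("missing arm: ", arm, call. = FALSE)
  if (is.null(timecourses)) {
    # table mode: normalize paths / data frames through the reader
    drug_a <- read_dose_effect_table(drug_a)
    drug_b <- read_dose_effect_table(drug_b)
    combination <- read_dose_effect_table(combination)
  }
  tab_a <- drug_a; tab_b <- drug_b; tab_e <- combination

  fit_a <- fit_dose_response(tab_a, label = "drug A")
  fit_b <- fit_dose_response(tab_b, label = "drug B")
  fit_e <- fit_dose_response(tab_e, label = "combination")
  lvl <- config$effect_level
  ed_a <- suppressWarnings(ed_x(fit_a, level = lvl, alpha = config$alpha))
  ed_b <- suppressWarnings(ed_x(fit_b, level = lvl, alpha = config$alpha))
  ed_e <- suppressWarnings(ed_x(fit_e, level = lvl, alpha = config$alpha))
  result <- analyze_interaction(ed_a, ed_b, ed_e, f = config$proportion_f,
                                alpha = config$alpha)
  design <- build_fixed_ratio_design(ed_a, ed_b, f = config$proportion_f)
  coords <- isobologram_coordinates(ed_a, ed_b, result$ed_theoretical,
                                    ed_e, f = config$proportion_f)
  structure(
    list(fits = list(drug_a = fit_a, drug_b = fit_b, combination = fit_e),
         eds = list(drug_a = ed_a, drug_b = ed_b, combination = ed_e),
         result = result, design = design, coordinates = coords,
         summaries = summaries, config = config),
    class = "isobolab_analysis")
}

#' @export
print.isobolab_analysis <- function(x, ...) {
  cat("== Fixed-ratio isobolographic analysis ==\n")
  for (f in x$fits) print(f)
  for (e in x$eds) print(e)
  print(x$result)
  invisible(x)
}

#' Write an analysis report bundle
#'
#' Writes a machine-readable JSON document with every estimate at full
#' precision, a CSV summary of the fits and effective doses (doses and
#' percentages rounded to 2 decimals for display), and the isobologram
#' coordinates CSV.
#'
#' @param analysis An `isobolab_analysis` from [run_full_analysis()].
#' @param dir Output directory (created if absent).
#' @return Named character vector of the files written, invisibly.
#' @export
write_report <- function(analysis, dir) {
  if (!inherits(analysis, "isobolab_analysis"))
    stop("analysis must be an isobolab_analysis object", call. = FALSE)
  if (length(analysis$fits) == 0L || length(analysis$eds) == 0L)
    stop("analysis is empty; nothing to write", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ed_json <- function(e) list(level = e$level, dose = e$dose, se = e$se,
                              ci_low = e$ci_low, ci_high = e$ci_high,
                              df = e$df, extrapolated = e$extrapolated)
  fit_json <- function(f) list(intercept = f$intercept, slope = f$slope,
                               r2 = f$r2, n_points = f$n_points,
                               residual_df = f$residual_df,
                               cov = as.vector(f$cov))
  res <- analysis$result
  doc <- list(
    config = unclass(analysis$config),
    fits = lapply(analysis$fits, fit_json),
    effective_doses = lapply(analysis$eds, ed_json),
    interaction = list(
      ed_theoretical = ed_json(res$ed_theoretical),
      ed_experimental = ed_json(res$ed_experimental),
      gamma = res$gamma, gamma_se = res$gamma_se,
      t_stat = res$t_stat, df = res$df, p_value = res$p_value,
      classification = res$classification),
    design_levels = analysis$design$levels)
  json_path <- file.path(dir, "analysis.json")
  jsonlite::write_json(doc, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  ed_rows <- do.call(rbind, lapply(names(analysis$eds), function(nm) {
    e <- analysis$eds[[nm]]
    data.frame(arm = nm, level = e$level, dose_mg_kg = round(e$dose, 2),
               se = round(e$se, 2), ci_low = round(e$ci_low, 2),
               ci_high = round(e$ci_high, 2))
  }))
  summary_path <- file.path(dir, "effective_doses.csv")
  utils::write.csv(ed_rows, summary_path, row.names = FALSE)
  design_path <- file.path(dir, "design_levels.csv")
  utils::write.csv(transform(analysis$design$levels,
                             dose_a = round(dose_a, 2),
                             dose_b = round(dose_b, 2),
                             total = round(total, 2)),
                   design_path, row.names = FALSE)
  coords_path <- file.path(dir, "isobologram_coordinates.csv")
  utils::write.csv(analysis$coordinates, coords_path, row.names = FALSE)
  invisible(c(json = json_path, summary = summary_path,
              design = design_path, coordinates = coords_path))
}
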