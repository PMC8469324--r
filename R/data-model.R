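#' Flinch-count time course for a single animal
#'
#' Container for one animal's formalin-test observation record: the number of
#' paw flinches counted in a 1-min window at each observation time, together
#' with the treatment metadata (component doses of drug A and drug B in
#' mg/kg). Times are the start minutes of each observation window; counts are
#' interpreted as flinches/min rates at those times when integrating.
#'
#' @param animal_id Identifier for the animal (coerced to character).
#' @param group_label Treatment-group label.
#' @param dose_a Dose of drug A in mg/kg (>= 0).
#' @param dose_b Dose of drug B in mg/kg (>= 0).
#' @param times Observation minutes, strictly increasing, within \[0, 60\].
#' @param counts Flinches observed in the 1-min window at each time;
#'   non-negative integers, same length as `times`.
#'
#' @return An object of class `flinch_timecourse`.
#' @export
#' @examples
#' tc <- flinch_timecourse("r1", "vehicle", 0, 0,
#'                         times = seq(0, 60, by = 5),
#'                         counts = rep(2L, 13))
#' tc$counts
flinch_timecourse <- function(animal_id, group_label, dose_a, dose_b,
                              times, counts) {
  stopifnot(length(dose_a) == 1L, length(dose_b) == 1L)
  if (!is.numeric(dose_a) || !is.numeric(dose_b) || dose_a < 0 || dose_b < 0)
    stop("doses must be non-negative numbers", call. = FALSE)
  times <- as.numeric(times)
  counts <- as.numeric(counts)
  if (length(times) != length(counts))
    stop("times and counts must have the same length", call. = FALSE)
  if (length(times) < 1L)
    stop("at least one observation is required", call. = FALSE)
  if (anyNA(times) || anyNA(counts))
    stop("times and counts must not contain NA", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (times[1L] < 0 || times[length(times)] > 60)
    stop("times must lie within [0, 60] minutes", call. = FALSE)
  if (any(counts < 0))
    stop("counts must be non-negative", call. = FALSE)
  structure(
    list(animal_id = as.character(animal_id),
         group_label = as.character(group_label),
         dose_a = as.numeric(dose_a), dose_b = as.numeric(dose_b),
         times = times, counts = counts),
    class = "flinch_timecourse")
}

#' @export
print.flinch_timecourse <- function(x, ...) {
  cat(sprintf("<flinch_timecourse> animal %s, group '%s', dose A %g / B %g mg/kg, %d obs over [%g, %g] min\n",
              x$animal_id, x$group_label, x$dose_a, x$dose_b,
              length(x$times), x$times[1L], x$times[length(x$times)]))
  invisible(x)
}

#' Treatment group of flinch time courses
#'
#' Bundles the animals of one treatment arm. All members must carry the same
#' component doses; exactly one group in a study should be flagged as the
#' vehicle (control) arm. The vehicle flag is explicit and never inferred
#' from zero doses, because non-drug arms (e.g. pathway antagonist controls)
#' may also carry zero doses of both study drugs.
#'
#' @param label Group label.
#' @param members List of [flinch_timecourse()] objects (n >= 1).
#' @param is_vehicle Logical; is this the vehicle/control arm?
#'
#' @return An object of class `treatment_group` with fields `label`,
#'   `members`, `is_vehicle`, `dose_a`, `dose_b`, `n`.
#' @export
treatment_group <- function(label, members, is_vehicle = FALSE) {
  if (!is.list(members) || length(members) < 1L)
    stop("a treatment group needs at least one time course", call. = FALSE)
  ok <- vapply(members, inherits, logical(1L), what = "flinch_timecourse")
  if (!all(ok))
    stop("all members must be flinch_timecourse objects", call. = FALSE)
  da <- vapply(members, `[[`, numeric(1L), "dose_a")
  db <- vapply(members, `[[`, numeric(1L), "dose_b")
  if (length(unique(da)) != 1L || length(unique(db)) != 1L)
    stop("all members of a group must share dose_a and dose_b", call. = FALSE)
  structure(
    list(label = as.character(label), members = members,
         is_vehicle = isTRUE(is_vehicle),
         dose_a = da[1L], dose_b = db[1L], n = length(members)),
    class = "treatment_group")
}

#' @export
print.treatment_group <- function(x, ...) {
  cat(sprintf("<treatment_group> '%s'%s: n = %d, dose A %g / B %g mg/kg\n",
              x$label, if (x$is_vehicle) " (vehicle)" else "",
              x$n, x$dose_a, x$dose_b))
  invisible(x)
}

#' Analysis configuration
#'
#' Collects the tunable settings of the pipeline: the target effect level for
#' effective-dose estimation (30 for ED30), the fraction of drug A in the
#' fixed-ratio combination, the test level, the phase boundary and end of the
#' observation window, and an optional seed.
#'
#' @param effect_level Target percent antinociception for ED estimation,
#'   in (0, 100). Default 30.
#' @param proportion_f Fraction of drug A's ED contributed to the fixed-ratio
#'   combination, in \[0, 1\]. Default 0.5 (the 1:1 design).
#' @param alpha Significance level, in (0, 1). Default 0.05.
#' @param phase_boundary Minute separating phase 1 (nociceptive) from phase 2
#'   (inflammatory). Default 15.
#' @param observation_end Last minute of the observation window. Default 60.
#' @param seed Optional integer seed.
#'
#' @return An object of class `run_config`.
#' @export
run_config <- function(effect_level = 30, proportion_f = 0.5, alpha = 0.05,
                       phase_boundary = 15, observation_end = 60,
                       seed = NULL) {
  if (!(effect_level > 0 && effect_level < 100))
    stop("effect_level must be in (0, 100)", call. = FALSE)
  if (!(proportion_f >= 0 && proportion_f <= 1))
    stop("proportion_f must be in [0, 1]", call. = FALSE)
  if (!(alpha > 0 && alpha < 1))
    stop("alpha must be in (0, 1)", call. = FALSE)
  if (!(phase_boundary > 0 && phase_boundary < observation_end))
    stop("phase_boundary must lie inside the observation window", call. = FALSE)
  structure(
    list(effect_level = effect_level, proportion_f = proportion_f,
         alpha = alpha, phase_boundary = phase_boundary,
         observation_end = observation_end,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "run_config")
}

#' Read flinch time courses from a long-format CSV
#'
#' Expects a header with columns `animal_id`, `group`, `dose_a`, `dose_b`,
#' `time_min`, `flinches`. Rows are grouped by (group, animal) into
#' [flinch_timecourse()] objects, sorted by time, and assembled into
#' [treatment_group()]s. A `vehicle` column (logical/0-1), if present, flags
#' the control arm; otherwise groups named `"vehicle"` (case-insensitive)
#' are flagged.
#'
#' @param path Path to the CSV file.
#'
#' @return A named list of `treatment_group` objects.
#' @export
read_timecourses <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("animal_id", "group", "dose_a", "dose_b", "time_min", "flinches")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (any(df$flinches < 0))
    stop("negative flinch count in input", call. = FALSE)
  key <- paste(df$group, df$animal_id, df$time_min, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (animal, time) observation in input", call. = FALSE)
  has_flag <- "vehicle" %in% names(df)
  groups <- split(df, df$group)
  out <- lapply(groups, function(g) {
    tcs <- lapply(split(g, g$animal_id), function(a) {
      a <- a[order(a$time_min), , drop = FALSE]
      flinch_timecourse(a$animal_id[1L], a$group[1L],
                        a$dose_a[1L], a$dose_b[1L],
                        a$time_min, a$flinches)
    })
    is_veh <- if (has_flag) any(as.logical(g$vehicle))
              else tolower(g$group[1L]) == "vehicle"
    treatment_group(g$group[1L], unname(tcs), is_vehicle = is_veh)
  })
  out
}

#' Write flinch time courses to a long-format CSV
#'
#' Inverse of [read_timecourses()]: writes one row per observation with the
#' columns that reader expects, plus the `vehicle` flag.
#'
#' @param groups List of `treatment_group` objects.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_timecourses <- function(groups, path) {
  rows <- lapply(groups, function(g) {
    do.call(rbind, lapply(g$members, function(tc) {
      data.frame(animal_id = tc$animal_id, group = g$label,
                 dose_a = tc$dose_a, dose_b = tc$dose_b,
                 time_min = tc$times, flinches = tc$counts,
                 vehicle = g$is_vehicle)
    }))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read a dose-effect table
#'
#' Table-mode input: group-level percent antinociception by dose, as printed
#' in a dose-response summary table. Requires columns `dose` (total mg/kg,
#' > 0) and `effect_pct`; optional `se` and `n`. `log10_dose` is computed
#' from `dose`; if the file carries its own `log10_dose` column it must agree
#' with `log10(dose)` to 1e-9.
#'
#' @param path Path to the CSV file, or a data frame with the same columns.
#'
#' @return A data frame of class `dose_effect` with columns `dose`,
#'   `log10_dose`, `effect_pct`, `se`, `n`, sorted by dose.
#' @export
#' @examples
#' tabs <- popex_asa_tables()
#' head(tabs$drug_b)
read_dose_effect_table <- function(path) {
  df <- if (is.data.frame(path)) path else {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  required <- c("dose", "effect_pct")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(df$dose)) || any(df$dose <= 0))
    stop("all doses must be finite and > 0", call. = FALSE)
  lg <- log10(df$dose)
  if ("log10_dose" %in% names(df)) {
    if (any(abs(df$log10_dose - lg) >= 1e-9))
      stop("log10_dose column disagrees with log10(dose)", call. = FALSE)
  }
  out <- data.frame(dose = df$dose, log10_dose = lg,
                    effect_pct = df$effect_pct,
                    se = if ("se" %in% names(df)) df$se else NA_real_,
                    n = if ("n" %in% names(df)) df$n else NA_integer_)
  out <- out[order(out$dose), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("dose_effect", "data.frame")
  out
}

#' Printed dose-effect tables of the PoPEx/ASA formalin study
#'
#' Convenience accessor for the three group-mean dose-effect tables shipped
#' with the package: overall percent antinociception versus dose for
#' acetylsalicylic acid (drug A), pomegranate peel extract (drug B), and
#' their 1:1 fixed-ratio combination, each with six dose levels and n = 6
#' animals per group.
#'
#' @return A named list of three `dose_effect` data frames:
#'   `drug_a` (ASA), `drug_b` (PoPEx), `combination`.
#' @export
popex_asa_tables <- function() {
  pth <- function(f) system.file("extdata", f, package = "isobolab",
                                 mustWork = TRUE)
  list(drug_a = read_dose_effect_table(pth("asa_overall.csv")),
       drug_b = read_dose_effect_table(pth("popex_overall.csv")),
       combination = read_dose_effect_table(pth("combination_overall.csv")))
}
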