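#' Measurement-unit dialects for patient tables
#'
#' Published CAR-T time courses report abundance in different units. The
#' dialect converts them to absolute cell numbers: qPCR transgene counts at
#' 1e5 cells per (copy per microgram of DNA) -- the factor implied by a
#' detection threshold of 25 copies/ug corresponding to 2.5e6 cells -- and
#' per-microliter concentrations via a total blood volume in microliters.
#' Per-kilogram doses are scaled by a nominal body weight of 60 kg.
#'
#' @param value_unit One of `"cells"`, `"copies_per_ug_dna"`,
#'   `"cells_per_uL"`.
#' @param conversion_factor Cells per reported unit; defaults to 1 for
#'   cells, 1e5 for copies/ug DNA, 5e6 (5 L of blood in uL) for cells/uL.
#' @param weight_kg Body weight used for per-kg doses (default 60).
#' @return A list of class `carkin_dialect`.
#' @export
#' @examples
#' d <- table_dialect("copies_per_ug_dna")
#' 25 * d$conversion_factor # 2.5e6 cells
table_dialect <- function(value_unit = c("cells", "copies_per_ug_dna",
                                         "cells_per_uL"),
                          conversion_factor = NULL, weight_kg = 60) {
  value_unit <- match.arg(value_unit)
  if (is.null(conversion_factor)) {
    conversion_factor <- switch(value_unit,
      cells = 1, copies_per_ug_dna = 1e5, cells_per_uL = 5e6)
  }
  if (!is.finite(conversion_factor) || conversion_factor <= 0)
    stop("conversion_factor must be > 0")
  if (!is.finite(weight_kg) || weight_kg <= 0)
    stop("weight_kg must be > 0")
  structure(list(value_unit = value_unit,
                 conversion_factor = conversion_factor,
                 weight_kg = weight_kg),
            class = "carkin_dialect")
}

#' Read a patient time-course table
#'
#' Reads a CSV with columns `day` and `value` (and optionally `censored`)
#' plus a metadata list (or YAML sidecar file) and assembles a
#' [patient_record()] in absolute cell numbers. Values are converted via
#' the dialect; doses given per kilogram are multiplied by the dialect's
#' body weight; a missing dose for ALL patients defaults to 1e8 cells (the
#' median CAR-positive viable T-cell dose for patients over 50 kg).
#'
#' @param path CSV file path.
#' @param dialect A [table_dialect()] (default: values already in cells).
#' @param meta Named list or path to a YAML file with optional entries
#'   `id`, `disease`, `dose` (total), `dose_per_kg`, `split_fractions`,
#'   `split_days`, `detection_threshold` (in the dialect's value unit),
#'   `T0`, `followup_day`, `outcome`.
#' @return A [patient_record()].
#' @export
read_patient_table <- function(path, dialect = table_dialect(), meta = list()) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.character(meta)) meta <- yaml::read_yaml(meta)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("day", "value") %in% names(tab)))
    stop("patient table must have columns `day` and `value`")
  bad <- which(!is.finite(tab$day) | !is.finite(tab$value) | tab$value < 0)
  if (length(bad) > 0)
    stop("unparseable or negative rows at lines: ",
         paste(bad + 1, collapse = ", "))

  # [[ ]] access throughout: `$` on lists partial-matches names (e.g.
  # meta$dose would silently pick up dose_per_kg)
  value_cells <- tab$value * dialect$conversion_factor
  threshold <- meta[["detection_threshold"]]
  threshold <- if (is.null(threshold)) 2.5e6
               else threshold * dialect$conversion_factor

  dose <- meta[["dose"]]
  if (is.null(dose) && !is.null(meta[["dose_per_kg"]]))
    dose <- meta[["dose_per_kg"]] * dialect$weight_kg
  if (is.null(dose)) {
    if (identical(meta[["disease"]], "ALL")) {
      dose <- 1e8
    } else {
      stop("dose missing from metadata (defaulted only for disease = 'ALL')")
    }
  }
  schedule <- if (!is.null(meta[["split_fractions"]])) {
    split_schedule(dose, meta[["split_fractions"]],
                   day = meta[["split_days"]] %||%
                     (seq_along(meta[["split_fractions"]]) - 1))
  } else {
    dose_schedule(0, dose)
  }

  obs <- tibble::tibble(day = tab$day, value = value_cells)
  if ("censored" %in% names(tab)) obs$censored <- as.logical(tab$censored)
  patient_record(
    id = meta[["id"]] %||% tools::file_path_sans_ext(basename(path)),
    observations = obs,
    schedule = schedule,
    detection_threshold = threshold,
    T0 = meta[["T0"]] %||% 1e7,
    followup_day = meta[["followup_day"]] %||% max(tab$day),
    outcome = meta[["outcome"]],
    disease = meta[["disease"]] %||% NA_character_
  )
}

#' Write a patient record to CSV (+ YAML sidecar)
#'
#' Inverse of [read_patient_table()] for records in absolute cells: writes
#' `day,value,censored` to `path` and, if `meta_path` is given, the
#' metadata as YAML.
#'
#' @param record A [patient_record()].
#' @param path Output CSV path.
#' @param meta_path Optional YAML sidecar path.
#' @return `path`, invisibly.
#' @export
write_patient_table <- function(record, path, meta_path = NULL) {
  utils::write.csv(as.data.frame(record$observations), path, row.names = FALSE)
  if (!is.null(meta_path)) {
    sched <- record$schedule
    meta <- list(id = record$id, disease = record$disease,
                 dose = sum(sched$cells),
                 detection_threshold = record$detection_threshold,
                 T0 = record$T0, followup_day = record$followup_day,
                 outcome = record$outcome)
    if (nrow(sched) > 1) {
      meta$split_fractions <- sched$cells / sum(sched$cells)
      meta$split_days <- sched$day
    }
    yaml::write_yaml(meta, meta_path)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full kinetics pipeline over a cohort
#'
#' For each patient: phase segmentation and slope seeding, least-squares
#' calibration, simulation under the fitted parameters, and the kinetic
#' outcome summary. Per-patient failures are caught, logged and skipped.
#' The cohort summary table holds, per patient, the coordinates used for
#' response stratification (28-day AUC and non-exhausted fraction) together
#' with peak, engraftment and relapse quantities.
#'
#' @param patients A list of [patient_record()]s or a `carkin_cohort`.
#' @param free Free parameter names for the fits.
#' @param init Base [carkin_params()] holding the fixed (study-design)
#'   constants; free starting values are refined per patient from the phase
#'   slopes. `NULL` uses the package defaults.
#' @param n_starts,seed,dt,outcome_weight Passed to [fit_patient()]; each
#'   patient gets a distinct deterministic sub-seed derived from `seed`.
#' @param horizons AUC horizons, days.
#' @param t_max Relapse search horizon, days (default 20000).
#' @return A list of class `carkin_pipeline`: `summary` (one tibble row per
#'   fitted patient), `fits` (named list of `carkin_fit`), `summaries`
#'   (named list of `carkin_summary`) and `failures` (named character
#'   vector of error messages).
#' @export
run_pipeline <- function(patients, free = c("beta", "p1", "delta", "mu"),
                         init = NULL, n_starts = 4, seed = 1L, dt = 0.01,
                         outcome_weight = 0, horizons = c(28, 60, 90),
                         t_max = 20000) {
  if (inherits(patients, "carkin_cohort")) patients <- patients$patients
  fits <- list(); summaries <- list(); failures <- character(0)
  rows <- list()
  for (i in seq_along(patients)) {
    rec <- patients[[i]]
    res <- tryCatch({
      fit <- fit_patient(rec, init = init, free = free, n_starts = n_starts,
                         seed = seed + i, dt = dt,
                         outcome_weight = outcome_weight,
                         seed_from_phases = TRUE)
      traj <- simulate_kinetics(fit$params, rec$schedule, T0 = rec$T0,
                                t_end = max(horizons, rec$followup_day,
                                            max(rec$observations$day)),
                                dt = dt, output_dt = 0.1)
      ks <- kinetic_summary(traj, threshold = rec$detection_threshold,
                            horizons = horizons, t_max = t_max)
      t_fu <- stats::approx(traj$time, traj$T, xout = rec$followup_day)$y
      list(fit = fit, ks = ks, row = tibble::tibble(
        id = rec$id,
        outcome = rec$outcome,
        predicted_outcome = classify_outcome(max(t_fu, 1e-30), rec$T0,
                                             rec$detection_threshold),
        loss = fit$loss,
        converged = fit$converged,
        auc0_28 = ks$auc$auc[ks$auc$horizon == 28 & ks$auc$phenotype == "total"],
        non_exhausted_28 = ks$non_exhausted$fraction[ks$non_exhausted$horizon == 28],
        t_peak = ks$peak$t_peak,
        C_peak = ks$peak$C_peak,
        peak_dose_ratio = ks$peak$peak_dose_ratio,
        EC = ks$EC,
        t_TR = ks$relapse$t_TR,
        relapse_reason = ks$relapse$reason
      ))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[rec$id] <- conditionMessage(res)
      message("patient ", rec$id, " failed: ", conditionMessage(res))
    } else {
      fits[[rec$id]] <- res$fit
      summaries[[rec$id]] <- res$ks
      rows[[rec$id]] <- res$row
    }
  }
  structure(list(
    summary = if (length(rows) > 0) dplyr::bind_rows(rows) else tibble::tibble(),
    fits = fits, summaries = summaries, failures = failures
  ), class = "carkin_pipeline")
}

#' @export
print.carkin_pipeline <- function(x, ...) {
  cat("<carkin_pipeline>", nrow(x$summary), "patients fitted,",
      length(x$failures), "failed\n")
  if (nrow(x$summary) > 0)
    print(x$summary[, c("id", "outcome", "predicted_outcome", "loss",
                        "auc0_28", "non_exhausted_28", "t_TR")])
  invisible(x)
}
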