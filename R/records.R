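#' Patient record
#'
#' Bundles a patient's CAR-T time course with the metadata needed for
#' calibration: dose schedule, detection threshold, initial tumor burden,
#' follow-up day and (optionally) the recorded therapy outcome.
#'
#' @param id Patient label.
#' @param observations Data frame with columns `day` (>= 0, sorted), `value`
#'   (total CAR-T cells) and optionally `censored` (set from the threshold
#'   when missing).
#' @param schedule A [dose_schedule()], a data frame, or a single total dose
#'   infused at day 0.
#' @param detection_threshold Assay detection threshold, cells (default
#'   2.5e6, the qPCR floor of 25 copies per microgram of DNA).
#' @param T0 Initial tumor burden, cells (default 1e7).
#' @param followup_day Day of the outcome assessment (default: last
#'   observation day).
#' @param outcome Optional label among `"CR"`, `"PR"`, `"SD"`, `"PD"`.
#' @param disease Optional disease label (e.g. ALL, CLL, DLBCL, MCL).
#' @return An object of class `carkin_patient`.
#' @export
patient_record <- function(id, observations, schedule,
                           detection_threshold = 2.5e6, T0 = 1e7,
                           followup_day = NULL, outcome = NULL,
                           disease = NA_character_) {
  obs <- tibble::as_tibble(observations)
  if (!all(c("day", "value") %in% names(obs)))
    stop("observations must have columns `day` and `value`")
  if (any(obs$day < 0)) stop("observation days must be >= 0")
  if (is.unsorted(obs$day)) obs <- dplyr::arrange(obs, .data$day)
  if (!"censored" %in% names(obs))
    obs$censored <- obs$value <= detection_threshold
  if (!is.logical(obs$censored)) obs$censored <- as.logical(obs$censored)
  if (!is.null(outcome) && !is.na(outcome) &&
      !outcome %in% c("CR", "PR", "SD", "PD"))
    stop("outcome must be one of CR, PR, SD, PD")
  if (is.null(followup_day)) followup_day <- max(obs$day)
  structure(list(
    id = as.character(id),
    disease = disease,
    schedule = as_schedule(schedule),
    observations = obs[, c("day", "value", "censored")],
    detection_threshold = detection_threshold,
    T0 = T0,
    followup_day = followup_day,
    outcome = if (is.null(outcome) || is.na(outcome)) NA_character_
              else as.character(outcome)
  ), class = "carkin_patient")
}

#' @export
print.carkin_patient <- function(x, ...) {
  cat("<carkin_patient> ", x$id,
      if (!is.na(x$disease)) paste0(" (", x$disease, ")"), "\n", sep = "")
  cat("  dose:", format(sum(x$schedule$cells), digits = 3), "cells in",
      nrow(x$schedule), "infusion(s)\n")
  cat("  observations:", nrow(x$observations), "days",
      format(min(x$observations$day)), "-", format(max(x$observations$day)),
      "(", sum(x$observations$censored), "censored )\n")
  cat("  threshold:", format(x$detection_threshold, digits = 3),
      "cells; T0:", format(x$T0, digits = 3),
      "; follow-up day", x$followup_day,
      if (!is.na(x$outcome)) paste0(" (", x$outcome, ")"), "\n")
  invisible(x)
}

true_params <- function(record) attr(record, "true_params")
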