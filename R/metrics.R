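trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

# trapezoid integral of column `col` over [0, horizon], interpolating the
# final partial interval when horizon falls between grid points
auc_column <- function(time, y, horizon) {
  if (horizon > max(time) + 1e-9)
    stop("horizon (", horizon, " d) beyond trajectory end (", max(time), " d)")
  inside <- time <= horizon + 1e-12
  x <- time[inside]; v <- y[inside]
  if (max(x) < horizon) {
    v <- c(v, stats::approx(time, y, xout = horizon)$y)
    x <- c(x, horizon)
  }
  trapz(x, v)
}

#' Per-phenotype area under the curve
#'
#' Trapezoidal integration of each CAR-T phenotype (and of the total `C`)
#' over `[0, horizon]` on the trajectory's output grid. The exposure over
#' the first 28 days (AUC 0-28) is the conventional early-response summary;
#' 60- and 90-day horizons probe later dynamics.
#'
#' @param traj A `carkin_trajectory` covering `[0, horizon]`.
#' @param horizon Upper integration limit, days (default 28).
#' @return A tibble with columns `phenotype` (`CD`, `CT`, `CM`, `CE`,
#'   `total`), `horizon` and `auc` (cell day).
#' @export
auc_by_phenotype <- function(traj, horizon = 28) {
  cols <- c("CD", "CT", "CM", "CE")
  aucs <- vapply(cols, function(cl) auc_column(traj$time, traj[[cl]], horizon),
                 numeric(1))
  total <- auc_column(traj$time, traj$C, horizon)
  tibble::tibble(
    phenotype = c(cols, "total"),
    horizon = horizon,
    auc = unname(c(aucs, total))
  )
}

#' Fraction of non-exhausted CAR-T cell exposure
#'
#' The share of the total CAR-T area under the curve contributed by the
#' non-exhausted phenotypes (distributed + effector + memory). Jointly with
#' the 28-day AUC this fraction separates complete responders (high
#' fraction) from stable-disease kinetics (fraction below ~0.8 with low
#' exposure).
#'
#' @param aucs A tibble as returned by [auc_by_phenotype()].
#' @return A single number in `[0, 1]`.
#' @export
non_exhausted_fraction <- function(aucs) {
  total <- aucs$auc[aucs$phenotype == "total"]
  if (length(total) != 1) stop("aucs must contain a single `total` row")
  if (total <= 0) stop("total AUC is zero: empty dynamics")
  unname(sum(aucs$auc[aucs$phenotype %in% c("CD", "CT", "CM")]) / total)
}

#' Peak expansion summary
#'
#' Locates the maximum of the total CAR-T population on the output grid
#' (earliest time on ties) and reports the phenotype composition there and
#' the expansion ratio `C(t_peak) / dose`.
#'
#' @param traj A `carkin_trajectory`.
#' @param dose Total infused cells (> 0); defaults to the trajectory's own
#'   schedule total when available.
#' @return A one-row tibble: `t_peak`, `C_peak`, `CD`, `CT`, `CM`, `CE` (at
#'   the peak) and `peak_dose_ratio`.
#' @export
peak_summary <- function(traj, dose = NULL) {
  if (is.null(dose)) {
    sched <- attr(traj, "schedule")
    if (is.null(sched) || nrow(sched) == 0)
      stop("dose not supplied and trajectory has no schedule")
    dose <- sum(sched$cells)
  }
  if (!is.finite(dose) || dose <= 0) stop("dose must be > 0")
  i <- which.max(traj$C)  # which.max returns the first (earliest) maximum
  tibble::tibble(
    t_peak = traj$time[i], C_peak = traj$C[i],
    CD = traj$CD[i], CT = traj$CT[i], CM = traj$CM[i], CE = traj$CE[i],
    peak_dose_ratio = traj$C[i] / dose
  )
}

# local maxima indices of a series (strict rise then fall)
local_maxima <- function(y) {
  n <- length(y)
  if (n < 3) return(integer(0))
  which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
}

#' Theoretical relapse time
#'
#' The model-predicted relapse is the first time, after the tumor burden has
#' fallen below the detection threshold, at which it crosses the threshold
#' upward again (linearly interpolated between grid points). Relapse is
#' reported as not applicable (`NA`) with a reason when
#' \itemize{
#'   \item the tumor never re-crosses the threshold within `t_max`
#'     (`"no_recurrence"`),
#'   \item the sub-threshold tumor settles on sustained oscillations -- at
#'     least three sub-threshold local maxima whose last three amplitudes
#'     stay within a factor 0.8--1.25 of each other (`"limit_cycle"`), or
#'   \item the tumor never falls below the threshold in the first place
#'     (`"no_remission"`, with a warning: relapse is undefined without
#'     remission).
#' }
#'
#' @param traj A `carkin_trajectory`; when it ends before `t_max` and
#'   carries its parameters, the simulation is extended automatically on a
#'   coarse grid.
#' @param threshold Tumor detection threshold, cells (> 0), default 2.5e6.
#' @param t_max Horizon for the relapse search, days (default 20000).
#' @return A one-row tibble: `t_TR` (days or `NA`), `reason` (`NA` when a
#'   relapse time exists), and the CAR-T composition `CD`, `CT`, `CM`, `CE`,
#'   `C` at relapse (all `NA` when not applicable).
#' @export
theoretical_relapse <- function(traj, threshold = 2.5e6, t_max = 20000) {
  if (!is.finite(threshold) || threshold <= 0)
    stop("threshold must be > 0")
  if (max(traj$time) < t_max) {
    kp <- attr(traj, "params")
    sched <- attr(traj, "schedule")
    if (!is.null(kp)) {
      traj <- simulate_kinetics(kp, sched, T0 = attr(traj, "T0"),
                                t_end = t_max, dt = attr(traj, "dt"),
                                output_dt = max(1, attr(traj, "output_dt")))
    } else {
      t_max <- max(traj$time)
    }
  }
  tt <- traj$time
  Tv <- traj$T
  na_row <- function(reason) tibble::tibble(
    t_TR = NA_real_, reason = reason, CD = NA_real_, CT = NA_real_,
    CM = NA_real_, CE = NA_real_, C = NA_real_)

  below <- which(Tv < threshold)
  if (length(below) == 0) {
    warning("tumor never falls below the detection threshold: ",
            "relapse time undefined (no remission)")
    return(na_row("no_remission"))
  }
  i0 <- below[1]
  # first upward crossing after remission
  after <- seq(i0, length(Tv) - 1)
  up <- after[Tv[after] < threshold & Tv[after + 1] >= threshold]
  if (length(up) > 0) {
    i <- up[1]
    w <- (threshold - Tv[i]) / (Tv[i + 1] - Tv[i])
    t_tr <- tt[i] + w * (tt[i + 1] - tt[i])
    comp <- vapply(c("CD", "CT", "CM", "CE", "C"), function(cl)
      traj[[cl]][i] + w * (traj[[cl]][i + 1] - traj[[cl]][i]), numeric(1))
    return(tibble::tibble(t_TR = t_tr, reason = NA_character_,
                          CD = comp[["CD"]], CT = comp[["CT"]],
                          CM = comp[["CM"]], CE = comp[["CE"]],
                          C = comp[["C"]]))
  }
  # no re-crossing: sustained sub-threshold oscillation vs. plain decay
  sub <- seq(i0, length(Tv))
  pk <- local_maxima(Tv[sub])
  if (length(pk) >= 3) {
    amp <- Tv[sub][utils::tail(pk, 3)]
    ratios <- amp[-1] / amp[-length(amp)]
    decaying <- all(diff(amp) < 0)
    if (!decaying && all(ratios >= 0.8 & ratios <= 1.25))
      return(na_row("limit_cycle"))
  }
  na_row("no_recurrence")
}

#' Classify therapy outcome from tumor burden at follow-up
#'
#' Complete response (CR): tumor below the detection threshold. Partial
#' response (PR): detectable but below 50% of the initial burden. Stable
#' disease (SD): within +/-50% of the initial burden. Progressive disease
#' (PD): more than 150% of the initial burden. Boundary values are assigned
#' to the less favorable class (half-open convention: `T = 0.5 T0` is SD,
#' `T = 1.5 T0` is SD, `T = threshold` is PR).
#'
#' @param T_followup Tumor burden at follow-up, cells (vectorized, > 0).
#' @param T0 Initial tumor burden, cells (default 1e7).
#' @param threshold Detection threshold, cells (default 2.5e6).
#' @return Character vector of labels among `"CR"`, `"PR"`, `"SD"`, `"PD"`.
#' @export
#' @examples
#' classify_outcome(c(1e6, 4e6, 1e7, 2e7)) # CR PR SD PD
classify_outcome <- function(T_followup, T0 = 1e7, threshold = 2.5e6) {
  if (any(!is.finite(T_followup)) || any(T_followup <= 0))
    stop("T_followup must be positive")
  if (T0 <= 0 || threshold <= 0) stop("T0 and threshold must be positive")
  dplyr::case_when(
    T_followup < threshold ~ "CR",
    T_followup < 0.5 * T0 ~ "PR",
    T_followup <= 1.5 * T0 ~ "SD",
    TRUE ~ "PD"
  )
}

#' Full kinetic outcome summary of a trajectory
#'
#' Computes the kinetic quantities used to characterize therapy response:
#' per-phenotype AUCs and non-exhausted fractions at the requested horizons,
#' the peak summary, the expected engrafted cells, and the theoretical
#' relapse time with the CAR-T composition at relapse.
#'
#' @param traj A `carkin_trajectory` (carrying parameters and schedule).
#' @param dose Total infused cells; defaults to the schedule total.
#' @param threshold Tumor detection threshold, cells.
#' @param horizons AUC horizons, days (default `c(28, 60, 90)`).
#' @param t_max Relapse search horizon, days.
#' @return A list of class `carkin_summary` with elements `auc` (tibble),
#'   `non_exhausted` (tibble: horizon, fraction), `peak` (tibble), `EC`
#'   (engrafted cells) and `relapse` (tibble).
#' @export
kinetic_summary <- function(traj, dose = NULL, threshold = 2.5e6,
                            horizons = c(28, 60, 90), t_max = 20000) {
  sched <- attr(traj, "schedule")
  if (is.null(dose)) dose <- sum(sched$cells)
  kp <- attr(traj, "params")
  auc <- dplyr::bind_rows(lapply(horizons, function(h) auc_by_phenotype(traj, h)))
  nef <- tibble::tibble(
    horizon = horizons,
    fraction = vapply(horizons, function(h)
      non_exhausted_fraction(auc[auc$horizon == h, ]), numeric(1))
  )
  structure(list(
    auc = auc,
    non_exhausted = nef,
    peak = peak_summary(traj, dose),
    EC = if (!is.null(kp)) engrafted_cells(kp, dose) else NA_real_,
    relapse = theoretical_relapse(traj, threshold, t_max)
  ), class = "carkin_summary")
}

#' @export
print.carkin_summary <- function(x, ...) {
  cat("<carkin_summary>\n")
  cat("  peak: C =", format(x$peak$C_peak, digits = 3), "cells at day",
      format(x$peak$t_peak, digits = 3),
      sprintf("(%.3g x dose)\n", x$peak$peak_dose_ratio))
  cat("  engrafted cells:", format(x$EC, digits = 3), "\n")
  for (i in seq_len(nrow(x$non_exhausted)))
    cat(sprintf("  AUC 0-%d: %.3g cell day, non-exhausted fraction %.3f\n",
                x$non_exhausted$horizon[i],
                x$auc$auc[x$auc$horizon == x$non_exhausted$horizon[i] &
                          x$auc$phenotype == "total"],
                x$non_exhausted$fraction[i]))
  if (is.na(x$relapse$t_TR)) {
    cat("  theoretical relapse: NA (", x$relapse$reason, ")\n", sep = "")
  } else {
    cat("  theoretical relapse at day", format(x$relapse$t_TR, digits = 4), "\n")
  }
  invisible(x)
}
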