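#' Default box constraints for patient-specific fitting
#'
#' Wide per-parameter intervals (searched in log10 space) covering the
#' physiological ranges of the rate constants.
#'
#' @return Named list of `c(lower, upper)` vectors.
#' @export
default_bounds <- function() {
  list(beta = c(0.05, 10), eta = c(1e-6, 0.1), r_min = c(1e-3, 1),
       p1 = c(0.05, 10), p2 = c(0.005, 1), p3 = c(0.5, 10),
       A = c(1e2, 1e8), a = c(1e4, 1e10), xi = c(0.05, 3),
       epsilon = c(1e-4, 0.5), lambda = c(1e-3, 3),
       theta = c(1e-13, 1e-8), alpha = c(1e-14, 1e-9),
       mu = c(1e-4, 0.5), delta = c(0.01, 3), r = c(1e-3, 0.5),
       b = c(1e-14, 1e-10), gamma = c(0.05, 10), vartheta = c(0.01, 100))
}

# simulate with output recorded exactly at the observation days (plus the
# follow-up day when within range), so the loss sees nodal values rather
# than interpolants
sim_for_record <- function(kp, record, dt, t_end = NULL) {
  if (is.null(t_end))
    t_end <- max(c(record$observations$day, record$schedule$day)) + 1
  out <- sort(unique(c(0, record$observations$day,
                       record$followup_day, t_end)))
  out <- out[out <= t_end]
  simulate_kinetics(kp, record$schedule, T0 = record$T0, t_end = t_end,
                    dt = dt, output_times = out)
}

#' Log-space least-squares loss against detectable observations
#'
#' Simulates the model under `kp` and returns the sum of squared residuals
#' between `log10` of the simulated total CAR-T count and `log10` of the
#' observed counts, over the uncensored observations only (values at or
#' below the detection threshold carry too much uncertainty and are
#' excluded, matching standard practice for qPCR counts). A simulated count
#' that is effectively zero at an observation day (below 1e-12 cells)
#' contributes a large finite penalty (the count is floored at 1e-30 cells
#' inside the logarithm, never an infinity) and flags the result.
#'
#' @param kp A [carkin_params()] object.
#' @param record A [patient_record()] with at least one uncensored
#'   observation.
#' @param dt Integration step, days (default 0.01).
#' @return The loss (dimensionless, >= 0), with attribute `flagged` set to
#'   `TRUE` when any model count was floored.
#' @export
residual_loss <- function(kp, record, dt = 0.01) {
  obs <- record$observations[!record$observations$censored, ]
  if (nrow(obs) == 0) stop("record has no uncensored observations")
  traj <- sim_for_record(kp, record, dt)
  model_c <- stats::approx(traj$time, traj$C, xout = obs$day)$y
  flagged <- any(model_c <= 1e-12)
  model_c <- pmax(model_c, 1e-30)
  loss <- sum((log10(model_c) - log10(obs$value))^2)
  attr(loss, "flagged") <- flagged
  loss
}

phase_seeded_init <- function(record, base, bounds) {
  est <- tryCatch({
    sl <- fit_phase_slopes(record$observations)
    slopes_to_estimates(sl, assumed_xi = base$xi)
  }, error = function(e) NULL, warning = function(w) {
    suppressWarnings(slopes_to_estimates(fit_phase_slopes(record$observations),
                                         assumed_xi = base$xi))
  })
  if (is.null(est)) return(base)
  clip <- function(x, nm) min(max(x, bounds[[nm]][1]), bounds[[nm]][2])
  upd <- list()
  g <- function(p) est$estimate[est$parameter == p]
  if (length(g("beta")) == 1) upd$beta <- clip(g("beta"), "beta")
  if (length(g("delta")) == 1) upd$delta <- clip(g("delta"), "delta")
  if (length(g("mu")) == 1) upd$mu <- clip(min(g("mu"), 0.9 * base$xi), "mu")
  if (length(g("p1_plus_r_min")) == 1)
    upd$p1 <- clip(g("p1_plus_r_min") - base$r_min, "p1")
  do.call(update_params, c(list(base), upd))
}

outcome_penalty <- function(T_fu, outcome, T0, threshold) {
  lo <- switch(outcome, CR = 0, PR = threshold, SD = 0.5 * T0, PD = 1.5 * T0)
  hi <- switch(outcome, CR = threshold, PR = 0.5 * T0, SD = 1.5 * T0, PD = Inf)
  T_fu <- max(T_fu, 1e-30)
  if (T_fu < lo) (log10(lo) - log10(T_fu))^2
  else if (T_fu > hi) (log10(T_fu) - log10(hi))^2
  else 0
}

#' Patient-specific parameter estimation
#'
#' Bounded multi-start local least squares in log10 parameter space against
#' a patient's detectable observations. The loss surface is multimodal, so
#' `n_starts` starting points are used: the supplied (or phase-seeded)
#' initial guess plus jittered copies (normal jitter, sd 0.25 dex, clipped
#' to bounds), each refined with a quasi-Newton box-constrained search
#' ([stats::nlminb()]). The best result is returned; its loss never exceeds
#' the loss of the initial guess. Results are deterministic given `seed`.
#'
#' When kinetic data cannot constrain the late dynamics, an optional
#' penalty (weight `outcome_weight`) pulls the simulated tumor burden at the
#' follow-up day into the band of the recorded outcome class.
#'
#' @param record A [patient_record()].
#' @param init Initial [carkin_params()]; when `NULL`, the package defaults
#'   are used as the base. Fixed (non-free) parameters keep the base values,
#'   so `init` is also where study-specific fixed constants (e.g. tumor
#'   growth and cytotoxicity from the literature) enter the fit.
#' @param seed_from_phases Refine the free starting values with the
#'   phase-slope estimates of the record (see [slopes_to_estimates()]);
#'   defaults to `TRUE` when `init` is not supplied.
#' @param free Character vector of parameter names to optimize (default
#'   `beta`, `p1`, `delta`, `mu` -- the slope-identified set).
#' @param bounds Named list of `c(lower, upper)` intervals (default
#'   [default_bounds()]).
#' @param n_starts Number of starts (default 4).
#' @param seed Integer seed controlling the start jitter.
#' @param dt Integration step for loss evaluations, days (default 0.01).
#' @param outcome_weight Weight of the outcome-band penalty (default 0:
#'   kinetic data only).
#' @return An object of class `carkin_fit`: fitted `params`, `loss`,
#'   `free`/`fixed` names, per-start diagnostics, convergence flag and
#'   goodness-of-fit table. Supports [tidy()], [glance()] and
#'   [ggplot2::autoplot()].
#' @export
fit_patient <- function(record, init = NULL, free = c("beta", "p1", "delta", "mu"),
                        bounds = default_bounds(), n_starts = 4, seed = 1L,
                        dt = 0.01, outcome_weight = 0,
                        seed_from_phases = is.null(init)) {
  stopifnot(inherits(record, "carkin_patient"))
  bad <- setdiff(free, par_order)
  if (length(bad) > 0) stop("unknown free parameters: ", paste(bad, collapse = ", "))
  base <- if (is.null(init)) carkin_params() else init
  if (seed_from_phases) base <- phase_seeded_init(record, base, bounds)
  validate_params(base)
  for (nm in free) {
    if (base[[nm]] < bounds[[nm]][1] || base[[nm]] > bounds[[nm]][2])
      stop("initial value of ", nm, " outside its bounds")
  }

  use_outcome <- outcome_weight > 0 && !is.na(record$outcome)
  t_need <- if (use_outcome)
    max(record$followup_day, max(record$observations$day)) + 1 else NULL

  objective <- function(lpar) {
    kp <- base
    kp[free] <- as.list(10^lpar)
    ok <- tryCatch({ validate_params(kp); TRUE }, error = function(e) FALSE)
    if (!ok) return(1e10)
    val <- tryCatch({
      if (use_outcome) {
        traj <- sim_for_record(kp, record, dt, t_end = t_need)
        obs <- record$observations[!record$observations$censored, ]
        mc <- pmax(stats::approx(traj$time, traj$C, xout = obs$day)$y, 1e-30)
        base_loss <- sum((log10(mc) - log10(obs$value))^2)
        t_fu <- stats::approx(traj$time, traj$T, xout = record$followup_day)$y
        base_loss + outcome_weight *
          outcome_penalty(t_fu, record$outcome, record$T0,
                          record$detection_threshold)
      } else {
        as.numeric(residual_loss(kp, record, dt))
      }
    }, error = function(e) 1e10)
    if (!is.finite(val)) 1e10 else val
  }

  lower <- log10(vapply(bounds[free], `[`, numeric(1), 1))
  upper <- log10(vapply(bounds[free], `[`, numeric(1), 2))
  start0 <- pmin(pmax(log10(unlist(base[free])), lower), upper)

  starts <- withr::with_seed(seed, {
    jit <- lapply(seq_len(max(0, n_starts - 1)), function(i)
      pmin(pmax(start0 + stats::rnorm(length(free), 0, 0.25), lower), upper))
    c(list(start0), jit)
  })

  runs <- purrr::map(starts, function(s) {
    res <- tryCatch(
      stats::nlminb(s, objective, lower = lower, upper = upper,
                    control = list(eval.max = 400, iter.max = 200)),
      error = function(e) list(par = s, objective = objective(s),
                               convergence = 1L, message = conditionMessage(e)))
    res
  })
  losses <- vapply(runs, function(r) r$objective, numeric(1))
  best <- runs[[which.min(losses)]]
  init_loss <- objective(start0)

  fitted <- base
  fitted[free] <- as.list(10^best$par)
  fitted <- structure(fitted[par_order], class = c("carkin_params", "list"))

  traj <- sim_for_record(fitted, record, dt,
                         t_end = max(record$followup_day,
                                     max(record$observations$day)) + 1)
  gof <- goodness_of_fit(record, traj)

  structure(list(
    params = fitted,
    loss = min(best$objective, init_loss),
    init = base,
    init_loss = init_loss,
    free = free,
    fixed = setdiff(par_order, free),
    converged = any(vapply(runs, function(r) isTRUE(r$convergence == 0), logical(1))),
    starts = tibble::tibble(
      start = seq_along(runs),
      loss = losses,
      convergence = vapply(runs, function(r) as.integer(r$convergence), integer(1))
    ),
    gof = gof,
    record = record,
    seed = as.integer(seed),
    dt = dt,
    outcome_weight = outcome_weight
  ), class = "carkin_fit")
}

#' Goodness of fit of a trajectory to a patient record
#'
#' @param record A [patient_record()] with at least one uncensored
#'   observation.
#' @param traj A `carkin_trajectory` covering the observation days.
#' @return A one-row tibble: `n_points` (uncensored count), `rmse_log10`
#'   (dex), `max_abs_log10` (dex) and `censored_consistency` (fraction of
#'   censored observations whose simulated count also lies at or below the
#'   threshold; `NA` when none are censored).
#' @export
goodness_of_fit <- function(record, traj) {
  obs <- record$observations
  unc <- obs[!obs$censored, ]
  if (nrow(unc) == 0) stop("record has no uncensored observations")
  mc <- pmax(stats::approx(traj$time, traj$C, xout = unc$day)$y, 1e-30)
  res <- log10(mc) - log10(unc$value)
  cen <- obs[obs$censored, ]
  consis <- if (nrow(cen) == 0) NA_real_ else {
    mcc <- stats::approx(traj$time, traj$C, xout = cen$day)$y
    mean(mcc <= record$detection_threshold)
  }
  tibble::tibble(
    n_points = nrow(unc),
    rmse_log10 = sqrt(mean(res^2)),
    max_abs_log10 = max(abs(res)),
    censored_consistency = consis
  )
}

#' @export
print.carkin_fit <- function(x, ...) {
  cat("<carkin_fit> patient", x$record$id, "\n")
  cat("  loss:", format(x$loss, digits = 5),
      "(init", format(x$init_loss, digits = 5), ")",
      if (x$converged) "converged" else "NOT converged", "\n")
  cat("  free:", paste(x$free, collapse = ", "), "\n")
  est <- unlist(x$params[x$free])
  cat(paste0("    ", format(names(est), width = 8), " ",
             format(est, digits = 4)), sep = "\n")
  cat("  rmse:", format(x$gof$rmse_log10, digits = 3), "dex over",
      x$gof$n_points, "points\n")
  invisible(x)
}

#' @describeIn fit_patient Tidy per-parameter table of a fit.
#' @param x A `carkin_fit` object.
#' @param ... Unused.
#' @method tidy carkin_fit
#' @export
tidy.carkin_fit <- function(x, ...) {
  tibble::tibble(
    term = par_order,
    estimate = unname(params_vector(x$params)),
    free = par_order %in% x$free
  )
}

#' @describeIn fit_patient One-row fit summary.
#' @method glance carkin_fit
#' @export
glance.carkin_fit <- function(x, ...) {
  tibble::tibble(
    loss = x$loss,
    converged = x$converged,
    n_starts = nrow(x$starts),
    n_points = x$gof$n_points,
    rmse_log10 = x$gof$rmse_log10,
    censored_consistency = x$gof$censored_consistency
  )
}
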