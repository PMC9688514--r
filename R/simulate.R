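#' Dose schedules
#'
#' `dose_schedule()` builds an impulsive dosing schedule; `split_schedule()`
#' builds the common 3-day fractionated regimen in which a total dose is
#' infused as 10%, 30% and 60% on days 0, 1 and 2.
#'
#' @param day Infusion days (strictly increasing, >= 0).
#' @param cells Cells infused at each day (> 0).
#' @param total Total dose for `split_schedule()`, cells.
#' @param fractions Dose fractions; a warning is raised (never silent
#'   renormalization) when they do not sum to 1.
#' @return A tibble with columns `day` and `cells`, class
#'   `carkin_schedule`.
#' @export
#' @examples
#' split_schedule(1e8)
dose_schedule <- function(day, cells) {
  if (length(day) != length(cells)) stop("day and cells lengths differ")
  if (length(day) > 0) {
    if (any(!is.finite(day)) || any(day < 0)) stop("days must be >= 0")
    if (is.unsorted(day, strictly = TRUE)) stop("days must be strictly increasing")
    if (any(!is.finite(cells)) || any(cells <= 0)) stop("cells must be > 0")
  }
  structure(tibble::tibble(day = as.numeric(day), cells = as.numeric(cells)),
            class = c("carkin_schedule", class(tibble::tibble())))
}

#' @rdname dose_schedule
#' @export
split_schedule <- function(total, fractions = c(0.10, 0.30, 0.60),
                           day = seq_along(fractions) - 1) {
  if (abs(sum(fractions) - 1) > 1e-8)
    warning("dose fractions sum to ", sum(fractions), ", not 1; ",
            "total infused will be ", sum(fractions), " * total")
  dose_schedule(day, total * fractions)
}

as_schedule <- function(schedule) {
  if (inherits(schedule, "carkin_schedule")) return(schedule)
  if (is.numeric(schedule) && length(schedule) == 1)
    return(dose_schedule(0, schedule))
  if (is.data.frame(schedule)) return(dose_schedule(schedule$day, schedule$cells))
  stop("schedule must be a carkin_schedule, a data frame, or a single dose")
}

#' Simulate the kinetic model
#'
#' Integrates the five-compartment system with the classical fixed-step
#' fourth-order Runge--Kutta method. Doses are added impulsively to the
#' distributed compartment at their scheduled days; all other CAR-T
#' phenotypes start at zero and the tumor starts at `T0`. The internal step
#' is `dt`; states are recorded on a sparser output grid (`output_dt`) so
#' long horizons stay memory-light.
#'
#' @param kp A [carkin_params()] object.
#' @param schedule A [dose_schedule()], a data frame with `day`/`cells`
#'   columns, a single total dose (infused at day 0), or `NULL` for an
#'   untreated control run.
#' @param T0 Initial tumor burden, cells (default 1e7).
#' @param t_end Final time, days (> 0).
#' @param dt Integration step, days (default 1e-3).
#' @param output_dt Output grid spacing, days (default 0.1).
#' @param output_times Optional explicit output times (sorted, within
#'   `[0, t_end]`), overriding the regular grid; states are recorded exactly
#'   at these integration nodes.
#' @return A tibble of class `carkin_trajectory` with columns `time`, `CD`,
#'   `CT`, `CM`, `CE`, `T`, `C` (total CAR-T) and `CF` (functional CAR-T),
#'   carrying the parameters, schedule and step sizes as attributes.
#' @export
#' @examples
#' traj <- simulate_kinetics(textbook_params(), 1e8, t_end = 90, dt = 0.01)
#' dplyr::slice_max(traj, C, n = 1)
simulate_kinetics <- function(kp, schedule = NULL, T0 = 1e7, t_end = 365,
                              dt = 1e-3, output_dt = 0.1,
                              output_times = NULL) {
  validate_params(kp)
  if (!is.finite(t_end) || t_end <= 0) stop("t_end must be > 0")
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0")
  if (!is.finite(T0) || T0 < 0) stop("T0 must be >= 0")
  sched <- if (is.null(schedule)) dose_schedule(numeric(0), numeric(0))
           else as_schedule(schedule)
  if (nrow(sched) > 0 && max(sched$day) > t_end)
    stop("dose scheduled after t_end")

  out_times <- if (is.null(output_times)) {
    unique(c(seq(0, t_end, by = output_dt), t_end))
  } else {
    ot <- sort(unique(as.numeric(output_times)))
    if (any(ot < 0) || any(ot > t_end))
      stop("output_times must lie within [0, t_end]")
    ot
  }
  res <- rk4_integrate(params_vector(kp), T0, t_end, dt, out_times,
                       sched$day, sched$cells)
  if (!res$ok)
    stop("integration produced non-finite state at t = ",
         format(res$first_bad_time),
         " days; reduce dt or check parameters")
  st <- res$states
  traj <- tibble::tibble(
    time = out_times,
    CD = st[, 1], CT = st[, 2], CM = st[, 3], CE = st[, 4], T = st[, 5]
  )
  traj$C <- traj$CD + traj$CT + traj$CM + traj$CE
  traj$CF <- traj$CD + traj$CT
  structure(traj,
            class = c("carkin_trajectory", class(tibble::tibble())),
            params = kp, schedule = sched, dt = dt, output_dt = output_dt,
            T0 = T0, worst_negative_rel = res$worst_negative_rel)
}

#' Per-capita rate of change of the total CAR-T population
#'
#' Computes `(1/C) dC/dt` by centered finite differences on the output grid
#' (one-sided at the ends). The sign pattern of this series diagnoses the
#' four kinetic phases: it is close to `-beta` while distribution dominates,
#' to `r_min + p1 - xi` during expansion, to `-delta` in the contraction and
#' to `-mu` in the persistence phase.
#'
#' @param traj A `carkin_trajectory`.
#' @return A tibble with columns `time` and `rate` (day^-1).
#' @export
per_capita_rate <- function(traj) {
  tt <- traj$time
  C <- traj$C
  if (any(C <= 0))
    stop("per-capita rate undefined: C = 0 in the evaluated range")
  n <- length(C)
  if (n < 3) stop("need at least 3 output points")
  rate <- numeric(n)
  rate[1] <- (C[2] - C[1]) / (tt[2] - tt[1]) / C[1]
  rate[n] <- (C[n] - C[n - 1]) / (tt[n] - tt[n - 1]) / C[n]
  rate[2:(n - 1)] <- (C[3:n] - C[1:(n - 2)]) /
    (tt[3:n] - tt[1:(n - 2)]) / C[2:(n - 1)]
  tibble::tibble(time = tt, rate = rate)
}

#' Export a trajectory as tidy CSV
#'
#' @param traj A `carkin_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}
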