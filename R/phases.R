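phase_names <- c("distribution", "expansion", "contraction", "persistence")

ols_log <- function(day, lv) {
  if (length(unique(day)) < 2)
    stop("degenerate phase fit: all observations at the same day")
  fit <- stats::lm(lv ~ day)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       se = unname(sqrt(diag(stats::vcov(fit)))[2]),
       sse = sum(stats::residuals(fit)^2))
}

prepare_series <- function(obs, values = c("cells", "log10_cells")) {
  values <- match.arg(values)
  obs <- tibble::as_tibble(obs)
  if (!all(c("day", "value") %in% names(obs)))
    stop("series must have columns `day` and `value`")
  if ("censored" %in% names(obs)) obs <- obs[!obs$censored, ]
  if (values == "log10_cells") obs$value <- 10^obs$value
  obs <- obs[is.finite(obs$value) & obs$value > 0, c("day", "value")]
  if (nrow(obs) == 0)
    stop("no usable observations (all censored or non-positive)")
  dplyr::arrange(obs, .data$day)
}

#' Segment a CAR-T time course into kinetic phases
#'
#' Splits a time course of total CAR-T counts into up to four contiguous
#' phases -- distribution, expansion, contraction, persistence -- on the
#' natural-log scale. The expansion/contraction boundary is the global
#' maximum of the log-counts (earliest point on ties); the
#' distribution/expansion boundary is the pre-peak minimum (the distribution
#' phase is flagged absent when that minimum is the first observation); the
#' contraction/persistence boundary is chosen to minimize the total residual
#' sum of squares of a two-segment log-linear fit over the post-peak points.
#' Boundary observations are shared by the adjacent phases. Phases with
#' fewer than two observations are flagged absent, as is the persistence
#' phase when the post-peak points are adequately described by a single
#' log-linear segment.
#'
#' @param obs Data frame with columns `day` and `value` (and optionally
#'   `censored`; censored rows are dropped). At least 4 positive values.
#' @param peak_hint Optional day near which the peak is to be located; the
#'   observation closest to it is used as the peak instead of the global
#'   argmax.
#' @param breakpoints Optional manual override: numeric vector of up to
#'   three interior boundary days `(b1, b2, b3)`, `NA` for absent
#'   boundaries, bypassing the automated scan.
#' @param values Either `"cells"` (default) or `"log10_cells"` when `value`
#'   holds log10-transformed counts.
#' @return An object of class `carkin_phases`: a tibble with one row per
#'   phase (`phase`, `start_day`, `end_day`, `n`, `present`) carrying the
#'   boundary days and the filtered series as attributes.
#' @export
#' @examples
#' traj <- simulate_kinetics(textbook_params(), 1e8, t_end = 120, dt = 0.01)
#' obs <- tibble::tibble(day = seq(0, 120, 2),
#'                       value = approx(traj$time, traj$C, seq(0, 120, 2))$y)
#' segment_phases(obs)
segment_phases <- function(obs, peak_hint = NULL, breakpoints = NULL,
                           values = c("cells", "log10_cells")) {
  ser <- prepare_series(obs, values)
  n <- nrow(ser)
  if (n < 4) stop("need at least 4 positive observations")
  day <- ser$day
  lv <- log(ser$value)

  if (!is.null(breakpoints)) {
    bp <- rep(NA_real_, 3)
    bp[seq_along(breakpoints)] <- breakpoints
    idx <- function(d) if (is.na(d)) NA_integer_ else which.min(abs(day - d))
    i_min <- idx(bp[1]); i_peak <- idx(bp[2]); i_b3 <- idx(bp[3])
    if (is.na(i_peak)) stop("manual breakpoints require the peak day (b2)")
    if (is.na(i_min)) i_min <- 1L
    seg_idx <- list(distribution = if (i_min > 1) c(1L, i_min),
                    expansion = if (i_peak > i_min) c(i_min, i_peak),
                    contraction = if (!is.na(i_b3)) c(i_peak, i_b3)
                                  else if (i_peak < n) c(i_peak, n),
                    persistence = if (!is.na(i_b3) && i_b3 < n) c(i_b3, n))
    return(build_phases(ser, seg_idx, c(bp[1], day[i_peak], bp[3])))
  }

  i_peak <- if (is.null(peak_hint)) which.max(lv)
            else which.min(abs(day - peak_hint))
  i_min <- which.min(lv[1:i_peak])

  seg_idx <- list(distribution = NULL, expansion = NULL,
                  contraction = NULL, persistence = NULL)
  if (i_min > 1) seg_idx$distribution <- c(1L, i_min)
  if (i_peak > i_min) seg_idx$expansion <- c(i_min, i_peak)

  b3 <- NA_real_
  n_post <- n - i_peak + 1
  if (n_post == 2) {
    seg_idx$contraction <- c(i_peak, n)
  } else if (n_post >= 3) {
    sse0 <- ols_log(day[i_peak:n], lv[i_peak:n])$sse
    ks <- seq(i_peak + 1L, n - 1L)
    fits <- lapply(ks, function(k) {
      f1 <- ols_log(day[i_peak:k], lv[i_peak:k])
      f2 <- ols_log(day[k:n], lv[k:n])
      list(sse = f1$sse + f2$sse, s1 = f1$slope, s2 = f2$slope)
    })
    best <- which.min(vapply(fits, `[[`, numeric(1), "sse"))
    one_segment <- sse0 <= 1e-10 * n_post ||
      abs(fits[[best]]$s1 - fits[[best]]$s2) <=
        0.02 * max(abs(fits[[best]]$s1), abs(fits[[best]]$s2))
    if (one_segment) {
      seg_idx$contraction <- c(i_peak, n)
    } else {
      k <- ks[best]
      seg_idx$contraction <- c(i_peak, k)
      seg_idx$persistence <- c(k, n)
      b3 <- day[k]
    }
  }
  build_phases(ser, seg_idx,
               c(if (i_min > 1) day[i_min] else NA_real_, day[i_peak], b3))
}

build_phases <- function(ser, seg_idx, boundaries) {
  rows <- purrr::map(phase_names, function(ph) {
    ix <- seg_idx[[ph]]
    present <- !is.null(ix) && (ix[2] - ix[1] + 1) >= 2
    tibble::tibble(
      phase = ph,
      start_day = if (present) ser$day[ix[1]] else NA_real_,
      end_day = if (present) ser$day[ix[2]] else NA_real_,
      n = if (present) ix[2] - ix[1] + 1L else 0L,
      present = present
    )
  })
  out <- dplyr::bind_rows(rows)
  structure(out,
            class = c("carkin_phases", class(tibble::tibble())),
            boundaries = boundaries, series = ser,
            indices = seg_idx)
}

#' Fit log-linear slopes within each kinetic phase
#'
#' Ordinary least squares of `ln(count)` against day within each present
#' phase. The four slopes are conventionally called `md` (distribution),
#' `me` (expansion), `mc` (contraction) and `mp` (persistence); when all
#' phases are present, `md < 0 < me`, `mc < 0`, `mp < 0` and `|mc| > |mp|`.
#'
#' @param obs Data frame with `day` and `value` columns (see
#'   [segment_phases()]); ignored if `seg` carries its own series.
#' @param seg A `carkin_phases` segmentation; computed from `obs` when
#'   omitted.
#' @param values Passed to [segment_phases()] when `seg` is omitted.
#' @return An object of class `carkin_slopes`: a tibble with columns
#'   `phase`, `slope` (natural-log units, day^-1; divide by `log(10)` for
#'   decades/day), `se`, `intercept`, `n` and `present`.
#' @export
fit_phase_slopes <- function(obs = NULL, seg = NULL,
                             values = c("cells", "log10_cells")) {
  if (is.null(seg)) seg <- segment_phases(obs, values = values)
  ser <- attr(seg, "series")
  idx <- attr(seg, "indices")
  rows <- purrr::map(phase_names, function(ph) {
    ix <- idx[[ph]]
    if (is.null(ix) || (ix[2] - ix[1] + 1) < 2) {
      return(tibble::tibble(phase = ph, slope = NA_real_, se = NA_real_,
                            intercept = NA_real_, n = 0L, present = FALSE))
    }
    rng <- ix[1]:ix[2]
    f <- ols_log(ser$day[rng], log(ser$value[rng]))
    tibble::tibble(phase = ph, slope = f$slope, se = f$se,
                   intercept = f$intercept, n = length(rng), present = TRUE)
  })
  structure(dplyr::bind_rows(rows),
            class = c("carkin_slopes", class(tibble::tibble())),
            segmentation = seg)
}

#' Extract the slope vector (md, me, mc, mp)
#'
#' @param slopes A `carkin_slopes` object.
#' @return Named numeric vector `c(md, me, mc, mp)` with `NA` for absent
#'   phases.
#' @export
slope_vector <- function(slopes) {
  stats::setNames(slopes$slope, c("md", "me", "mc", "mp"))
}

#' First-pass parameter estimates from phase slopes
#'
#' Maps the fitted phase slopes to the model parameters they approximate:
#' the distribution decline gives `beta = -md`; the expansion slope gives
#' the combination `p1 + r_min = me + xi` (the effector death rate `xi` is
#' not separately identifiable from the slope, so an assumed value must be
#' supplied); the contraction decline gives the exhausted-cell death rate
#' `delta = -mc`; the persistence decline gives the memory death rate
#' `mu = -mp`. Absent phases yield no estimate. Estimates violating the
#' model constraint `mu < xi` are returned unchanged with a warning, never
#' silently altered.
#'
#' @param slopes A `carkin_slopes` object (or anything [slope_vector()]
#'   accepts).
#' @param assumed_xi Assumed effector death rate, day^-1 (default 0.5).
#' @return A tibble with columns `parameter`, `estimate` and `from_slope`,
#'   one row per identifiable quantity; carries the attribute
#'   `violates_mu_lt_xi`.
#' @export
slopes_to_estimates <- function(slopes, assumed_xi = 0.5) {
  m <- slope_vector(slopes)
  if (all(is.na(m))) stop("no phase slope available")
  rows <- list()
  if (!is.na(m["md"]))
    rows <- c(rows, list(tibble::tibble(parameter = "beta",
                                        estimate = -m[["md"]],
                                        from_slope = "md")))
  if (!is.na(m["me"]))
    rows <- c(rows, list(tibble::tibble(parameter = "p1_plus_r_min",
                                        estimate = m[["me"]] + assumed_xi,
                                        from_slope = "me")))
  if (!is.na(m["mc"]))
    rows <- c(rows, list(tibble::tibble(parameter = "delta",
                                        estimate = -m[["mc"]],
                                        from_slope = "mc")))
  if (!is.na(m["mp"]))
    rows <- c(rows, list(tibble::tibble(parameter = "mu",
                                        estimate = -m[["mp"]],
                                        from_slope = "mp")))
  out <- dplyr::bind_rows(rows)
  violation <- FALSE
  mu_est <- out$estimate[out$parameter == "mu"]
  if (length(mu_est) == 1 && mu_est >= assumed_xi) {
    violation <- TRUE
    warning("estimated mu (", signif(mu_est, 3), ") >= assumed xi (",
            assumed_xi, "): violates mu < xi; returned unaltered")
  }
  attr(out, "violates_mu_lt_xi") <- violation
  out
}
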