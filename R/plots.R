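#' Plot a simulated trajectory
#'
#' Log10 time courses of the CAR-T phenotypes, the total population and the
#' tumor burden. Values below `floor` are not drawn.
#'
#' @param object A `carkin_trajectory`.
#' @param floor Smallest plotted count, cells (default 1).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot carkin_trajectory
#' @export
autoplot.carkin_trajectory <- function(object, floor = 1, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              cols = c("CD", "CT", "CM", "CE", "C", "T"),
                              names_to = "population", values_to = "cells")
  long <- long[long$cells >= floor, ]
  long$population <- factor(long$population,
                            levels = c("C", "CD", "CT", "CM", "CE", "T"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$cells,
                                     colour = .data$population)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "days after infusion", y = "cells",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a phase segmentation with its fitted slopes
#'
#' @param object A `carkin_slopes` object (from [fit_phase_slopes()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot carkin_slopes
#' @export
autoplot.carkin_slopes <- function(object, ...) {
  seg <- attr(object, "segmentation")
  ser <- attr(seg, "series")
  pres <- object[object$present, ]
  segs <- dplyr::mutate(
    dplyr::left_join(pres, tibble::as_tibble(seg), by = "phase"),
    y0 = exp(.data$intercept + .data$slope * .data$start_day),
    y1 = exp(.data$intercept + .data$slope * .data$end_day))
  ggplot2::ggplot(ser, ggplot2::aes(x = .data$day, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_segment(
      data = segs,
      ggplot2::aes(x = .data$start_day, xend = .data$end_day,
                   y = .data$y0, yend = .data$y1, colour = .data$phase),
      linewidth = 1) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "days after infusion", y = "CAR-T cells",
                  colour = "phase") +
    ggplot2::theme_minimal()
}

#' Plot a patient fit
#'
#' Observations (censored points open) over the fitted model curve.
#'
#' @param object A `carkin_fit`.
#' @param t_end Plot horizon, days (default: last observation day).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot carkin_fit
#' @export
autoplot.carkin_fit <- function(object, t_end = NULL, ...) {
  rec <- object$record
  if (is.null(t_end)) t_end <- max(rec$observations$day)
  traj <- simulate_kinetics(object$params, rec$schedule, T0 = rec$T0,
                            t_end = t_end, dt = object$dt, output_dt = 0.1)
  ggplot2::ggplot(rec$observations,
                  ggplot2::aes(x = .data$day, y = .data$value)) +
    ggplot2::geom_line(data = traj,
                       ggplot2::aes(x = .data$time, y = pmax(.data$C, 1)),
                       colour = "grey30") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$censored), size = 2) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1)) +
    ggplot2::geom_hline(yintercept = rec$detection_threshold,
                        linetype = "dashed", colour = "grey60") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "days after infusion", y = "total CAR-T cells",
                  title = rec$id) +
    ggplot2::theme_minimal()
}

#' Cohort response-stratification map
#'
#' Scatter of the 28-day AUC against the corresponding non-exhausted
#' fraction, one point per patient, colored by outcome -- the coordinate
#' pair that best separates complete responders, partial responders and
#' stable disease.
#'
#' @param summary A pipeline summary tibble (from [run_pipeline()]) with
#'   columns `auc0_28`, `non_exhausted_28` and `outcome`.
#' @return A ggplot object.
#' @export
plot_cohort_map <- function(summary) {
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = .data$auc0_28, y = .data$non_exhausted_28,
                               colour = .data$outcome)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "AUC 0-28 (cell day)",
                  y = "non-exhausted fraction (0-28 d)",
                  colour = "outcome") +
    ggplot2::theme_minimal()
}
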