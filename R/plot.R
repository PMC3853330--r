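#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a simulation time series
#'
#' Two panels: population counts (active Teff, active Treg, virus — the
#' model's predator-prey triplet) and damage (recoverable, unrecoverable,
#' total, in myelin units) against simulated time.
#'
#' @param object A `rrmsim_run`.
#' @param which `"both"`, `"populations"` or `"damage"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rrmsim_run <- function(object, which = c("both", "populations", "damage"),
                                ...) {
  which <- match.arg(which)
  ts <- object$timeseries
  ts$years <- ts$step / object$params$steps_per_year
  pops <- ts |>
    dplyr::select("years", "teff_active", "treg_active", "virus") |>
    tidyr::pivot_longer(-"years", names_to = "series", values_to = "count") |>
    dplyr::mutate(panel = "populations")
  dmg <- ts |>
    dplyr::select("years", "recoverable", "unrecoverable", "total") |>
    tidyr::pivot_longer(-"years", names_to = "series", values_to = "count") |>
    dplyr::mutate(panel = "damage (myelin units)")
  dat <- switch(which, both = dplyr::bind_rows(pops, dmg),
                populations = pops, damage = dmg)
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$years, y = .data$count,
                                         colour = .data$series)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c(
      teff_active = "red", treg_active = "blue", virus = "darkgreen",
      recoverable = "blue", unrecoverable = "red", total = "black")) +
    ggplot2::labs(x = "simulated years", y = NULL, colour = NULL,
                  title = sprintf("Virtual patient (seed %d)", object$seed)) +
    ggplot2::theme_minimal()
  if (which == "both")
    p <- p + ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y")
  p
}

#' Plot a spatial damage snapshot
#'
#' One tile per patch: intact tissue in light grey, recoverable damage in
#' dark grey, permanent lesions in black — the model's end-of-run spatial
#' plot.
#'
#' @param object A `rrmsim_snapshot` (see [snapshot()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rrmsim_snapshot <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$col, y = .data$row,
                                       fill = .data$category)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(intact = "grey85",
                                          recoverable = "grey40",
                                          unrecoverable = "black"),
                               drop = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "patch") +
    ggplot2::theme_minimal()
}

#' Plot cohort outcome distributions
#'
#' Empirical cumulative distributions of the per-patient final total damage;
#' with two cohorts the horizontal gap visualises the KS statistic separating
#' the arms.
#'
#' @param object A `rrmsim_cohort` or a `cohort_comparison`.
#' @param ... For a cohort: further `rrmsim_cohort`s to overlay.
#' @return A ggplot object.
#' @export
autoplot.rrmsim_cohort <- function(object, ...) {
  cohorts <- c(list(object), Filter(function(x) inherits(x, "rrmsim_cohort"),
                                    list(...)))
  dat <- dplyr::bind_rows(lapply(cohorts, function(ch) {
    tibble::tibble(scenario = attr(ch, "scenario") %||% "cohort",
                   final_total = ch$final_total)
  }))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$final_total,
                                    colour = .data$scenario)) +
    ggplot2::stat_ecdf(linewidth = 0.6) +
    ggplot2::labs(x = "final total damage (myelin units)", y = "ECDF",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.rrmsim_cohort
#' @export
autoplot.cohort_comparison <- function(object, ...) {
  autoplot.rrmsim_cohort(object$hill, object$healthy) +
    ggplot2::labs(subtitle = sprintf("KS D = %.4f", object$ks$statistic))
}

#' @importFrom rlang .data %||%
NULL
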