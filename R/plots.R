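# ggplot2 views of the fitted objects.

#' Plot a positional density as an event-by-position heat map
#'
#' The classic positional variance diagram: rows are events ordered by mean
#' posterior position, columns are sequence positions; a dark diagonal means
#' a confident ordering.
#'
#' @param object A `positional_density`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.positional_density <- function(object, ...) {
  df <- tidy.positional_density(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$event,
                                   fill = .data$density)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "grey10",
                                 limits = c(0, 1)) +
    ggplot2::scale_x_continuous(breaks = seq_len(ncol(object)),
                                expand = c(0, 0)) +
    ggplot2::labs(x = "Sequence position", y = NULL,
                  fill = "Posterior\ndensity") +
    ggplot2::theme_minimal()
}

#' Plot a fitted normal/abnormal mixture and its event posterior
#'
#' Component densities (solid) and the direction-constrained event posterior
#' (dashed, right axis in probability units).
#'
#' @param object A `kde_event_model`.
#' @param n_grid Curve resolution.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.kde_event_model <- function(object, n_grid = 512, ...) {
  rng <- range(object$centers)
  pad <- 3 * max(object$bandwidth_normal, object$bandwidth_abnormal)
  x <- seq(rng[1] - pad, rng[2] + pad, length.out = n_grid)
  dens <- component_density(object, x)
  post <- as.numeric(event_posterior(object, x))
  scale <- max(dens$f_event, dens$f_noevent)
  df <- tibble::tibble(
    x = rep(x, 2),
    density = c(dens$f_noevent, dens$f_event),
    component = rep(c("normal", "abnormal"), each = n_grid)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$density,
                                   colour = .data$component)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_line(
      data = tibble::tibble(x = x, density = post * scale,
                            component = "P(event | x)"),
      linetype = "dashed", colour = "grey25") +
    ggplot2::scale_colour_manual(
      values = c(normal = "#3B7DB8", abnormal = "#E08214")) +
    ggplot2::scale_y_continuous(
      sec.axis = ggplot2::sec_axis(~ . / scale, name = "P(event | x)")) +
    ggplot2::labs(title = object$feature, x = "Value", y = "Density",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier plot of the primary outcome by stratum and arm
#'
#' Step curves with Greenwood log-log confidence ribbons, faceted by
#' analysis stratum.
#'
#' @param object A `primary_outcome`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.primary_outcome <- function(object, ...) {
  km <- object$km
  # prepend the t = 0 point of each curve
  zero <- dplyr::distinct(km, .data$stratum, .data$arm)
  zero$time <- 0; zero$survival <- 1; zero$ci_low <- 1; zero$ci_high <- 1
  df <- dplyr::bind_rows(zero, km)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival,
                                   colour = .data$arm, fill = .data$arm)) +
    ggplot2::geom_step() +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high),
                         alpha = 0.15, colour = NA, stat = "identity") +
    ggplot2::facet_wrap(~stratum) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Months since randomization",
                  y = "Fraction not converted", colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Histogram of assigned model stages
#'
#' @param stages Tibble with a `stage` column (and optionally `diagnosis` or
#'   `subgroup` for fill).
#' @param threshold Optional stage threshold drawn as a dashed line; stages
#'   strictly beyond it are the late-stage subgroup.
#' @param fill Optional column name used as fill.
#' @return A ggplot.
#' @export
plot_stage_histogram <- function(stages, threshold = NULL, fill = NULL) {
  p <- ggplot2::ggplot(stages, ggplot2::aes(x = .data$stage))
  p <- if (!is.null(fill)) {
    p + ggplot2::geom_bar(ggplot2::aes(fill = .data[[fill]]),
                          position = "stack")
  } else {
    p + ggplot2::geom_bar(fill = "grey40")
  }
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_vline(xintercept = threshold + 0.5,
                                 linetype = "dashed", colour = "red")
  }
  p + ggplot2::labs(x = "Model stage", y = "Subjects") +
    ggplot2::theme_minimal()
}
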