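signal_labels <- c(
  pro = "Prochlorococcus (cells/L)",
  infected_pct = "infected cells (%)",
  virus = "free virions (/L)",
  grazer = "grazers (/L)"
)

night_shading <- function(t_min, t_max) {
  # night is 18:00-06:00 local, i.e. t mod 1 in [0.5, 1)
  days <- seq(floor(t_min), ceiling(t_max))
  shade <- tibble::tibble(
    xmin = pmax(days + 0.5, t_min),
    xmax = pmin(days + 1.0, t_max)
  )
  shade <- shade[shade$xmax > shade$xmin, ]
  ggplot2::geom_rect(
    data = shade,
    ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax),
    ymin = -Inf, ymax = Inf, fill = "grey85", alpha = 0.5,
    inherit.aes = FALSE
  )
}

#' Plot a simulated trajectory
#'
#' Four stacked panels (one per observable signal) with night-time shading.
#'
#' @param object A `pd_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pd_trajectory <- function(object, ...) {
  long <- observe_long(object)
  long$signal <- factor(long$signal, levels = SIGNALS)
  ggplot2::ggplot(long, ggplot2::aes(.data$time_days, .data$value)) +
    night_shading(min(long$time_days), max(long$time_days)) +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::facet_wrap(~signal,
      ncol = 1, scales = "free_y",
      labeller = ggplot2::as_labeller(signal_labels)
    ) +
    ggplot2::labs(x = "time (days since 06:00, day 0)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an observation set
#'
#' @param object A `pd_obs`.
#' @param model Optional model series in the same long format (e.g. a
#'   retrended posterior-median simulation) drawn as a line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pd_obs <- function(object, model = NULL, ...) {
  df <- as_tibble(object)
  df$signal <- factor(df$signal, levels = SIGNALS)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time_days, .data$value)) +
    night_shading(min(df$time_days), max(df$time_days)) +
    ggplot2::geom_point(size = 0.5, colour = "grey30")
  if (!is.null(model)) {
    mdf <- as_tibble(model)
    mdf$signal <- factor(mdf$signal, levels = SIGNALS)
    p <- p + ggplot2::geom_line(data = mdf, colour = "#b2182b")
  }
  p +
    ggplot2::facet_wrap(~signal,
      ncol = 1, scales = "free_y",
      labeller = ggplot2::as_labeller(signal_labels)
    ) +
    ggplot2::labs(x = "time (days since 06:00, day 0)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot posterior distributions
#'
#' Density of each sampled quantity with the median and central 95%
#' interval marked.
#'
#' @param object A `pd_fit`.
#' @param parameters Subset of parameter names (default: the free
#'   life-history parameters).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pd_fit <- function(object, parameters = object$free, ...) {
  draws <- as_tibble(as.data.frame(object$draws[, parameters, drop = FALSE]))
  long <- tidyr::pivot_longer(draws, dplyr::everything(),
    names_to = "parameter", values_to = "value"
  )
  sm <- object$summary[object$summary$parameter %in% parameters, ]
  ggplot2::ggplot(long, ggplot2::aes(.data$value)) +
    ggplot2::geom_density(fill = "#92c5de", alpha = 0.6) +
    ggplot2::geom_vline(
      data = sm,
      ggplot2::aes(xintercept = .data$median), colour = "#b2182b"
    ) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = NULL, y = "posterior density") +
    ggplot2::theme_minimal()
}

#' Plot the posterior mortality partition
#'
#' Distribution of the mortality fractions (lysis, grazing, other) over
#' posterior draws.
#'
#' @param object A `pd_partition_post`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pd_partition_post <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$draws[, c("f_lysis", "f_grazing", "f_other")],
    dplyr::everything(),
    names_to = "component", values_to = "fraction"
  )
  long$component <- factor(long$component,
    levels = c("f_lysis", "f_grazing", "f_other"),
    labels = c("viral lysis", "grazing", "other")
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$fraction, .data$component)) +
    ggplot2::geom_boxplot(fill = "#92c5de", outlier.size = 0.3) +
    ggplot2::scale_x_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(
      x = "share of total mortality", y = NULL,
      title = sprintf("gamma = %g", object$gamma)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a single-parameter sensitivity sweep
#'
#' Total daily mortality and lysis:grazing ratio against the multiplier,
#' one colour per parameter; non-coexisting points are dropped.
#'
#' @param object A `pd_sweep` (rows from one or more [sweep_single()]
#'   calls).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pd_sweep <- function(object, ...) {
  df <- as_tibble(object)
  df <- df[df$coexistence, c(
    "parameter", "multiplier", "m_total_daily",
    "lysis_to_grazing"
  )]
  long <- tidyr::pivot_longer(df, c("m_total_daily", "lysis_to_grazing"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$multiplier, .data$value,
    colour = .data$parameter
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "multiplier on baseline", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an adsorption-clearance covariation grid
#'
#' Heatmap of the chosen metric over the two multiplier axes; extinct
#' cells are blanked (shown in white).
#'
#' @param object A `pd_grid`.
#' @param metric `"lysis_to_grazing"` or `"m_total_daily"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pd_grid <- function(object,
                             metric = c("lysis_to_grazing", "m_total_daily"),
                             ...) {
  metric <- match.arg(metric)
  df <- as_tibble(object)
  df$z <- log10(df[[metric]])
  df$z[df$extinct] <- NA
  ggplot2::ggplot(df, ggplot2::aes(.data$phi_multiplier,
    .data$psi_multiplier,
    fill = .data$z
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_viridis_c(na.value = "white") +
    ggplot2::labs(
      x = "adsorption multiplier", y = "clearance multiplier",
      fill = paste0("log10 ", metric)
    ) +
    ggplot2::theme_minimal()
}
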