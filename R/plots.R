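#' Plot region HbO time series
#'
#' One facetted trace per region with task blocks shaded.
#'
#' @param object A `region_series`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.region_series <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"time",
                              names_to = "region", values_to = "hbo")
  long$region <- factor(long$region, levels = REGIONS)
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$hbo))
  par <- attr(object, "paradigm")
  if (!is.null(par)) {
    tasks <- as.data.frame(par[par$condition == "task", ])
    p <- p + ggplot2::geom_rect(
      data = tasks,
      ggplot2::aes(xmin = .data$onset, xmax = .data$onset + .data$duration),
      ymin = -Inf, ymax = Inf, fill = "grey85", inherit.aes = FALSE
    )
  }
  p +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$region)) +
    ggplot2::labs(x = "Time (s)", y = expression(Delta * "HbO (" * mu * "M)"))
}

#' Plot WCO/WPCO versus frequency
#'
#' Time-averaged coherence profiles on a log-frequency axis with the
#' five physiological bands shaded.
#'
#' @param object A `coherence_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.coherence_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("frequency", "wco", "wpco")],
    -"frequency", names_to = "metric", values_to = "value"
  )
  bands <- physiological_bands()
  ggplot2::ggplot(long, ggplot2::aes(x = .data$frequency, y = .data$value)) +
    ggplot2::geom_rect(
      data = dplyr::mutate(
        bands, shade = rep(c("grey95", "grey88"), length.out = dplyr::n())
      ),
      ggplot2::aes(xmin = .data$f_low, xmax = .data$f_high,
                   fill = .data$shade),
      ymin = -Inf, ymax = Inf, inherit.aes = FALSE, show.legend = FALSE
    ) +
    ggplot2::scale_fill_identity() +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), ncol = 1,
                        labeller = ggplot2::as_labeller(toupper)) +
    ggplot2::scale_x_log10() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Frequency (Hz)", y = "Coherence",
                  title = attr(object, "pair"))
}

#' Plot a time-frequency coherence map
#'
#' @param object A `coherence_map` from [timefreq_coherence_map()];
#'   values outside the cone of influence are blank.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.coherence_map <- function(object, ...) {
  df <- expand.grid(frequency = object$frequency, time = object$time)
  df$coherence <- as.vector(object$coherence)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$frequency,
                                   fill = .data$coherence)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "white") +
    ggplot2::labs(x = "Time (s)", y = "Frequency (Hz)", fill = "WCO")
}

#' Plot cohort connectivity by pair and group
#'
#' Mean band-averaged metric per pair with 95% CI error bars, by
#' group.
#'
#' @param long Long connectivity tibble from [bind_connectivity()].
#' @param metric `"wpco"` or `"wco"`.
#' @return A ggplot.
#' @export
plot_connectivity <- function(long, metric = c("wpco", "wco")) {
  metric <- match.arg(metric)
  summ <- long |>
    dplyr::group_by(.data$pair, .data$group) |>
    dplyr::summarise(
      mean = mean(.data[[metric]]),
      ci = ifelse(dplyr::n() > 1,
                  qt(0.975, dplyr::n() - 1) * sd(.data[[metric]]) /
                    sqrt(dplyr::n()), 0),
      .groups = "drop"
    )
  summ$pair <- factor(summ$pair, levels = region_pairs()$pair)
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$pair, y = .data$mean,
                                     fill = .data$group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$ci, ymax = .data$mean + .data$ci),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25
    ) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = toupper(metric)) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
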