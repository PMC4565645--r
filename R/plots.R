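# Standard figures of the analysis: group-mean bars with bootstrap CIs,
# memory scatter plots with the fitted one-lag line, predicted-vs-empirical
# CDF overlays, and the geographic bubble map of predicted changes.

#' Bar plot of group means over census years
#'
#' One panel per indicator; bars are the mean scale-adjusted metric of the
#' above- and below-law groups per year with bootstrap CI whiskers.
#' Optionally overlays predicted group means as grey bars.
#'
#' @param summary a [group_summary()] tibble.
#' @param predicted optional second summary tibble (e.g. of forecasts),
#'   drawn in grey.
#' @return a ggplot object.
#' @export
plot_group_means <- function(summary, predicted = NULL) {
  summary$year <- factor(summary$year)
  p <- ggplot2::ggplot(summary,
                       ggplot2::aes(x = .data$year, y = .data$mean_D,
                                    fill = .data$year)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low,
                                        ymax = .data$ci_high), width = 0.25) +
    ggplot2::facet_grid(group ~ indicator, scales = "free_y") +
    ggplot2::labs(x = "census year", y = "mean scale-adjusted metric D") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none",
                   axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (!is.null(predicted)) {
    predicted$year <- factor(predicted$year)
    p <- p + ggplot2::geom_col(data = predicted, fill = "grey60", alpha = 0.8) +
      ggplot2::geom_errorbar(data = predicted,
                             ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high), width = 0.25)
  }
  p
}

#' Scatter plot of a memory fit
#'
#' D at the later census against D at the earlier one, with the fitted
#' one-lag line and the identity for reference.
#'
#' @param fit a `memory_fit`.
#' @return a ggplot object.
#' @export
plot_memory_scatter <- function(fit) {
  stopifnot(inherits(fit, "memory_fit"))
  lab <- sprintf("%s: alpha = %.3f (SE %.3f), rho = %.2f",
                 fit$indicator, fit$slope, fit$se_slope, fit$rho)
  ggplot2::ggplot(fit$data, ggplot2::aes(x = .data$d_t, y = .data$d_t1)) +
    ggplot2::geom_point(alpha = 0.3, colour = "purple4") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_abline(slope = fit$slope, intercept = fit$intercept,
                         linetype = "dashed", colour = "black") +
    ggplot2::labs(title = lab,
                  x = sprintf("D(%d)", fit$year_pair[1]),
                  y = sprintf("D(%d)", fit$year_pair[2])) +
    ggplot2::theme_minimal()
}

#' Overlay of empirical and predicted CDFs of the scale-adjusted metric
#'
#' @param predicted,empirical metric tables sharing (city, indicator, year)
#'   keys.
#' @return a ggplot object, one panel per indicator.
#' @export
plot_cdf_overlay <- function(predicted, empirical) {
  both <- dplyr::bind_rows(
    dplyr::mutate(predicted, source = "predicted"),
    dplyr::mutate(empirical, source = "empirical")
  )
  ggplot2::ggplot(both, ggplot2::aes(x = .data$D, colour = .data$source)) +
    ggplot2::stat_ecdf() +
    ggplot2::facet_wrap(~indicator, scales = "free_x") +
    ggplot2::scale_colour_manual(values = c(empirical = "steelblue",
                                            predicted = "black")) +
    ggplot2::labs(x = "scale-adjusted metric D", y = "CDF") +
    ggplot2::theme_minimal()
}

#' Per-city change in the scale-adjusted metric between two tables
#'
#' @param predicted,empirical metric tables; joined per (city_id, indicator).
#' @return tibble `city_id`, `indicator`, `delta` (= predicted - empirical).
#' @export
sami_changes <- function(predicted, empirical) {
  m <- dplyr::inner_join(predicted, empirical, by = c("city_id", "indicator"),
                         suffix = c("_pred", "_emp"))
  tibble(city_id = m$city_id, indicator = m$indicator,
         delta = m$D_pred - m$D_emp)
}

#' Bubble map of predicted changes
#'
#' Draws one circle per city at its coordinates. The radius is proportional
#' to |delta|; the fill uses a diverging two-hue scale — shades of azure for
#' an expected decrease, shades of red for an expected increase, darker for
#' larger absolute change. Optionally also writes the same layer as GeoJSON.
#'
#' @param changes tibble `city_id`, `delta` (optionally `indicator`, which
#'   facets the map).
#' @param coords coordinate table ([read_coordinates()]).
#' @param geojson_path optional path; when given, [write_change_geojson()]
#'   is called per the full change set.
#' @param scale radius multiplier passed to the GeoJSON writer.
#' @return a ggplot object.
#' @export
render_change_map <- function(changes, coords, geojson_path = NULL, scale = 1) {
  m <- dplyr::inner_join(changes, coords, by = "city_id")
  if (!is.null(geojson_path)) {
    write_change_geojson(changes[c("city_id", "delta")] |>
                           dplyr::distinct(.data$city_id, .keep_all = TRUE),
                         coords, geojson_path, scale = scale)
  }
  rng <- max(abs(m$delta), 0)
  p <- ggplot2::ggplot(m, ggplot2::aes(x = .data$longitude, y = .data$latitude,
                                       size = abs(.data$delta),
                                       fill = .data$delta)) +
    ggplot2::geom_point(shape = 21, colour = "grey30", alpha = 0.8) +
    ggplot2::scale_fill_gradient2(low = "deepskyblue4", mid = "white",
                                  high = "darkred", midpoint = 0,
                                  limits = if (rng > 0) c(-rng, rng) else NULL) +
    ggplot2::scale_size_area(max_size = 4) +
    ggplot2::coord_quickmap() +
    ggplot2::labs(x = "longitude", y = "latitude",
                  fill = "predicted change", size = "|change|") +
    ggplot2::theme_minimal()
  if ("indicator" %in% names(m)) p <- p + ggplot2::facet_wrap(~indicator)
  p
}
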