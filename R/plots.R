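#' Plot a ratio trace
#'
#' @param object A `ratio_trace` tibble.
#' @param channels Also show the two raw channels (rescaled) when `TRUE`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ratio_trace
#' @export
autoplot.ratio_trace <- function(object, channels = FALSE, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$ratio)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::labs(x = "time (s)", y = "Fluo4 / FuraRed ratio")
  if (channels) {
    long <- tidyr::pivot_longer(object, c("fluo4", "furared"),
                                names_to = "channel", values_to = "intensity")
    long <- dplyr::group_by(long, .data$channel)
    long <- dplyr::mutate(long, intensity = .data$intensity / max(.data$intensity))
    p <- p + ggplot2::geom_line(
      data = long,
      ggplot2::aes(y = .data$intensity * max(object$ratio),
                   colour = .data$channel),
      alpha = 0.5
    )
  }
  p
}

#' Dose-response plot with fitted curves
#'
#' Per-concentration observations with the first-order decay and/or
#' Michaelis-Menten fit overlaid.
#'
#' @param series Concentration-series tibble (`concentration_ng_ml`,
#'   `dwell_s`).
#' @param decay A `decay_fit` (optional).
#' @param mm An `mm_fit` (optional).
#' @return A ggplot.
#' @export
plot_dose_response <- function(series, decay = NULL, mm = NULL) {
  series <- as_tibble(series)
  grid <- tibble(concentration_ng_ml = seq(min(series$concentration_ng_ml),
                                           max(series$concentration_ng_ml),
                                           length.out = 200))
  p <- ggplot2::ggplot(series, ggplot2::aes(x = .data$concentration_ng_ml,
                                            y = .data$dwell_s)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::stat_summary(fun = mean, geom = "point", size = 3,
                          colour = "#d95f02") +
    ggplot2::labs(x = "concentration (ng/ml)", y = "dwell time (s)")
  if (!is.null(decay) && isTRUE(decay$converged)) {
    grid$decay <- decay$y0 + decay$A1 * exp(-grid$concentration_ng_ml / decay$t1)
    p <- p + ggplot2::geom_line(data = grid,
                                ggplot2::aes(y = .data$decay),
                                colour = "#7570b3")
  }
  if (!is.null(mm) && isTRUE(mm$converged)) {
    grid$mm <- mm$dt_max * grid$concentration_ng_ml /
      (mm$k_half + grid$concentration_ng_ml)
    p <- p + ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$mm),
                                colour = "#1b9e77")
  }
  p
}

#' Box plot of per-cell colocalization by group
#'
#' @param records [per_cell_coloc()] records for one or more groups.
#' @return A ggplot.
#' @export
plot_coloc <- function(records) {
  ggplot2::ggplot(as_tibble(records),
                  ggplot2::aes(x = .data$group, y = .data$pearson_r)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5) +
    ggplot2::labs(x = NULL, y = "Pearson colocalization coefficient")
}
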