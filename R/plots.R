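# ggplot2 views of the three analyses.

#' Plot the attenuation histogram with the fitted mixture
#'
#' @param model an [fit_attenuation_model()] result.
#' @param values the HU samples the model was fitted to.
#' @param binwidth histogram bin width (HU).
#' @return A ggplot object: density histogram with the three weighted
#'   component curves and their sum.
#' @export
plot_attenuation_fit <- function(model, values, binwidth = 5) {
  cm <- model$components
  grid <- seq(min(values), max(values), length.out = 512)
  curves <- do.call(rbind, lapply(seq_len(nrow(cm)), function(k)
    data.frame(hu = grid, density = cm$weight[k] *
                 dnorm(grid, cm$mean[k], cm$sd[k]),
               component = cm$label[k])))
  total <- data.frame(hu = grid,
                      density = colSums(vapply(seq_len(nrow(cm)), function(k)
                        cm$weight[k] * dnorm(grid, cm$mean[k], cm$sd[k]),
                        numeric(length(grid)))))
  ggplot2::ggplot(data.frame(hu = values), ggplot2::aes(x = .data$hu)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            binwidth = binwidth, fill = "grey85",
                            colour = NA) +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(y = .data$density,
                                    colour = .data$component)) +
    ggplot2::geom_line(data = total, ggplot2::aes(y = .data$density),
                       linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(oligemic = "#2c7fb8",
                                            normal = "#fdae61",
                                            hyperemic = "#d7191c")) +
    ggplot2::labs(x = "Attenuation (HU)", y = "Density",
                  title = "Three-compartment attenuation mixture")
}

#' Plot a radial attenuation profile with its linear fit
#'
#' @param profile a [radial_profile()].
#' @param fit optional [fit_slope()] result (computed if missing).
#' @return A ggplot object: shell means against relative hilum-to-pleura
#'   distance with the fitted line.
#' @export
plot_radial_profile <- function(profile, fit = NULL) {
  if (is.null(fit)) fit <- fit_slope(profile)
  sub <- profile[profile$n_voxels > 0, ]
  ggplot2::ggplot(sub, ggplot2::aes(x = .data$bin_center, y = .data$mean_hu)) +
    ggplot2::geom_point(shape = 4) +
    ggplot2::geom_abline(intercept = fit$intercept, slope = fit$slope,
                         colour = "red") +
    ggplot2::labs(x = "Relative distance hilum → pleura",
                  y = "Mean attenuation (HU)",
                  title = sprintf("Centralization slope %.1f HU/unit (R² = %.2f)",
                                  fit$slope, fit$r2))
}

#' Correlation heatmap with non-significant cells masked
#'
#' Mirrors the reporting convention of showing only coefficients that survive
#' the FDR correction.
#'
#' @param report a [correlation_report()].
#' @return A ggplot tile plot; cells not significant after BH are blank.
#' @export
plot_correlation_heatmap <- function(report) {
  df <- as.data.frame(report)
  df$rho_shown <- ifelse(df$significant, df$rho, NA_real_)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$variable, y = .data$metric,
                                   fill = .data$rho_shown)) +
    ggplot2::geom_tile(colour = "grey70") +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data$rho_shown), "",
                     sprintf("%.2f", .data$rho_shown))), size = 3) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = c(-1, 1),
                                  na.value = "grey95", name = "ρ") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Spearman correlations (critical p = %.4g)",
                                  attr(report, "critical_p"))) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
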