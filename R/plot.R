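#' Plot a median spectrum
#'
#' Line plot of the median PSD (dB re 1 uPa^2/Hz) against frequency, with
#' the band's peak-search window shaded and the extracted peak marked.
#'
#' @param object a `reefpam_median_spectrum`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.reefpam_median_spectrum <- function(object, ...) {
  df <- tibble(freq = object$freqs, psd = object$median_psd_db)
  pk <- extract_band_features(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$freq, y = .data$psd)) +
    ggplot2::annotate("rect", xmin = object$band$f_lo, xmax = object$band$f_hi,
                      ymin = -Inf, ymax = Inf, alpha = 0.08) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = tibble(freq = pk$gamma_fpeak_hz,
                                      psd = pk$psd_fpeak_db),
                        colour = "red", size = 2) +
    ggplot2::labs(
      x = "Frequency (Hz)",
      y = expression("Median PSD (dB re 1 " * mu * "Pa"^2 * " Hz"^-1 * ")"),
      title = sprintf("%s | %s | %s band (%d frames)", object$site,
                      object$period, object$band$name, object$n_frames)
    ) +
    ggplot2::theme_minimal()
}

#' Violin plots of a soundscape feature
#'
#' The standard visualization for comparing peak levels between groups:
#' violins with inset boxplots per group, faceted by band and diel period.
#'
#' @param features a feature table.
#' @param response response column (default `psd_fpeak_db`).
#' @param group grouping column (`"year"` or `"protection"`).
#' @return A ggplot object.
#' @export
plot_feature_violin <- function(features, response = "psd_fpeak_db",
                                group = "protection") {
  ggplot2::ggplot(features, ggplot2::aes(x = .data[[group]],
                                         y = .data[[response]],
                                         fill = .data[[group]])) +
    ggplot2::geom_violin(alpha = 0.6) +
    ggplot2::geom_boxplot(width = 0.15, outlier.shape = NA, fill = "white") +
    ggplot2::facet_grid(band ~ period, scales = "free_y") +
    ggplot2::labs(x = NULL, y = response) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Ordination biplot of a CCA result
#'
#' Sites, taxa and constraint arrows on the first two constrained axes.
#'
#' @param object a `reefpam_cca`.
#' @param groups optional site group labels for colouring.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.reefpam_cca <- function(object, groups = NULL, ...) {
  s <- as.data.frame(object$site_scores)
  if (ncol(s) < 2) abort("need at least two ordination axes to plot")
  names(s)[1:2] <- c("a1", "a2")
  s$site <- rownames(object$site_scores)
  s$group <- if (is.null(groups)) "site" else as.character(groups)
  sp <- as.data.frame(object$species_scores)
  names(sp)[1:2] <- c("a1", "a2")
  bp <- as.data.frame(object$biplot_scores)
  names(bp)[1:2] <- c("a1", "a2")
  bp$label <- rownames(object$biplot_scores)
  mult <- max(abs(s[, 1:2])) * 0.9
  ggplot2::ggplot(s, ggplot2::aes(x = .data$a1, y = .data$a2)) +
    ggplot2::geom_point(data = sp, shape = 3, colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$group), size = 2) +
    ggplot2::geom_segment(data = bp,
                          ggplot2::aes(x = 0, y = 0, xend = .data$a1 * mult,
                                       yend = .data$a2 * mult),
                          arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
                          colour = "blue") +
    ggplot2::geom_text(data = bp, ggplot2::aes(x = .data$a1 * mult,
                                               y = .data$a2 * mult,
                                               label = .data$label),
                       colour = "blue", vjust = -0.5, size = 3) +
    ggplot2::labs(x = "CCA1", y = "CCA2") +
    ggplot2::theme_minimal()
}
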