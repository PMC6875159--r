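#' Plot a separation histogram
#'
#' Bar chart of the fraction of pairs per separation bin, with the
#' touching bin (separation <= 0) drawn in its own color at the left.
#'
#' @param object A [separation_histogram()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot separation_histogram
#' @export
autoplot.separation_histogram <- function(object, ...) {
  bw <- attr(object, "bin_width") %||% 0.05
  df <- tibble::as_tibble(unclass(object))
  df$x <- ifelse(df$touching, -bw / 2, (df$bin_low + df$bin_high) / 2)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$fraction,
                                   fill = .data$touching)) +
    ggplot2::geom_col(width = bw * 0.92, show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#b2182b",
                                          `FALSE` = "grey35")) +
    ggplot2::labs(x = "separation (median vesicle diameters)",
                  y = "fraction of pairs") +
    ggplot2::theme_minimal()
}

#' Plot per-cloud bridge probabilities
#'
#' The figure convention of the study: one point per tomogram, a circle
#' at the group median and a box over the middle two quartiles.
#'
#' @param object A [bridge_probability_by_cloud()] result (optionally
#'   with a `group` column for side-by-side groups).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bridge_probability
#' @export
autoplot.bridge_probability <- function(object, ...) {
  df <- tibble::as_tibble(unclass(object))
  if (!"group" %in% names(df)) df$group <- "all"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$p_bridge)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.4, coef = 0) +
    ggplot2::geom_jitter(width = 0.08, height = 0, alpha = 0.6) +
    ggplot2::stat_summary(fun = stats::median, geom = "point", shape = 21,
                          size = 3, fill = "white") +
    ggplot2::labs(x = NULL, y = "bridge probability per pair") +
    ggplot2::theme_minimal()
}

#' Plot a docked-distance bridge-probability profile
#'
#' @param profile Output of [docked_distance_profile()].
#' @return A ggplot object.
#' @export
plot_docked_profile <- function(profile) {
  df <- profile
  df$x <- (df$bin_low + df$bin_high) / 2
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$p_bridge)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "distance to nearest docked vesicle (median diameters)",
      y = "bridge probability"
    ) +
    ggplot2::theme_minimal()
}

#' Display one view of a pair-view set
#'
#' @param object A `pair_views` from [extract_pair_views()].
#' @param view Which view: `"0"`, `"p45"` or `"m45"`.
#' @param ... Unused.
#' @return A ggplot raster of the averaged section.
#' @method autoplot pair_views
#' @export
autoplot.pair_views <- function(object, view = c("0", "p45", "m45"), ...) {
  view <- match.arg(view)
  m <- object[[paste0("view_", view)]]
  df <- tidyr::expand_grid(i = seq_len(nrow(m)), j = seq_len(ncol(m)))
  df$value <- m[cbind(df$i, df$j)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
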