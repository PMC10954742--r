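#' Plot a momentum heatmap
#'
#' Region-by-momentum tile plot with regions ordered east to west, matching
#' the tabulation of [heatmap_counts()]. Requires ggplot2.
#'
#' @param heatmap A `momentum_heatmap`.
#' @return A ggplot object.
#' @export
plot_momentum_heatmap <- function(heatmap) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stopf("ggplot2 is required for plotting")
  }
  df <- heatmap_long(heatmap)
  df$region <- factor(df$region, levels = rev(rownames(heatmap)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$momentum, y = .data$region,
                                   fill = .data$count)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(.data$count > 0, .data$count, "")),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::scale_x_continuous(breaks = 0:attr(heatmap, "max_momentum"),
                                labels = paste0("t", 0:attr(heatmap, "max_momentum"))) +
    ggplot2::labs(x = "momentum", y = NULL, fill = "species",
                  title = sprintf("First records per %s and momentum",
                                  attr(heatmap, "level")))
}

#' Plot cumulative median spread curves
#'
#' Overlays the cumulative eCDF-median years-since-entry of one or more
#' scenarios. Requires ggplot2.
#'
#' @param ... Named `cumulative_curve` objects (names become the legend).
#' @return A ggplot object.
#' @export
plot_cumulative_curves <- function(...) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stopf("ggplot2 is required for plotting")
  }
  curves <- list(...)
  if (is.null(names(curves)) || any(!nzchar(names(curves)))) {
    names(curves) <- vapply(curves, function(c) attr(c, "scenario"), "")
  }
  df <- do.call(rbind, lapply(names(curves), function(nm) {
    cbind(scenario = nm, as.data.frame(curves[[nm]]))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$cumulative,
                                   color = .data$scenario)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = unique(df$step),
                                labels = unique(df$label)) +
    ggplot2::labs(x = "momentum transition", y = "cumulative median years since entry") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
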