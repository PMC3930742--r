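#' Plot a window-size scan
#'
#' Accuracy (and the other metrics) against window size, the view used
#' to pick the best peptide length.
#'
#' @param object A `window_scan` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot window_scan
#' @export
autoplot.window_scan <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object), "window_size",
                  "Sn", "Sp", "Acc", "MCC"),
    cols = c("Sn", "Sp", "Acc", "MCC"),
    names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$window_size,
                                     y = 100 * .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "window size (2n + 1)", y = "metric (%)",
                  colour = NULL,
                  title = "Cross-validated performance by window size") +
    ggplot2::theme_minimal()
}

#' Plot per-iteration CV metrics of a balanced-resampling run
#'
#' @param object A `resampling_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot resampling_result
#' @export
autoplot.resampling_result <- function(object, ...) {
  long <- tidyr::pivot_longer(tidy(object),
                              cols = c("Sn", "Sp", "Acc", "MCC"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = 100 * .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "metric (%)",
                  title = "Fold-averaged metrics across resampling iterations") +
    ggplot2::theme_minimal()
}

#' Heatmap of a PSSC score matrix
#'
#' Positive cells mark residues enriched around acetylated lysines,
#' negative cells residues typical of non-acetylated windows.
#'
#' @param object A `pssc_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pssc_matrix
#' @export
autoplot.pssc_matrix <- function(object, ...) {
  df <- tibble::as_tibble(as.table(unclass(object)), .name_repair = "minimal")
  names(df) <- c("residue", "position", "score")
  df$position <- factor(df$position, levels = colnames(object))
  df$residue <- factor(df$residue, levels = rev(rownames(object)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$residue,
                                   fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b") +
    ggplot2::labs(x = "window position", y = NULL,
                  title = "Position-specific symbol composition scores") +
    ggplot2::theme_minimal()
}
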