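#' Scree plot of a fitted PCA space
#'
#' @param object A `pca_space`.
#' @param ... Unused.
#' @return A ggplot: explained-variance fraction per retained component.
#' @method autoplot pca_space
#' @export
autoplot.pca_space <- function(object, ...) {
  df <- tidy.pca_space(object)
  df$component <- factor(df$component, levels = df$component)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component,
                                   y = .data$explained_fraction)) +
    ggplot2::geom_col(fill = "seagreen") +
    ggplot2::labs(x = NULL, y = "Explained variance fraction") +
    ggplot2::theme_minimal()
}

#' Compare human and projected variance per component
#'
#' Side-by-side bars of the fraction of variance each retained human
#' component explains in the human training data and in the projected mouse
#' score matrix.
#'
#' @param model A `pca_space`.
#' @param projected A `projected_scores` from [project_into()].
#' @return A ggplot.
#' @export
plot_variance_explained <- function(model, projected) {
  df <- dplyr::bind_rows(
    tibble::tibble(component = colnames(model$loadings),
                   fraction = model$explained_fraction / sum(model$explained_fraction),
                   dataset = "human (training)"),
    tibble::tibble(component = projected$component,
                   fraction = projected$projected_fraction,
                   dataset = "mouse (projected)")
  )
  df$component <- factor(df$component, levels = colnames(model$loadings))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$fraction,
                                   fill = .data$dataset)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c("human (training)" = "seagreen",
                                          "mouse (projected)" = "turquoise3")) +
    ggplot2::labs(x = NULL, y = "Variance fraction", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Selection-frequency plot for a consensus selection
#'
#' @param object A `consensus_selection`.
#' @param ... Unused.
#' @return A ggplot: per-component selection frequency with the threshold
#'   line; selected components highlighted.
#' @method autoplot consensus_selection
#' @export
autoplot.consensus_selection <- function(object, ...) {
  df <- object$frequency
  df$component <- factor(df$component, levels = df$component)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$frequency,
                                   fill = .data$selected)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "magenta3",
                                          `FALSE` = "grey60"),
                               guide = "none") +
    ggplot2::labs(x = NULL, y = "Selection frequency") +
    ggplot2::theme_minimal()
}

#' Null-distribution histogram with the observed statistic
#'
#' @param object A `null_distribution`.
#' @param ... Unused.
#' @return A ggplot: histogram of null LOO-RMSE values with a vertical line
#'   at the observed value.
#' @method autoplot null_distribution
#' @export
autoplot.null_distribution <- function(object, ...) {
  df <- tidy.null_distribution(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$rmse)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey40") +
    ggplot2::labs(x = "Null LOO-RMSE", y = "Count") +
    ggplot2::theme_minimal()
  if (!is.na(object$observed_rmse)) {
    p <- p + ggplot2::geom_vline(xintercept = object$observed_rmse,
                                 colour = "magenta3", linewidth = 1)
  }
  p
}

#' Age-decoupling significance plot
#'
#' @param object An `age_decoupling` tibble from [age_decoupling()].
#' @param threshold Reference threshold line (default 0.01).
#' @param ... Unused.
#' @return A ggplot: -log10 F-test p-value per component.
#' @method autoplot age_decoupling
#' @export
autoplot.age_decoupling <- function(object, threshold = 0.01, ...) {
  df <- object
  df$component <- factor(df$component, levels = unique(df$component))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component,
                                   y = -log10(.data$p.value),
                                   fill = .data$pass)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = -log10(threshold), linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "magenta3",
                                          `FALSE` = "grey60"),
                               guide = "none") +
    ggplot2::labs(x = NULL, y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
}
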