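#' Plot a per-group function-function correlation heat map
#'
#' @param report Output of [correlation_matrix_report()].
#' @return A ggplot: faceted 7x7 heat maps, blue positive, red inverse.
#' @export
plot_correlation_matrix <- function(report) {
  fns <- function_names()
  df <- dplyr::mutate(report,
                      function_a = factor(.data$function_a, levels = fns),
                      function_b = factor(.data$function_b, levels = rev(fns)))
  ggplot2::ggplot(df, ggplot2::aes(.data$function_a, .data$function_b,
                                   fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "firebrick", mid = "white",
                                  high = "steelblue4", limits = c(-1, 1)) +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman\nrho") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot the strength histogram of pairwise correlations
#'
#' @param hist_tbl Output of [strength_histogram()].
#' @return A ggplot of per-group proportions by correlation-strength band.
#' @export
plot_strength_histogram <- function(hist_tbl) {
  df <- dplyr::mutate(hist_tbl, bin = factor(.data$bin, levels = unique(.data$bin)))
  ggplot2::ggplot(df, ggplot2::aes(.data$bin, .data$proportion,
                                   fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "Spearman rho band", y = "Proportion of function pairs",
                  fill = "Group") +
    ggplot2::theme_minimal()
}

#' Plot subclass positivity prevalence
#'
#' @param prev Output of [prevalence_by_group()].
#' @return A ggplot of prevalence by group and subclass.
#' @export
plot_prevalence <- function(prev) {
  ggplot2::ggplot(prev, ggplot2::aes(.data$subclass, .data$prevalence,
                                     fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%"),
                                limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "Subjects positive", fill = "Group") +
    ggplot2::theme_minimal()
}

#' @describeIn polyfunction_model Accuracy distributions of the two arms and
#'   the mean coefficient weights, side by side.
#' @param object A `polyfc_run`.
#' @param ... Unused.
#' @export
autoplot.polyfc_run <- function(object, ...) {
  acc <- dplyr::bind_rows(tidy(object$true), tidy(object$permuted))
  p1 <- ggplot2::ggplot(acc, ggplot2::aes(.data$balanced_accuracy,
                                          fill = .data$arm)) +
    ggplot2::geom_histogram(alpha = 0.6, position = "identity", bins = 30) +
    ggplot2::geom_vline(xintercept = 0.5, linetype = 2) +
    ggplot2::labs(x = "Balanced accuracy", y = "CV iterations", fill = NULL) +
    ggplot2::theme_minimal()
  cf <- object$coefficients
  p2 <- ggplot2::ggplot(cf, ggplot2::aes(stats::reorder(.data$feature,
                                                        .data$mean_weight),
                                         .data$mean_weight,
                                         fill = .data$mean_weight > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Mean standardized coefficient") +
    ggplot2::theme_minimal()
  if (requireNamespace("patchwork", quietly = TRUE)) {
    p1 + patchwork::plot_spacer() + p2
  } else {
    list(accuracy = p1, coefficients = p2)
  }
}
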