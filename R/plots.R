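#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an IFS accuracy curve
#'
#' @param object A `"pseterm_ifs"`.
#' @param ... Unused.
#' @return A ggplot: accuracy against prefix size, best prefix marked.
#' @method autoplot pseterm_ifs
#' @export
autoplot.pseterm_ifs <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_features, y = .data$accuracy)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = object$best_size, linetype = "dashed") +
    ggplot2::labs(x = "Number of top-ranked features",
                  y = "Cross-validated accuracy",
                  title = sprintf("Incremental feature selection (%s ranking)",
                                  object$method),
                  subtitle = sprintf("best prefix: %d features",
                                     object$best_size)) +
    ggplot2::theme_minimal()
}

#' Plot a ROC curve
#'
#' @param object A `"pseterm_roc"`.
#' @param ... Unused.
#' @return A ggplot of the ROC curve with the AUC in the title.
#' @method autoplot pseterm_roc
#' @export
autoplot.pseterm_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step(colour = "firebrick") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("ROC (AUC = %.4f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' Plot per-class k-mer preference
#'
#' @param data Output of [kmer_class_preference()].
#' @param top Number of most positively skewed k-mers to show.
#' @return A dodged bar chart of per-class ratios.
#' @export
plot_kmer_preference <- function(data, top = 18) {
  df <- utils::head(data, top)
  long <- tidyr::pivot_longer(df, c("ratio_pos", "ratio_neg"),
                              names_to = "class", values_to = "ratio")
  long$class <- ifelse(long$class == "ratio_pos", "terminator",
                       "non-terminator")
  long$kmer <- factor(long$kmer, levels = df$kmer)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$kmer, y = .data$ratio,
                                     fill = .data$class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "Share of sequences containing the k-mer") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
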