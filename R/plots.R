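#' Plot the ROC or precision-recall curve of an evaluation report
#'
#' @param object An `scplpa_eval`.
#' @param curve `"roc"` or `"pr"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scplpa_eval <- function(object, curve = c("roc", "pr"), ...) {
  curve <- rlang::arg_match(curve)
  if (curve == "roc") {
    df <- object$roc_points
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
      ggplot2::geom_abline(slope = 1, intercept = 0,
                           linetype = "dashed", colour = "grey60") +
      ggplot2::geom_step() +
      ggplot2::labs(
        x = "False positive rate", y = "True positive rate",
        title = sprintf("ROC (%s), AUC = %.4f", object$method, object$auc)
      )
  } else {
    df <- object$pr_points
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$recall, y = .data$precision)) +
      ggplot2::geom_step(direction = "vh") +
      ggplot2::labs(
        x = "Recall", y = "Precision",
        title = sprintf("Precision-recall (%s), AUPR = %.4f",
                        object$method, object$aupr)
      )
  }
  p + ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' Plot a parameter sweep
#'
#' One panel per sweep stage, AUC against the parameter varied in that
#' stage.
#'
#' @param sweep A tibble returned by [parameter_sweep()].
#' @return A ggplot object.
#' @export
plot_parameter_sweep <- function(sweep) {
  long <- dplyr::mutate(
    sweep,
    value = dplyr::case_when(
      .data$stage == "alpha" ~ .data$alpha,
      .data$stage == "delta" ~ .data$delta,
      TRUE ~ .data$epsilon
    ),
    stage = factor(.data$stage, levels = c("alpha", "delta", "epsilon"))
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, y = .data$auc)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~stage, scales = "free_x") +
    ggplot2::labs(x = "Parameter value", y = "LOOCV AUC",
                  title = "Sequential parameter sweep") +
    ggplot2::theme_minimal()
}

#' Heatmap of final prediction scores
#'
#' @param result An `scplpa_result`.
#' @param mark_known Outline the already known associations.
#' @return A ggplot object.
#' @export
plot_score_heatmap <- function(result, mark_known = TRUE) {
  df <- tidy.scplpa_result(result)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$disease, y = .data$mirna,
                                        fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
  if (mark_known) {
    p <- p + ggplot2::geom_tile(
      data = df[df$known == 1, ],
      colour = "white", linewidth = 0.4, fill = NA
    )
  }
  p
}
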