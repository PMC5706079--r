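#' Plot ROC or precision-recall curves for an evaluation report
#'
#' Curves are computed from the pooled out-of-fold scores.
#'
#' @param object An `evaluation_report`.
#' @param type `"roc"` or `"pr"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot evaluation_report
#' @export
autoplot.evaluation_report <- function(object, type = c("roc", "pr"), ...) {
  type <- match.arg(type)
  p <- object$predictions
  lab <- paste0(object$spec$algorithm, ", ",
                object$origin %||% "?", "/",
                object$feature_group %||% "?")
  if (type == "roc") {
    pts <- roc_points(p$score, p$truth)
    ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
      ggplot2::geom_step(colour = "#2166ac") +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                           colour = "grey60") +
      ggplot2::coord_equal() +
      ggplot2::labs(
        x = "False positive rate (1 - specificity)",
        y = "True positive rate (sensitivity)",
        title = sprintf("ROC curve (auROC = %.3f)", object$pooled$auroc),
        subtitle = lab) +
      ggplot2::theme_minimal()
  } else {
    pts <- pr_points(p$score, p$truth)
    ggplot2::ggplot(pts, ggplot2::aes(x = .data$recall, y = .data$precision)) +
      ggplot2::geom_step(direction = "vh", colour = "#b2182b") +
      ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
      ggplot2::labs(
        x = "Recall", y = "Precision",
        title = sprintf("Precision-recall curve (auPR = %.3f)",
                        object$pooled$aupr),
        subtitle = lab) +
      ggplot2::theme_minimal()
  }
}

#' Heatmap of a grid run's pooled accuracy
#'
#' @param grid Tibble returned by [run_grid()].
#' @param metric Column of `grid` to display.
#' @return A ggplot object.
#' @export
plot_grid_metric <- function(grid, metric = "accuracy") {
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$algorithm,
                                     y = .data$feature_group,
                                     fill = .data[[metric]])) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.3f", .data[[metric]])), colour = "white") +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "Classifier", y = "Feature group", fill = metric) +
    ggplot2::theme_minimal()
}
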