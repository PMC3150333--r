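#' Plot the validity-index ensemble across candidate k
#'
#' One panel per index with the voting direction in the strip label; the
#' chosen k is marked by a vertical line.
#'
#' @param object an `ige_kselect` result.
#' @param ... unused.
#' @export
autoplot.ige_kselect <- function(object, ...) {
  long <- tidyr::pivot_longer(object$report[1:6], -"k",
                              names_to = "index", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$chosen_k, linetype = 2,
                        colour = "grey40") +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::labs(x = "number of clusters k", y = "index value",
                  title = sprintf("Cluster validity ensemble (chosen k = %d)",
                                  object$chosen_k)) +
    ggplot2::theme_minimal()
}

#' Plot the ROC curve of an NRBF evaluation
#'
#' @param object an `ige_rbf_eval` result.
#' @param ... unused.
#' @export
autoplot.ige_rbf_eval <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("NRBF ROC, combined train+test (AUC = %.3f)",
                                  object$auc)) +
    ggplot2::theme_minimal()
}

#' Heatmap of class-score profiles ordered by cluster
#'
#' Subjects (columns) are sorted by cluster assignment; allergens are rows.
#' Mirrors the cluster-sorted matrix view used to visualize reactivity
#' profiles, with class 0 in black and increasing scores in reds.
#'
#' @param x class-score reactivity table.
#' @param result an `ige_kmeans` fit on the same subjects.
#' @return A ggplot object.
#' @export
plot_profile_heatmap <- function(x, result) {
  ord <- order(result$assignments[x$subject_id])
  long <- tidyr::pivot_longer(x, -"subject_id",
                              names_to = "allergen_id", values_to = "score")
  long$subject_id <- factor(long$subject_id, levels = x$subject_id[ord])
  ggplot2::ggplot(long, ggplot2::aes(x = .data$subject_id,
                                     y = .data$allergen_id,
                                     fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "black", high = "red", limits = c(0, 5)) +
    ggplot2::labs(x = "subjects (cluster-ordered)", y = "allergens",
                  fill = "class\nscore") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.text.y = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}
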