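#' Plot the importance-gain distribution of a GRN
#'
#' Histogram of per-candidate importance gains (log10 scale, zero gains
#' dropped), filled by selection status.
#'
#' @param object A `grn`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot grn
#' @export
autoplot.grn <- function(object, ...) {
  d <- dplyr::filter(object$edges, .data$gain > 0)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$gain, fill = .data$selected)) +
    ggplot2::geom_histogram(bins = 40, position = "stack") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "importance gain", y = "candidate edges",
                  fill = "selected") +
    ggplot2::theme_minimal()
}

#' Plot ablation z-scores
#'
#' @param object An `ablation_study`.
#' @param ... Unused.
#' @return A ggplot histogram of per-target z-scores with the null centre
#'   marked.
#' @method autoplot ablation_study
#' @export
autoplot.ablation_study <- function(object, ...) {
  ggplot2::ggplot(object$records, ggplot2::aes(x = .data$z)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(
      x = "ablation z-score", y = "targets",
      title = sprintf("mean z = %.2f (one-sided p = %.2g)",
                      object$mean_z, object$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' Volcano plot of differential regulation
#'
#' @param object A `diff_reg_table`.
#' @param ... Unused.
#' @return A ggplot of mean gain difference vs -log10 p, coloured by
#'   significance.
#' @method autoplot diff_reg_table
#' @export
autoplot.diff_reg_table <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$mean_diff, y = -log10(pmax(.data$p, 1e-300)),
                 colour = .data$significant)
  ) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "mean gain difference (A - B)",
                  y = expression(-log[10] ~ p), colour = "significant") +
    ggplot2::theme_minimal()
}

#' Plot edge robustness scores
#'
#' @param object A `robustness_result`.
#' @param ... Unused.
#' @return A ggplot bar chart of Pr(E | D) per candidate TF.
#' @method autoplot robustness_result
#' @export
autoplot.robustness_result <- function(object, ...) {
  d <- dplyr::arrange(object$scores, .data$score)
  d$tf_id <- factor(d$tf_id, levels = d$tf_id)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$tf_id, y = .data$score)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Pr(E | D)",
                  title = sprintf("%s (B = %d)", object$target_id, object$B)) +
    ggplot2::theme_minimal()
}

#' Plot calibrated threshold optima
#'
#' @param object A `threshold_table`.
#' @param ... Unused.
#' @return A ggplot of per-replicate optima by (n, p) cell with the lower
#'   quartile marked.
#' @method autoplot threshold_table
#' @export
autoplot.threshold_table <- function(object, ...) {
  d <- dplyr::mutate(object$optima,
                     cell = sprintf("n=%d, p=%d", .data$n, .data$p))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$cell, y = .data$threshold_opt)) +
    ggplot2::geom_boxplot(fill = "grey90") +
    ggplot2::stat_summary(fun = function(v) quantile(v, 0.25),
                          geom = "point", colour = "red") +
    ggplot2::labs(x = NULL, y = "optimal gain threshold") +
    ggplot2::theme_minimal()
}
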