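#' Plot a screening table
#'
#' Bar plot of the KS statistic per feature (in catalog order, coloured by
#' feature class) with the screening threshold as a dashed line.
#'
#' @param object A `screening_table` from [screen_features()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot screening_table
#' @export
autoplot.screening_table <- function(object, ...) {
  thr <- attr(object, "d_threshold")
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$index, y = .data$ks_d,
                               fill = .data$class)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed") +
    ggplot2::labs(x = "feature (catalog order)",
                  y = "Kolmogorov-Smirnov statistic D",
                  fill = "class") +
    ggplot2::theme_minimal()
}

#' Density plot of one feature by cohort
#'
#' Mirrors the per-feature distribution comparison used when inspecting
#' screened features: overlaid densities of one feature for the two labels.
#'
#' @param features Feature table.
#' @param feature Feature name to plot.
#' @return A ggplot object.
#' @export
plot_feature_density <- function(features, feature) {
  if (!feature %in% names(features))
    abort(paste0("unknown feature: ", feature))
  dat <- features[!is.na(features[[feature]]) & !is.na(features$label), ]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data[[feature]],
                                    fill = .data$label,
                                    colour = .data$label)) +
    ggplot2::geom_density(alpha = 0.35) +
    ggplot2::labs(x = feature, y = "density") +
    ggplot2::theme_minimal()
}

#' ROC curve of a cross-validation result
#'
#' Empirical ROC curve of the pooled out-of-fold probabilities, with the
#' chance diagonal.
#'
#' @param object A `hairpin_cv` from [cross_validate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hairpin_cv
#' @export
autoplot.hairpin_cv <- function(object, ...) {
  pred <- object$predictions
  curve <- roc_points(pred$prob, pred$label, object$positive_label)
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "false positive rate", y = "true positive rate",
      title = sprintf("%d-fold CV ROC (area %.3f)", object$k,
                      object$metrics$roc_area)) +
    ggplot2::theme_minimal()
}

#' Points of the empirical ROC curve
#'
#' One point per distinct score threshold (plus the endpoints); the area
#' under the linearly interpolated curve equals the rank-statistic AUC of
#' [roc_auc()].
#'
#' @param scores Numeric scores, higher = more positive.
#' @param labels Class labels.
#' @param positive The positive label.
#' @return Tibble with `threshold`, `fpr`, `tpr`, ordered by increasing
#'   `fpr`.
#' @export
roc_points <- function(scores, labels, positive) {
  pos <- labels == positive
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) abort("both classes must be present")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores[pos] >= t), numeric(1)) / n1
  fpr <- vapply(thr, function(t) sum(scores[!pos] >= t), numeric(1)) / n0
  tibble::tibble(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
}
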