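#' Plot an ROC or precision-recall curve
#'
#' @param object An `mcm_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mcm_curve <- function(object, ...) {
  if (object$kind == "roc") {
    ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                           colour = "grey60") +
      ggplot2::geom_step(direction = "hv") +
      ggplot2::labs(x = "False positive rate", y = "True positive rate",
                    title = sprintf("ROC (AUC %.3f, 95%% CI %.3f-%.3f)",
                                    object$auc, object$ci_low, object$ci_high)) +
      ggplot2::coord_equal()
  } else {
    ggplot2::ggplot(object$points,
                    ggplot2::aes(x = .data$recall, y = .data$precision)) +
      ggplot2::geom_step(direction = "vh") +
      ggplot2::ylim(0, 1) +
      ggplot2::labs(x = "Recall", y = "Precision",
                    title = sprintf("Precision-recall (AUC %.3f, 95%% CI %.3f-%.3f)",
                                    object$auc, object$ci_low, object$ci_high))
  }
}

#' Plot training and testing ROC curves of a workflow result together
#'
#' @param object An `mcm_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mcm_result <- function(object, ...) {
  pts <- dplyr::bind_rows(
    dplyr::mutate(object$train_report$roc$points, set = "training"),
    dplyr::mutate(object$test_report$roc$points, set = "testing")
  )
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                    colour = .data$set)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  colour = NULL) +
    ggplot2::coord_equal()
}

#' Plot a metaproperty assessment: class labels and fitted logit curve
#'
#' @param object An `mcm_assessment`.
#' @param values,labels The metric values and 0/1 labels the assessment was
#'   computed from (for the scatter overlay); optional.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mcm_assessment <- function(object, values = NULL, labels = NULL, ...) {
  if (object$degenerate) stop_validation("degenerate assessment has no curve")
  p <- ggplot2::ggplot(object$curve,
                       ggplot2::aes(x = .data$value, y = .data$probability)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Metaproperty value", y = "Probability of class 1")
  if (!is.null(values) && !is.null(labels)) {
    p <- p + ggplot2::geom_point(
      data = tibble::tibble(value = values, probability = labels),
      alpha = 0.4)
  }
  p
}

#' Top-down view of a scan's first returns
#'
#' @param object A `tls_scan`.
#' @param ... Unused.
#' @return A ggplot of first-return (x, y) positions coloured by height.
#' @export
autoplot.tls_scan <- function(object, ...) {
  fr <- object[object$return_index == 1L, , drop = FALSE]
  xyz <- spherical_to_cartesian(fr$distance_m, fr$zenith_deg, fr$azimuth_deg)
  ggplot2::ggplot(xyz, ggplot2::aes(x = .data$x, y = .data$y,
                                    colour = .data$z)) +
    ggplot2::geom_point(size = 0.3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", colour = "z (m)",
                  title = scan_id(object))
}
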