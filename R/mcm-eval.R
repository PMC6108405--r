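#' Accuracy assessment of predicted classifications
#'
#' Confusion counts and derived rates for a binary prediction, with class 1
#' as the positive class. The confusion table follows the per-class layout
#' of classification breakdown tables: for each class, how many of its
#' members were correctly recovered ("true") and how many members of the
#' other class were pulled into it ("false").
#'
#' @param true_labels Binary 0/1 truth.
#' @param predicted Binary 0/1 predictions.
#' @param set_name Name recorded on the report ("training", "testing", ...).
#'
#' @return An object of class `mcm_accuracy`: list with `set_name`, `n`,
#'   `confusion` (tibble), `accuracy_pct`, `sensitivity`, `specificity`,
#'   `false_positive_rate`, `false_negative_rate`.
#' @export
#'
#' @examples
#' # 322/324 of class 1 and 78/81 of class 0 correct -> 98.77%
#' truth <- c(rep(1, 324), rep(0, 81))
#' pred <- c(rep(1, 322), 0, 0, rep(0, 78), 1, 1, 1)
#' accuracy_report(truth, pred, "training")$accuracy_pct
accuracy_report <- function(true_labels, predicted, set_name = "set") {
  if (length(true_labels) != length(predicted)) {
    stop_validation("true_labels and predicted differ in length")
  }
  if (!all(true_labels %in% c(0, 1)) || !all(predicted %in% c(0, 1))) {
    stop_validation("labels and predictions must be binary 0/1")
  }
  n <- length(true_labels)
  tp <- sum(true_labels == 1 & predicted == 1)
  tn <- sum(true_labels == 0 & predicted == 0)
  fp <- sum(true_labels == 0 & predicted == 1)
  fn <- sum(true_labels == 1 & predicted == 0)
  n1 <- tp + fn
  n0 <- tn + fp
  confusion <- tibble::tibble(
    class = c(1, 0),
    n_true = c(tp, tn),
    n_class = c(n1, n0),
    n_false = c(fp, fn),
    n_other = c(n0, n1)
  )
  structure(
    list(set_name = set_name, n = n, confusion = confusion,
         accuracy_pct = 100 * (tp + tn) / n,
         sensitivity = if (n1 > 0) tp / n1 else NA_real_,
         specificity = if (n0 > 0) tn / n0 else NA_real_,
         false_positive_rate = if (n0 > 0) fp / n0 else NA_real_,
         false_negative_rate = if (n1 > 0) fn / n1 else NA_real_),
    class = "mcm_accuracy"
  )
}

#' @export
print.mcm_accuracy <- function(x, ...) {
  cat(sprintf("<mcm_accuracy '%s'> n = %d, accuracy %.2f%%, sens %.3f, spec %.3f\n",
              x$set_name, x$n, x$accuracy_pct, x$sensitivity, x$specificity))
  invisible(x)
}

#' Accuracy expected by chance
#'
#' The sum of squared class proportions, `100 * sum((n_i / N)^2)` percent:
#' the expected accuracy of assigning classes at random in proportion to
#' their prevalence. Minimized at `100 / k` for k balanced groups,
#' maximized at 100 for a single group.
#'
#' @param group_counts Nonnegative per-class counts.
#' @return Percent in `(0, 100]`.
#' @export
#'
#' @examples
#' chance_accuracy(c(50, 50))    # 50
#' chance_accuracy(c(462, 115))  # 68.08 (unbalanced two-class example)
chance_accuracy <- function(group_counts) {
  if (any(is.na(group_counts)) || any(group_counts < 0)) {
    stop_validation("group counts must be nonnegative")
  }
  total <- sum(group_counts)
  if (total <= 0) stop_validation("total count must be positive")
  100 * sum((group_counts / total)^2)
}

#' Chi-squared goodness of fit of predicted against true class totals
#'
#' `sum((obs - exp)^2 / exp)` with `df = k - 1`. A non-significant statistic
#' indicates the model's predicted class frequencies are consistent with the
#' true frequencies.
#'
#' @param observed Predicted per-class counts.
#' @param expected True per-class counts (all positive).
#'
#' @return List with `statistic`, `df` and `p_value`.
#' @export
#'
#' @examples
#' chi_squared_gof(c(131, 139), c(144, 126))  # 2.5148, 1 df
chi_squared_gof <- function(observed, expected) {
  if (length(observed) != length(expected) || length(observed) < 2) {
    stop_validation("observed and expected must be equal-length vectors of >= 2 classes")
  }
  if (any(expected <= 0)) stop_validation("expected counts must all be positive")
  stat <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df = df, lower.tail = FALSE))
}

roc_points <- function(labels, scores) {
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  s <- scores[ord]
  # one operating point per distinct threshold
  keep <- c(diff(s) != 0, TRUE)
  tp <- cumsum(y)[keep]
  fp <- cumsum(1 - y)[keep]
  n1 <- sum(y)
  n0 <- length(y) - n1
  tibble::tibble(
    fpr = c(0, fp / n0),
    tpr = c(0, tp / n1)
  )
}

auc_trapezoid <- function(x, y) {
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

roc_auc <- function(labels, scores) {
  pts <- roc_points(labels, scores)
  auc_trapezoid(pts$fpr, pts$tpr)
}

pr_points <- function(labels, scores) {
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  s <- scores[ord]
  keep <- c(diff(s) != 0, TRUE)
  tp <- cumsum(y)[keep]
  pred_pos <- seq_along(y)[keep]
  n1 <- sum(y)
  tibble::tibble(recall = tp / n1, precision = tp / pred_pos)
}

# Average precision: sum over operating points of (recall step) x precision.
pr_auc <- function(labels, scores) {
  pts <- pr_points(labels, scores)
  sum(diff(c(0, pts$recall)) * pts$precision)
}

bootstrap_ci <- function(labels, scores, statistic, n_resamples, seed) {
  idx0 <- which(labels == 0)
  idx1 <- which(labels == 1)
  set.seed(seed)
  vals <- vapply(seq_len(n_resamples), function(i) {
    take <- c(sample(idx0, length(idx0), replace = TRUE),
              sample(idx1, length(idx1), replace = TRUE))
    statistic(labels[take], scores[take])
  }, numeric(1))
  quantile(vals, c(0.025, 0.975), names = FALSE, na.rm = TRUE)
}

#' ROC and precision-recall curves with bootstrap confidence intervals
#'
#' `roc_with_ci()` sweeps every distinct score threshold to build the ROC
#' curve and computes the AUC by the trapezoid rule (equivalently, the
#' tie-aware Mann-Whitney concordance probability). `pr_with_ci()` builds
#' the precision-recall curve and computes the average-precision AUC. Both
#' attach a 95% percentile confidence interval from a seeded,
#' class-stratified bootstrap.
#'
#' @param labels Binary 0/1 labels (both classes present for ROC; positives
#'   present for PR).
#' @param probabilities Predicted scores or probabilities.
#' @param config An [mcm_config()] supplying `bootstrap_resamples` and
#'   `seed`.
#'
#' @return An object of class `mcm_curve`: list with `kind` (`"roc"` or
#'   `"pr"`), `points` (tibble), `auc`, `ci_low`, `ci_high`, `n_resamples`.
#' @export
#'
#' @examples
#' set.seed(1)
#' y <- rbinom(100, 1, 0.5)
#' p <- plogis(2 * y + rnorm(100))
#' roc_with_ci(y, p, mcm_config(bootstrap_resamples = 200))$auc
roc_with_ci <- function(labels, probabilities, config = mcm_config()) {
  if (length(unique(labels)) < 2) {
    stop_validation("ROC needs both classes present")
  }
  pts <- roc_points(labels, probabilities)
  auc <- auc_trapezoid(pts$fpr, pts$tpr)
  ci <- bootstrap_ci(labels, probabilities, roc_auc,
                     config$bootstrap_resamples, config$seed)
  structure(list(kind = "roc", points = pts, auc = auc,
                 ci_low = ci[1], ci_high = ci[2],
                 n_resamples = config$bootstrap_resamples),
            class = "mcm_curve")
}

#' @rdname roc_with_ci
#' @export
pr_with_ci <- function(labels, probabilities, config = mcm_config()) {
  if (sum(labels == 1) == 0) {
    stop_validation("precision-recall needs positive cases")
  }
  pts <- pr_points(labels, probabilities)
  auc <- pr_auc(labels, probabilities)
  ci <- bootstrap_ci(labels, probabilities, pr_auc,
                     config$bootstrap_resamples, config$seed)
  structure(list(kind = "pr", points = pts, auc = auc,
                 ci_low = ci[1], ci_high = ci[2],
                 n_resamples = config$bootstrap_resamples),
            class = "mcm_curve")
}

#' @export
print.mcm_curve <- function(x, ...) {
  cat(sprintf("<mcm_curve %s> AUC %.4f (95%% CI %.4f-%.4f, %d resamples)\n",
              toupper(x$kind), x$auc, x$ci_low, x$ci_high, x$n_resamples))
  invisible(x)
}
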