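#' Configuration for the metaproperty classification workflow
#'
#' @param alpha Significance level for Wald and model-level tests.
#' @param residual_threshold Standardized-residual cutoff for flagging
#'   outliers (default 3).
#' @param cooks_threshold Cook's distance cutoff for flagging influential
#'   observations (default 1.5).
#' @param classification_threshold Probability cutoff for assigning class 1.
#' @param log_transform_vars Character vector of metric columns to replace
#'   by their natural logs (renamed with a `log_` prefix) before fitting.
#' @param drop_separating_vars Drop completely separating predictors before
#'   fitting instead of switching to Firth regression.
#' @param full_population_mode Train and evaluate on the complete set of
#'   scans (no train/test split) -- appropriate for small proof-of-concept
#'   populations, at the cost of optimistic accuracy.
#' @param seed Seed for the stratified split and bootstrap resampling.
#' @param bootstrap_resamples Bootstrap resamples for ROC/PR confidence
#'   intervals (default 2000).
#' @param Z,E Critical value and margin of error (percent) for the power
#'   analysis sizing the testing set.
#'
#' @return An object of class `mcm_config`.
#' @export
mcm_config <- function(alpha = 0.05, residual_threshold = 3,
                       cooks_threshold = 1.5, classification_threshold = 0.5,
                       log_transform_vars = character(0),
                       drop_separating_vars = FALSE,
                       full_population_mode = FALSE,
                       seed = 1L, bootstrap_resamples = 2000L,
                       Z = 1.96, E = 5) {
  check_number(alpha, "alpha", min = 1e-12, max = 1 - 1e-12)
  check_number(residual_threshold, "residual_threshold", min = 1e-12)
  check_number(cooks_threshold, "cooks_threshold", min = 1e-12)
  check_number(classification_threshold, "classification_threshold", min = 0, max = 1)
  check_flag(drop_separating_vars, "drop_separating_vars")
  check_flag(full_population_mode, "full_population_mode")
  check_number(bootstrap_resamples, "bootstrap_resamples", min = 1)
  structure(
    list(alpha = alpha, residual_threshold = residual_threshold,
         cooks_threshold = cooks_threshold,
         classification_threshold = classification_threshold,
         log_transform_vars = as.character(log_transform_vars),
         drop_separating_vars = drop_separating_vars,
         full_population_mode = full_population_mode,
         seed = as.integer(seed),
         bootstrap_resamples = as.integer(bootstrap_resamples),
         Z = Z, E = E),
    class = "mcm_config"
  )
}

#' Detect complete separation of a metric between two classes
#'
#' `TRUE` when the value ranges of the two classes do not overlap, i.e. the
#' maximum of one class falls strictly below the minimum of the other. Such
#' a predictor classifies perfectly on its own, and makes the standard
#' logistic MLE diverge. Non-finite (flagged) values are excluded before
#' comparison.
#'
#' @param values Numeric metric values, one per scan.
#' @param labels Binary 0/1 class labels.
#'
#' @return `TRUE` or `FALSE`.
#' @export
#'
#' @examples
#' detect_complete_separation(c(1, 2, 3, 4, 5), c(0, 0, 0, 1, 1))  # TRUE
#' detect_complete_separation(c(1, 3, 2, 5), c(0, 0, 1, 1))        # FALSE
detect_complete_separation <- function(values, labels) {
  if (length(values) != length(labels)) {
    stop_validation("values and labels differ in length")
  }
  keep <- is.finite(values) & !is.na(labels)
  v0 <- values[keep & labels == 0]
  v1 <- values[keep & labels == 1]
  if (length(v0) == 0 || length(v1) == 0) {
    stop_validation("a class has no finite values; separation is undefined")
  }
  max(v0) < min(v1) || max(v1) < min(v0)
}

#' Accuracy of the best single-threshold classifier on one metric
#'
#' Sweeps every candidate cut point (midpoints between consecutive sorted
#' values, plus the extremes) in both orientations and returns the best
#' achievable accuracy in percent. A metric that completely separates the
#' classes scores 100. Infinite values are ordered naturally (an infinite
#' first:second ratio sits above any threshold).
#'
#' @inheritParams detect_complete_separation
#' @return Percent in `[0, 100]`.
#' @export
#'
#' @examples
#' best_threshold_accuracy(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1))  # 100
best_threshold_accuracy <- function(values, labels) {
  if (length(values) != length(labels)) {
    stop_validation("values and labels differ in length")
  }
  keep <- !is.na(values) & !is.na(labels)
  v <- values[keep]
  y <- labels[keep]
  if (length(v) == 0) stop_validation("no usable values")
  fin <- sort(unique(v[is.finite(v)]))
  cand <- c(min(fin) - 1, (head(fin, -1) + tail(fin, -1)) / 2, max(fin) + 1)
  acc <- vapply(cand, function(t) {
    max(mean((v >= t) == y), mean((v < t) == y))
  }, numeric(1))
  100 * max(acc)
}

#' Graphical-assessment record for one metaproperty
#'
#' The first workflow step: a univariate logistic fit of the class label on
#' the metric, producing the fitted probability curve across the metric's
#' range (the overlay for a classification scatter plot), a linearity
#' diagnostic, and the complete-separation flag. The linearity diagnostic
#' bins the metric into quantile bins and correlates the empirical logit of
#' the per-bin class proportion (with a 0.5 continuity correction) against
#' the bin mean -- near 1 when the log-odds are linear in the metric, the
#' assumption a logistic model rests on.
#'
#' @param values Numeric metric values.
#' @param labels Binary 0/1 labels.
#' @param n_bins Number of quantile bins for the linearity diagnostic.
#' @param n_curve Number of points on the fitted probability curve.
#'
#' @return An object of class `mcm_assessment`: a list with `curve` (tibble
#'   of `value`, `probability`), `linearity` (correlation in `[-1, 1]`),
#'   `separation` (logical), `slope_p` (Wald p-value of the univariate
#'   slope) and `degenerate` (TRUE for a constant metric, which gets no
#'   curve).
#' @export
logit_assessment <- function(values, labels, n_bins = 8L, n_curve = 101L) {
  keep <- is.finite(values) & !is.na(labels)
  v <- values[keep]
  y <- labels[keep]
  if (sum(y == 0) < 2 || sum(y == 1) < 2) {
    stop_validation("need at least 2 scans per class with finite values")
  }
  if (diff(range(v)) < .Machine$double.eps) {
    return(structure(list(curve = NULL, linearity = NA_real_,
                          separation = FALSE, slope_p = NA_real_,
                          degenerate = TRUE),
                     class = "mcm_assessment"))
  }
  sep <- detect_complete_separation(v, y)
  fit <- if (sep) fit_firth(matrix(v, dimnames = list(NULL, "value")), y)
         else fit_logistic(matrix(v, dimnames = list(NULL, "value")), y)
  grid <- seq(min(v), max(v), length.out = n_curve)
  curve <- tibble::tibble(
    value = grid,
    probability = plogis(pmin(30, pmax(-30, fit$beta[1] + fit$beta[2] * grid)))
  )
  # empirical-logit linearity across quantile bins
  brk <- unique(quantile(v, probs = seq(0, 1, length.out = n_bins + 1)))
  lin <- NA_real_
  if (length(brk) >= 4) {
    bin <- cut(v, brk, include.lowest = TRUE)
    ok_bin <- tapply(y, bin, length)
    prop <- tapply(y, bin, sum)
    mid <- tapply(v, bin, mean)
    use <- !is.na(ok_bin)
    elogit <- log((prop[use] + 0.5) / (ok_bin[use] - prop[use] + 0.5))
    if (length(elogit) >= 3 && sd(elogit) > 0 && sd(mid[use]) > 0) {
      lin <- cor(mid[use], elogit)
    }
  }
  structure(list(curve = curve, linearity = lin, separation = sep,
                 slope_p = unname(fit$wald_p[2]), degenerate = FALSE),
            class = "mcm_assessment")
}

#' @export
print.mcm_assessment <- function(x, ...) {
  if (x$degenerate) {
    cat("<mcm_assessment> degenerate (constant metric)\n")
  } else {
    cat(sprintf("<mcm_assessment> separation: %s, linearity: %s, slope p: %s\n",
                x$separation, format(x$linearity, digits = 3),
                format.pval(x$slope_p, digits = 3)))
  }
  invisible(x)
}

#' Apply natural-log transforms to metaproperty columns
#'
#' Replaces the named columns by their natural logarithms and renames them
#' with a `log_` prefix. Values must be strictly positive and finite; a
#' flagged-infinite first:second ratio, for example, is rejected rather
#' than silently log-transformed.
#'
#' @param table A metaproperty table (tibble).
#' @param vars Character vector of column names to transform; defaults to
#'   `config$log_transform_vars`.
#' @param config An [mcm_config()].
#'
#' @return The table with transformed, renamed columns.
#' @export
#'
#' @examples
#' tab <- tibble::tibble(scan_id = "s1", opa = exp(2))
#' apply_transforms(tab, vars = "opa")$log_opa  # 2
apply_transforms <- function(table, vars = config$log_transform_vars,
                             config = mcm_config()) {
  for (v in vars) {
    if (!v %in% names(table)) {
      stop_validation("no column '%s' to transform", v)
    }
    x <- table[[v]]
    bad <- which(!is.na(x) & (!is.finite(x) | x <= 0))
    if (length(bad) > 0) {
      id <- if ("scan_id" %in% names(table)) table$scan_id[bad[1]] else bad[1]
      stop_validation("cannot log-transform '%s': non-positive or non-finite value at scan %s",
                      v, id)
    }
    table[[v]] <- log(x)
    names(table)[names(table) == v] <- paste0("log_", v)
  }
  table
}

#' Required testing-set size for a given confidence and margin of error
#'
#' Finite-population sample-size formula: with `x = Z^2 r (100 - r)`,
#' `n = ceiling(N x / ((N - 1) E^2 + x))`, where `r` and `E` are on the
#' percent scale. At `r = 50`, `Z = 1.96`, `E = 5` the large-`N` limit is
#' the familiar 385.
#'
#' @param N Total number of scans.
#' @param r Proportion of one class, in percent (0 < r < 100).
#' @param Z Critical value for the confidence level (1.96 for 95%).
#' @param E Margin of error in percent (default 5).
#'
#' @return A list of class `power_analysis` with fields `N`, `r`, `Z`, `E`,
#'   `x` and `n` (the required testing-set size).
#' @export
#'
#' @examples
#' power_analysis(N = 1e9, r = 50)$n  # 385
power_analysis <- function(N, r, Z = 1.96, E = 5) {
  check_number(N, "N", min = 2)
  check_number(Z, "Z", min = 1e-9)
  check_number(E, "E", min = 1e-9)
  if (!is.numeric(r) || length(r) != 1 || is.na(r) || r <= 0 || r >= 100) {
    rlang::abort("`r` must be a percentage strictly between 0 and 100",
                 class = c("metaprop_degenerate_proportion",
                           "metaprop_validation_error"))
  }
  x <- Z^2 * r * (100 - r)
  n <- ceiling(N * x / ((N - 1) * E^2 + x))
  n <- min(n, N)
  structure(list(N = N, r = r, Z = Z, E = E, x = x, n = as.integer(n)),
            class = "power_analysis")
}

#' @export
print.power_analysis <- function(x, ...) {
  cat(sprintf("<power_analysis> N = %g, r = %g%%, Z = %g, E = %g%% -> n = %d\n",
              x$N, x$r, x$Z, x$E, x$n))
  invisible(x)
}

#' Stratified train/test split
#'
#' Testing rows are drawn randomly without replacement from each class in
#' proportion to the class's representation, using largest-remainder
#' rounding so per-class counts sum exactly to `test_n`. Identical seeds
#' give identical splits.
#'
#' @param table A metaproperty table with a binary `label` column.
#' @param test_n Number of rows for the testing set.
#' @param seed RNG seed.
#'
#' @return A list with tibbles `train` and `test`.
#' @export
stratified_split <- function(table, test_n, seed = 1L) {
  if (!"label" %in% names(table) || any(is.na(table$label))) {
    stop_validation("table must have a complete binary `label` column")
  }
  n <- nrow(table)
  check_number(test_n, "test_n", min = 1, max = n - 1)
  classes <- sort(unique(table$label))
  if (length(classes) < 2) stop_validation("both classes must be present")
  class_n <- vapply(classes, function(cl) sum(table$label == cl), numeric(1))
  ideal <- test_n * class_n / n
  take <- floor(ideal)
  remainder <- test_n - sum(take)
  if (remainder > 0) {
    extra <- order(ideal - take, decreasing = TRUE)[seq_len(remainder)]
    take[extra] <- take[extra] + 1
  }
  if (any(class_n - take < 1)) {
    stop_validation("test_n = %d would leave a class empty in training", test_n)
  }
  set.seed(seed)
  test_idx <- unlist(lapply(seq_along(classes), function(i) {
    rows <- which(table$label == classes[i])
    sample(rows, take[i])
  }))
  test_idx <- sort(test_idx)
  list(train = table[-test_idx, , drop = FALSE],
       test = table[test_idx, , drop = FALSE])
}
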