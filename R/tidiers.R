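#' Tidy a fitted classification model
#'
#' @param x An `mcm_fit`.
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `term`, `estimate`,
#'   `std.error`, `statistic` (z), `p.value`.
#' @export
tidy.mcm_fit <- function(x, ...) {
  tibble::tibble(
    term = x$variable_names,
    estimate = unname(x$beta),
    std.error = unname(x$se),
    statistic = unname(x$beta / x$se),
    p.value = unname(x$wald_p)
  )
}

#' @rdname tidy.mcm_fit
#' @export
glance.mcm_fit <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    converged = x$converged,
    n_iterations = x$n_iterations,
    log_likelihood = x$log_likelihood,
    model_p = x$model_p,
    n_obs = x$n_obs,
    df = length(x$variable_names) - 1L
  )
}

#' Tidy a classification workflow result
#'
#' `tidy()` returns the coefficient table of the final model; `glance()` a
#' one-row summary of the whole run (regression method, set sizes,
#' accuracies, chance accuracy, AUCs).
#'
#' @param x An `mcm_result`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.mcm_result <- function(x, ...) tidy(x$fit)

#' @rdname tidy.mcm_result
#' @export
glance.mcm_result <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    n_scans = x$power$N,
    n_test = x$power$n,
    full_population = x$config$full_population_mode,
    train_accuracy_pct = x$train_report$accuracy$accuracy_pct,
    test_accuracy_pct = x$test_report$accuracy$accuracy_pct,
    chance_accuracy_pct = x$train_report$chance_accuracy_pct,
    train_roc_auc = x$train_report$roc$auc,
    test_roc_auc = x$test_report$roc$auc,
    train_pr_auc = x$train_report$pr$auc,
    test_pr_auc = x$test_report$pr$auc
  )
}

#' Tidy an ROC/PR curve or an accuracy report
#'
#' @param x An `mcm_curve` or `mcm_accuracy`.
#' @param ... Unused.
#' @return The curve points, or the per-class confusion table, as a tibble.
#' @export
tidy.mcm_curve <- function(x, ...) x$points

#' @rdname tidy.mcm_curve
#' @export
tidy.mcm_accuracy <- function(x, ...) x$confusion
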