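metric_columns <- function(table) {
  setdiff(names(table)[vapply(table, is.numeric, logical(1))],
          c("label"))
}

#' Run the full metaproperty classification workflow
#'
#' Executes the ten-stage workflow over a metaproperty table: per-metric
#' graphical assessment (univariate logistic curve, linearity, complete
#' separation), optional log transforms, power analysis to size the testing
#' set, stratified train/test split, binomial or Firth logistic regression
#' (Firth whenever any retained predictor completely separates the
#' classes), influence diagnostics, model reduction if the model-level test
#' fails, prediction, and train/test evaluation: confusion counts, overall
#' accuracy, sensitivity/specificity, chance accuracy, chi-squared goodness
#' of fit, ROC and precision-recall curves with bootstrap confidence
#' intervals.
#'
#' Rows with missing (flagged) metric values are removed listwise before
#' analysis; the count is recorded in the result. With
#' `config$drop_separating_vars`, completely separating metrics are excluded
#' from the model instead of triggering Firth regression -- the treatment
#' used when such diagnostics are reported on their own. With
#' `config$full_population_mode`, the model is trained and evaluated on the
#' complete population (no split).
#'
#' @param table A metaproperty table: `scan_id`, binary `label`, metric
#'   columns (any numeric columns besides the label are used as
#'   predictors), optional `flags`.
#' @param config An [mcm_config()].
#'
#' @return An object of class `mcm_result`; see [tidy.mcm_result()] and
#'   [glance.mcm_result()].
#' @export
#'
#' @examples
#' scans <- generate_labeled_dataset(6, 8, pattern = scan_pattern(
#'   zenith_step = 7.5, azimuth_step = 15), base_seed = 3)
#' tab <- extract_metaproperties(scans)
#' res <- run_mcm(dplyr::select(tab, scan_id, label, mean_distance,
#'                              mean_intensity, opa, rugosity),
#'                mcm_config(full_population_mode = TRUE,
#'                           bootstrap_resamples = 100))
#' glance(res)
run_mcm <- function(table, config = mcm_config()) {
  stage <- function(name, expr) {
    withCallingHandlers(expr, error = function(e) {
      if (is.null(attr(e, "mcm_stage"))) {
        e$message <- sprintf("[stage: %s] %s", name, conditionMessage(e))
        attr(e, "mcm_stage") <- name
      }
      stop(e)
    })
  }
  if (!"label" %in% names(table) || any(is.na(table$label)) ||
      !all(table$label %in% c(0, 1))) {
    stop_validation("table must carry a complete binary `label` column")
  }
  if (sum(table$label == 0) < 2 || sum(table$label == 1) < 2) {
    stop_validation("need at least 2 scans per class")
  }

  metrics <- metric_columns(table)
  if (length(metrics) == 0) stop_validation("no metric columns in table")

  # listwise deletion of rows with missing metric values
  complete <- complete.cases(table[metrics])
  n_dropped <- sum(!complete)
  table <- table[complete, , drop = FALSE]

  table <- stage("transformation", apply_transforms(table, config = config))
  metrics <- metric_columns(table)

  assessments <- stage("assessment", lapply(
    setNames(metrics, metrics),
    function(m) logit_assessment(table[[m]], table$label)
  ))
  separating <- names(Filter(function(a) isTRUE(a$separation), assessments))

  predictors <- metrics
  if (config$drop_separating_vars && length(separating) > 0) {
    predictors <- setdiff(predictors, separating)
    if (length(predictors) == 0) {
      stop_computation("every predictor completely separates the classes; nothing left to model")
    }
  }
  method <- if (any(predictors %in% separating)) "firth" else "standard"

  N <- nrow(table)
  r <- 100 * sum(table$label == 1) / N
  power <- stage("power_analysis", power_analysis(N, r, config$Z, config$E))

  # The finite-population formula asks for almost the whole population when
  # N is small; keep enough training rows to estimate the coefficients.
  test_n <- min(power$n, N - max(4L, length(predictors) + 2L))
  if (!config$full_population_mode && test_n < 1) {
    stop_validation("population too small to split; use full_population_mode")
  }
  if (config$full_population_mode) {
    train <- table
    test <- table
    split_seed <- NA_integer_
  } else {
    sp <- stage("stratified_split",
                stratified_split(table, test_n, seed = config$seed))
    train <- sp$train
    test <- sp$test
    split_seed <- config$seed
  }

  X_train <- as.matrix(train[predictors])
  y_train <- train$label
  fit <- stage("regression", {
    fitter <- if (method == "firth") fit_firth else fit_logistic
    f <- fitter(X_train, y_train)
    if (!f$converged && method == "standard") {
      # separation can emerge jointly even when no single metric separates
      method <- "firth"
      f <- fit_firth(X_train, y_train)
    }
    f
  })
  reduction_failed <- FALSE
  if (!fit$converged || is.na(fit$model_p) || fit$model_p >= config$alpha) {
    # discretionary step: fall back to the full fit when no reduced model
    # converges either (e.g. labels carry no signal at all)
    fit <- stage("model_reduction", tryCatch(
      reduce_model(X_train, y_train, config, method = method),
      metaprop_computation_error = function(e) {
        reduction_failed <<- TRUE
        fit
      }))
  }
  predictors <- setdiff(fit$variable_names, "(Intercept)")

  diagnostics <- stage("influence_diagnostics", tryCatch(
    diagnose_influence(fit, as.matrix(train[predictors]), y_train, config),
    metaprop_computation_error = function(e) NULL
  ))

  chance <- chance_accuracy(c(sum(table$label == 0), sum(table$label == 1)))
  evaluate <- function(data, set_name) {
    pred <- predict_classes(fit, as.matrix(data[predictors]), config)
    acc <- accuracy_report(data$label, pred$class, set_name)
    chi <- chi_squared_gof(
      observed = c(sum(pred$class == 0), sum(pred$class == 1)),
      expected = c(sum(data$label == 0), sum(data$label == 1))
    )
    list(
      accuracy = acc,
      chance_accuracy_pct = chance,
      chi_squared = chi,
      roc = stage("roc", roc_with_ci(data$label, pred$probability, config)),
      pr = stage("pr", pr_with_ci(data$label, pred$probability, config)),
      probabilities = pred$probability,
      classes = pred$class,
      scan_ids = if ("scan_id" %in% names(data)) data$scan_id else NULL
    )
  }
  train_report <- stage("evaluation", evaluate(train, "training"))
  test_report <- stage("evaluation", evaluate(test, "testing"))

  structure(
    list(config = config, n_dropped_rows = n_dropped,
         assessments = assessments, separating_vars = separating,
         method = method, power = power,
         split = list(seed = split_seed, test_n = test_n,
                      train_ids = train$scan_id %f|% NULL,
                      test_ids = test$scan_id %f|% NULL),
         fit = fit, reduction_failed = reduction_failed,
         diagnostics = diagnostics,
         train_report = train_report, test_report = test_report),
    class = "mcm_result"
  )
}

#' @export
print.mcm_result <- function(x, ...) {
  cat("<mcm_result>\n")
  cat(sprintf("  regression: %s logistic (%d predictors)%s\n", x$method,
              length(x$fit$variable_names) - 1,
              if (length(x$fit$reduction_trace %f|% character(0)) > 0)
                sprintf(", reduced (dropped: %s)",
                        paste(x$fit$reduction_trace, collapse = ", "))
              else ""))
  if (length(x$separating_vars) > 0) {
    cat(sprintf("  completely separating: %s\n",
                paste(x$separating_vars, collapse = ", ")))
  }
  cat(sprintf("  testing-set size (power analysis): %d of %d\n",
              x$power$n, x$power$N))
  for (rep in list(x$train_report, x$test_report)) {
    cat(sprintf("  %s: accuracy %.2f%% (chance %.2f%%), ROC AUC %.4f (%.4f-%.4f)\n",
                rep$accuracy$set_name, rep$accuracy$accuracy_pct,
                rep$chance_accuracy_pct, rep$roc$auc, rep$roc$ci_low,
                rep$roc$ci_high))
  }
  invisible(x)
}

#' Serialize a workflow result to JSON (plus curve points as CSV)
#'
#' @param result An `mcm_result`.
#' @param path Output JSON path.
#' @param curves_path Optional CSV path for the ROC/PR curve points of both
#'   sets.
#'
#' @return `path`, invisibly.
#' @export
write_mcm_result <- function(result, path, curves_path = NULL) {
  rep_json <- function(rep) {
    list(
      set = rep$accuracy$set_name,
      n = rep$accuracy$n,
      confusion = rep$accuracy$confusion,
      accuracy_pct = rep$accuracy$accuracy_pct,
      sensitivity = rep$accuracy$sensitivity,
      specificity = rep$accuracy$specificity,
      false_positive_rate = rep$accuracy$false_positive_rate,
      false_negative_rate = rep$accuracy$false_negative_rate,
      chance_accuracy_pct = rep$chance_accuracy_pct,
      chi_squared = rep$chi_squared,
      roc = list(auc = rep$roc$auc, ci_low = rep$roc$ci_low,
                 ci_high = rep$roc$ci_high, points = rep$roc$points),
      pr = list(auc = rep$pr$auc, ci_low = rep$pr$ci_low,
                ci_high = rep$pr$ci_high, points = rep$pr$points)
    )
  }
  payload <- list(
    schema_version = "1.0",
    config = unclass(result$config),
    n_dropped_rows = result$n_dropped_rows,
    method = result$method,
    separating_vars = result$separating_vars,
    assessments = lapply(result$assessments, function(a)
      list(separation = a$separation, linearity = a$linearity,
           slope_p = a$slope_p, degenerate = a$degenerate)),
    power = unclass(result$power),
    split = result$split,
    coefficients = tidy(result$fit),
    diagnostics = if (is.null(result$diagnostics)) NULL else
      list(outliers = result$diagnostics$outliers,
           influential = result$diagnostics$influential),
    train = rep_json(result$train_report),
    test = rep_json(result$test_report)
  )
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  if (!is.null(curves_path)) {
    curves <- dplyr::bind_rows(
      dplyr::mutate(result$train_report$roc$points, set = "training", kind = "roc",
                    x = .data$fpr, y = .data$tpr, fpr = NULL, tpr = NULL),
      dplyr::mutate(result$test_report$roc$points, set = "testing", kind = "roc",
                    x = .data$fpr, y = .data$tpr, fpr = NULL, tpr = NULL),
      dplyr::mutate(result$train_report$pr$points, set = "training", kind = "pr",
                    x = .data$recall, y = .data$precision,
                    recall = NULL, precision = NULL),
      dplyr::mutate(result$test_report$pr$points, set = "testing", kind = "pr",
                    x = .data$recall, y = .data$precision,
                    recall = NULL, precision = NULL)
    )
    readr::write_csv(curves[, c("set", "kind", "x", "y")], curves_path)
  }
  invisible(path)
}
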