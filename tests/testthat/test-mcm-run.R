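sim_table <- function(base_seed, n0 = 6, n1 = 8) {
  scans <- generate_labeled_dataset(n0, n1, pattern = scan_pattern(
    zenith_step = 2.5, azimuth_step = 5), base_seed = base_seed)
  extract_metaproperties(scans)
}

test_that("the full workflow classifies simulated rooms vs forests", {
  tab <- sim_table(301)
  # standard treatment: report the two completely separating diagnostics
  # on their own and model the remaining four on the whole population
  res <- run_mcm(
    dplyr::select(tab, "scan_id", "label", "mean_distance", "mean_intensity",
                  "opa", "rugosity"),
    mcm_config(full_population_mode = TRUE, bootstrap_resamples = 100))
  expect_s3_class(res, "mcm_result")
  expect_equal(res$train_report$accuracy$accuracy_pct, 100)
  expect_equal(res$test_report$accuracy$accuracy_pct, 100)
  expect_equal(res$train_report$roc$auc, 1.0)
  g <- glance(res)
  expect_equal(g$test_accuracy_pct, 100)
  expect_identical(g$full_population, TRUE)
})

test_that("separating metrics switch the fit to Firth or get dropped", {
  tab <- sim_table(302)
  cols <- c("scan_id", "label", "mean_distance", "mean_intensity",
            "first_second_ratio", "no_return_ratio", "opa", "rugosity")
  res <- run_mcm(dplyr::select(tab, dplyr::all_of(cols)),
                 mcm_config(full_population_mode = TRUE,
                            bootstrap_resamples = 50))
  expect_true(all(c("first_second_ratio", "no_return_ratio") %in%
                    res$separating_vars))
  expect_equal(res$method, "firth")
  expect_true(res$fit$converged)

  # with one separating diagnostic and overlapping companions, dropping
  # removes exactly the diagnostic and a standard fit proceeds
  set.seed(61)
  n <- 40
  y <- rep(c(0, 1), each = n / 2)
  built <- tibble::tibble(
    scan_id = sprintf("s%02d", 1:n), label = y,
    diagnostic = ifelse(y == 1, runif(n, 10, 20), runif(n, 0, 5)),
    overlap_a = rnorm(n, mean = y),
    overlap_b = rnorm(n, mean = -0.5 * y)
  )
  dropped <- run_mcm(built, mcm_config(full_population_mode = TRUE,
                                       drop_separating_vars = TRUE,
                                       bootstrap_resamples = 50))
  expect_equal(dropped$separating_vars, "diagnostic")
  expect_false("diagnostic" %in% dropped$fit$variable_names)
  expect_true(all(c("overlap_a", "overlap_b") %in% dropped$fit$variable_names))

  # dropping every predictor is a computation error, reported as such
  only_diag <- dplyr::select(built, "scan_id", "label", "diagnostic")
  expect_error(run_mcm(only_diag, mcm_config(full_population_mode = TRUE,
                                             drop_separating_vars = TRUE)),
               class = "metaprop_computation_error")
})

test_that("shuffled labels score near chance on held-out data", {
  tab <- sim_table(303, n0 = 22, n1 = 22)
  tab <- dplyr::select(tab, "scan_id", "label", "mean_distance",
                       "mean_intensity", "opa", "rugosity")
  accs <- vapply(1:20, function(seed) {
    set.seed(7000 + seed)
    shuffled <- tab
    shuffled$label <- sample(tab$label)
    res <- run_mcm(shuffled, mcm_config(seed = seed, bootstrap_resamples = 20))
    res$test_report$accuracy$accuracy_pct
  }, numeric(1))
  chance <- chance_accuracy(c(22, 22))
  expect_lt(abs(mean(accs) - chance), 10)
})

test_that("identical seed and table give identical results", {
  tab <- sim_table(304)
  cfg <- mcm_config(seed = 5, bootstrap_resamples = 50)
  cols <- dplyr::select(tab, "scan_id", "label", "mean_distance",
                        "mean_intensity", "opa", "rugosity")
  r1 <- run_mcm(cols, cfg)
  r2 <- run_mcm(cols, cfg)
  expect_identical(r1$split, r2$split)
  expect_identical(r1$fit$beta, r2$fit$beta)
  expect_identical(r1$test_report$roc$ci_low, r2$test_report$roc$ci_low)
  expect_identical(glance(r1), glance(r2))
})

test_that("full-population mode trains and tests on identical sets", {
  tab <- sim_table(305)
  res <- run_mcm(dplyr::select(tab, "scan_id", "label", "mean_distance",
                               "rugosity"),
                 mcm_config(full_population_mode = TRUE,
                            bootstrap_resamples = 20))
  expect_equal(res$train_report$accuracy$n, nrow(tab))
  expect_equal(res$test_report$accuracy$n, nrow(tab))
  expect_setequal(res$split$train_ids, res$split$test_ids)
})

test_that("log transforms flow through the workflow and rejections are staged", {
  tab <- sim_table(306)
  res <- run_mcm(dplyr::select(tab, "scan_id", "label", "mean_distance",
                               "opa", "rugosity"),
                 mcm_config(full_population_mode = TRUE,
                            log_transform_vars = "opa",
                            bootstrap_resamples = 20))
  expect_true("log_opa" %in% res$fit$variable_names)

  bad <- dplyr::select(tab, "scan_id", "label", "mean_distance", "opa")
  bad$opa[1] <- -2
  err <- tryCatch(
    run_mcm(bad, mcm_config(full_population_mode = TRUE,
                            log_transform_vars = "opa")),
    error = identity)
  expect_match(conditionMessage(err), "transformation")
})

test_that("missing metric values are dropped listwise with a count", {
  tab <- sim_table(307)
  tab <- dplyr::select(tab, "scan_id", "label", "mean_distance", "rugosity")
  tab$mean_distance[c(2, 9)] <- NA
  res <- run_mcm(tab, mcm_config(full_population_mode = TRUE,
                                 bootstrap_resamples = 20))
  expect_equal(res$n_dropped_rows, 2)
  expect_equal(res$power$N, nrow(tab) - 2)
})

test_that("results serialize to JSON with curve CSVs", {
  tab <- sim_table(308)
  res <- run_mcm(dplyr::select(tab, "scan_id", "label", "mean_distance",
                               "mean_intensity", "opa", "rugosity"),
                 mcm_config(full_population_mode = TRUE,
                            bootstrap_resamples = 20))
  json_path <- withr::local_tempfile(fileext = ".json")
  csv_path <- withr::local_tempfile(fileext = ".csv")
  write_mcm_result(res, json_path, csv_path)
  payload <- jsonlite::read_json(json_path)
  expect_equal(payload$method, res$method)
  expect_equal(payload$train$accuracy_pct,
               res$train_report$accuracy$accuracy_pct)
  expect_equal(payload$power$n, res$power$n)
  curves <- readr::read_csv(csv_path, show_col_types = FALSE)
  expect_setequal(unique(curves$kind), c("roc", "pr"))
  expect_setequal(unique(curves$set), c("training", "testing"))
})
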