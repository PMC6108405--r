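test_that("logistic slope equals the closed-form log odds ratio of a 2x2 table", {
  x <- c(rep(1, 50), rep(0, 50))
  y <- c(rep(1, 40), rep(0, 10), rep(1, 10), rep(0, 40))
  fit <- fit_logistic(matrix(x, dimnames = list(NULL, "exposure")), y)
  expect_true(fit$converged)
  expect_equal(unname(fit$beta["exposure"]), log(16), tolerance = 1e-4)
  expect_lt(fit$wald_p["exposure"], 0.001)
  expect_lt(fit$model_p, 0.001)
})

test_that("logistic Wald p-values are null-calibrated", {
  hits <- 0
  for (rep in 1:100) {
    set.seed(1000 + rep)
    x <- rnorm(500)
    y <- rbinom(500, 1, 0.5)
    fit <- fit_logistic(matrix(x, dimnames = list(NULL, "x")), y)
    if (fit$wald_p["x"] > 0.05) hits <- hits + 1
  }
  expect_gte(hits, 90)
})

test_that("logistic fit recovers generating coefficients within 3 SE", {
  ok <- 0
  for (rep in 1:100) {
    set.seed(2000 + rep)
    n <- 5000
    X <- cbind(a = rnorm(n), b = rnorm(n))
    beta_true <- c(0.5, -1.5, 2)   # intercept, a, b
    eta <- beta_true[1] + X %*% beta_true[2:3]
    y <- rbinom(n, 1, plogis(eta))
    fit <- fit_logistic(X, y)
    if (all(abs(fit$beta - beta_true) <= 3 * fit$se)) ok <- ok + 1
  }
  expect_gte(ok, 95)
})

test_that("complete separation leaves the MLE flagged non-converged", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8)
  y <- c(0, 0, 0, 0, 1, 1, 1, 1)
  fit <- fit_logistic(matrix(x, dimnames = list(NULL, "x")), y)
  expect_false(fit$converged)
})

test_that("rank-deficient predictors raise a collinearity error naming columns", {
  X <- cbind(a = rnorm(30), b = rnorm(30))
  X <- cbind(X, c = X[, "a"] * 2)
  y <- rbinom(30, 1, 0.5)
  y[1:2] <- c(0, 1)
  err <- tryCatch(fit_logistic(X, y), error = identity)
  expect_s3_class(err, "metaprop_collinearity_error")
  expect_true(any(c("a", "c") %in% err$aliased))
})

test_that("Firth regression yields finite converged estimates under separation", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8)
  y <- c(0, 0, 0, 0, 1, 1, 1, 1)
  fit <- fit_firth(matrix(x, dimnames = list(NULL, "x")), y)
  expect_true(fit$converged)
  expect_true(all(is.finite(fit$beta)))
  expect_true(all(is.finite(fit$se)))
  expect_gt(fit$beta["x"], 0)
})

test_that("the Firth penalty vanishes on large non-separated samples", {
  set.seed(99)
  n <- 2000
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.3 + 0.8 * x))
  std <- fit_logistic(matrix(x, dimnames = list(NULL, "x")), y)
  fir <- fit_firth(matrix(x, dimnames = list(NULL, "x")), y)
  expect_true(std$converged && fir$converged)
  expect_lt(abs(fir$beta["x"] - std$beta["x"]) / abs(std$beta["x"]), 0.02)
})

test_that("Firth estimates maximize the penalized likelihood (optim oracle)", {
  # 2x2 data with one zero cell: x=1 -> all successes
  x <- c(rep(1, 5), rep(0, 7))
  y <- c(rep(1, 5), rep(1, 2), rep(0, 5))
  fit <- fit_firth(matrix(x, dimnames = list(NULL, "x")), y)

  Xm <- cbind(1, x)
  pen_ll <- function(b) {
    p <- plogis(drop(Xm %*% b))
    w <- p * (1 - p)
    info <- t(Xm * w) %*% Xm
    sum(y * log(p) + (1 - y) * log(1 - p)) + 0.5 * log(det(info))
  }
  opt <- optim(c(0, 0), function(b) -pen_ll(b), method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  expect_equal(unname(fit$beta), opt$par, tolerance = 1e-3)
  expect_gte(pen_ll(unname(fit$beta)), opt$value * -1 - 1e-6)
})

test_that("influence diagnostics are calibrated and honor thresholds", {
  clean <- 0
  for (rep in 1:100) {
    set.seed(3000 + rep)
    # mild signal keeps fitted probabilities away from 0/1, where even
    # correctly generated observations produce large Pearson residuals
    x <- rnorm(500)
    y <- rbinom(500, 1, plogis(0.5 * x))
    fit <- fit_logistic(matrix(x, dimnames = list(NULL, "x")), y)
    d <- diagnose_influence(fit, matrix(x, dimnames = list(NULL, "x")), y)
    if (length(d$outliers) == 0) clean <- clean + 1
  }
  expect_gte(clean, 95)

  # planted contaminated point: extreme x with flipped response
  set.seed(4000)
  x <- c(rnorm(200), 8)
  y <- c(rbinom(200, 1, plogis(2 * x[1:200])), 0)
  fit <- fit_logistic(matrix(x, dimnames = list(NULL, "x")), y)
  d <- diagnose_influence(fit, matrix(x, dimnames = list(NULL, "x")), y)
  expect_true(201 %in% union(d$outliers, d$influential))

  # raising the residual threshold empties the outlier list
  loose <- mcm_config(residual_threshold = max(abs(d$diagnostics$std_pearson_residual)) + 1)
  d2 <- diagnose_influence(fit, matrix(x, dimnames = list(NULL, "x")), y, loose)
  expect_length(d2$outliers, 0)

  bad_fit <- fit_logistic(matrix(1:8, dimnames = list(NULL, "x")),
                          c(0, 0, 0, 0, 1, 1, 1, 1))
  expect_error(diagnose_influence(bad_fit, matrix(1:8), c(0, 0, 0, 0, 1, 1, 1, 1)),
               class = "metaprop_computation_error")
})

test_that("model reduction keeps converging full models and drops by Wald order", {
  set.seed(55)
  n <- 300
  X <- cbind(signal = rnorm(n), noise1 = rnorm(n), noise2 = rnorm(n))
  y <- rbinom(n, 1, plogis(2 * X[, "signal"]))
  fit <- reduce_model(X, y)
  expect_equal(sort(setdiff(fit$variable_names, "(Intercept)")),
               c("noise1", "noise2", "signal"))
  expect_length(fit$reduction_trace, 0)

  # pure-noise labels with an informative predictor present only weakly:
  # reduction follows descending Wald p until a converging model remains
  set.seed(56)
  n <- 120
  X <- cbind(signal = rnorm(n), n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n))
  y <- rbinom(n, 1, plogis(1.2 * X[, "signal"]))
  full <- fit_logistic(X, y)
  red <- reduce_model(X, y)
  expect_true("signal" %in% red$variable_names)
  if (length(red$reduction_trace) > 0) {
    # first variable dropped had the highest full-model Wald p
    noise_p <- full$wald_p[setdiff(full$variable_names, "(Intercept)")]
    expect_equal(red$reduction_trace[1], names(which.max(noise_p)))
  }
})

test_that("predictions are the inverse-logit of the linear predictor", {
  fit <- fit_logistic(matrix(rnorm(40), ncol = 2,
                             dimnames = list(NULL, c("a", "b"))),
                      rep(c(0, 1), 10))
  # all-zero coefficients -> probability one half
  fit0 <- fit
  fit0$beta[] <- 0
  X <- matrix(rnorm(20), ncol = 2, dimnames = list(NULL, c("a", "b")))
  expect_true(all(predict_classes(fit0, X)$probability == 0.5))

  # overflow guard: huge linear predictors stay inside (0, 1)
  fitg <- fit
  fitg$beta[] <- c(0, 1e6, -1e6)
  p <- predict_classes(fitg, X)$probability
  expect_true(all(p > 0 & p < 1))

  # direct matrix recomputation
  p2 <- predict_classes(fit, X)$probability
  eta <- cbind(1, X) %*% fit$beta
  expect_equal(p2, as.numeric(plogis(eta)), tolerance = 1e-12)

  # schema mismatch
  Xbad <- matrix(rnorm(10), ncol = 2, dimnames = list(NULL, c("a", "zz")))
  expect_error(predict_classes(fit, Xbad), class = "metaprop_schema_error")
})
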