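build_model_matrix <- function(X) {
  if (is.data.frame(X)) {
    bad <- names(X)[!vapply(X, is.numeric, logical(1))]
    if (length(bad) > 0) {
      stop_validation("non-numeric predictor column(s): %s", paste(bad, collapse = ", "))
    }
    X <- as.matrix(X)
  }
  if (!is.matrix(X)) X <- matrix(X, ncol = 1, dimnames = list(NULL, "x"))
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (any(!is.finite(X))) {
    stop_validation("predictor matrix contains missing or non-finite values")
  }
  Xm <- cbind("(Intercept)" = 1, X)
  qr_x <- qr(Xm)
  if (qr_x$rank < ncol(Xm)) {
    aliased <- colnames(Xm)[qr_x$pivot[(qr_x$rank + 1):ncol(Xm)]]
    rlang::abort(
      sprintf("predictor matrix is rank-deficient; aliased column(s): %s",
              paste(aliased, collapse = ", ")),
      class = c("metaprop_collinearity_error", "metaprop_validation_error"),
      aliased = aliased)
  }
  Xm
}

check_binary_response <- function(y, n) {
  if (length(y) != n) stop_validation("response length does not match predictors")
  if (any(is.na(y)) || !all(y %in% c(0, 1))) {
    stop_validation("response must be binary 0/1 with no missing values")
  }
  if (length(unique(y)) < 2) stop_validation("both classes must be present")
  as.numeric(y)
}

binomial_loglik <- function(y, p) {
  eps <- 1e-12
  p <- pmin(1 - eps, pmax(eps, p))
  sum(y * log(p) + (1 - y) * log(1 - p))
}

new_mcm_fit <- function(method, Xm, beta, se, converged, n_iterations,
                        log_likelihood, null_log_likelihood) {
  z <- beta / se
  wald_p <- 2 * pnorm(-abs(z))
  lr <- 2 * (log_likelihood - null_log_likelihood)
  df <- ncol(Xm) - 1L
  model_p <- if (df > 0) pchisq(max(0, lr), df = df, lower.tail = FALSE) else NA_real_
  structure(
    list(method = method,
         variable_names = colnames(Xm),
         beta = setNames(as.numeric(beta), colnames(Xm)),
         se = setNames(as.numeric(se), colnames(Xm)),
         wald_p = setNames(as.numeric(wald_p), colnames(Xm)),
         model_p = model_p,
         converged = converged,
         n_iterations = n_iterations,
         log_likelihood = log_likelihood,
         null_log_likelihood = null_log_likelihood,
         n_obs = nrow(Xm)),
    class = "mcm_fit"
  )
}

#' @export
print.mcm_fit <- function(x, ...) {
  cat(sprintf("<mcm_fit: %s logistic regression> %d obs, %s, model p = %s\n",
              x$method, x$n_obs,
              if (x$converged) "converged" else "NOT converged",
              format.pval(x$model_p, digits = 3)))
  print(tidy(x))
  invisible(x)
}

#' Binomial logistic regression with a divergence guard
#'
#' Maximum-likelihood logistic regression fitted by iteratively reweighted
#' least squares (via [stats::glm.fit()]). Per-coefficient p-values are
#' two-sided Wald tests of beta/SE against the standard normal; the
#' model-level p-value is the likelihood-ratio test against the
#' intercept-only model. `converged` is `FALSE` when the IRLS iteration cap
#' is hit, a coefficient exceeds the divergence guard, or the fit attains a
#' numerically perfect (zero-deviance) solution -- the signature of complete
#' separation, under which the MLE does not exist and [fit_firth()] should
#' be used instead.
#'
#' @param X Predictor matrix or data frame (no intercept column; one is
#'   added). Must be full rank.
#' @param y Binary 0/1 response.
#' @param max_iter IRLS iteration cap.
#' @param divergence_guard Absolute coefficient bound beyond which the fit
#'   is declared divergent.
#'
#' @return An object of class `mcm_fit` with elements `method`, `beta`,
#'   `se`, `wald_p`, `model_p`, `converged`, `n_iterations`,
#'   `log_likelihood`. Supports [tidy()] and [glance()].
#' @export
#'
#' @examples
#' x <- c(rep(0, 50), rep(1, 50))
#' y <- c(rep(0, 40), rep(1, 10), rep(0, 10), rep(1, 40))
#' fit_logistic(data.frame(exposure = x), y)  # slope = log(16)
fit_logistic <- function(X, y, max_iter = 25L, divergence_guard = 1e4) {
  Xm <- build_model_matrix(X)
  y <- check_binary_response(y, nrow(Xm))
  fit <- suppressWarnings(
    stats::glm.fit(Xm, y, family = binomial(),
                   control = list(maxit = max_iter))
  )
  beta <- coef(fit)
  p <- fit$fitted.values
  w <- pmax(p * (1 - p), 1e-12)
  info <- crossprod(Xm * sqrt(w))
  se <- sqrt(diag(solve(info)))
  ll <- binomial_loglik(y, p)
  null_ll <- binomial_loglik(y, mean(y))
  perfect <- fit$deviance < 1e-6
  converged <- fit$converged && !perfect && max(abs(beta)) < divergence_guard
  out <- new_mcm_fit("standard", Xm, beta, se, converged, fit$iter, ll, null_ll)
  out$fitted <- as.numeric(p)
  out
}

#' Firth's bias-reduced (penalized) logistic regression
#'
#' Maximizes the Jeffreys-prior penalized log-likelihood
#' `l(beta) + log det I(beta) / 2` by Newton iteration on the modified score
#' `U*(beta) = X' (y - p + h (1/2 - p))`, where `h` are the hat-matrix
#' leverages -- Firth's bias-reduction adjustment. Estimates are finite even
#' under complete separation, which is why the classification workflow
#' switches to this fit when any metaproperty completely separates the
#' classes. Standard errors come from the Fisher information at the
#' penalized optimum; the model-level p-value is a penalized likelihood
#' ratio test against the intercept-only penalized fit.
#'
#' @inheritParams fit_logistic
#' @param max_iter Newton iteration cap.
#' @param tol Convergence tolerance on the modified score.
#'
#' @return An `mcm_fit` with `method = "firth"`.
#' @export
#'
#' @examples
#' x <- c(1, 2, 3, 4, 5, 6)
#' y <- c(0, 0, 0, 1, 1, 1)  # completely separated
#' fit_firth(data.frame(x = x), y)$converged
fit_firth <- function(X, y, max_iter = 100L, tol = 1e-8) {
  Xm <- build_model_matrix(X)
  y <- check_binary_response(y, nrow(Xm))
  full <- firth_newton(Xm, y, max_iter, tol)
  null <- firth_newton(Xm[, 1, drop = FALSE], y, max_iter, tol)
  out <- new_mcm_fit("firth", Xm, full$beta, full$se, full$converged,
                     full$iter, full$penalized_ll, null$penalized_ll)
  out$log_likelihood_unpenalized <- full$ll
  out$fitted <- as.numeric(full$p)
  out
}

firth_newton <- function(Xm, y, max_iter, tol) {
  k <- ncol(Xm)
  beta <- rep(0, k)
  pll_at <- function(beta) {
    eta <- pmin(30, pmax(-30, drop(Xm %*% beta)))
    p <- plogis(eta)
    w <- pmax(p * (1 - p), 1e-12)
    info <- crossprod(Xm * sqrt(w))
    ll <- binomial_loglik(y, p)
    list(p = p, w = w, info = info,
         pll = ll + 0.5 * determinant(info, logarithm = TRUE)$modulus[1],
         ll = ll)
  }
  cur <- pll_at(beta)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    # leverages of the weighted design
    xw <- Xm * sqrt(cur$w)
    inv_info <- solve(cur$info)
    h <- rowSums((xw %*% inv_info) * xw)
    score <- drop(crossprod(Xm, y - cur$p + h * (0.5 - cur$p)))
    if (max(abs(score)) < tol) { converged <- TRUE; break }
    delta <- drop(inv_info %*% score)
    # step-halving on the penalized likelihood
    step <- 1
    repeat {
      cand <- pll_at(beta + step * delta)
      if (cand$pll >= cur$pll - 1e-10 || step < 1e-4) break
      step <- step / 2
    }
    beta <- beta + step * delta
    cur <- cand
  }
  se <- sqrt(diag(solve(cur$info)))
  list(beta = beta, se = se, converged = converged, iter = iter,
       penalized_ll = cur$pll, ll = cur$ll, p = cur$p)
}

#' Residual and influence diagnostics for a fitted classification model
#'
#' Standardized Pearson residuals and Cook's distances per observation.
#' Observations whose absolute standardized residual exceeds
#' `residual_threshold` (default 3) are listed as outliers; those whose
#' Cook's distance exceeds `cooks_threshold` (default 1.5) as influential.
#' The two lists are reported separately (an observation may be in both, or
#' in one only).
#'
#' @param fit A converged `mcm_fit`.
#' @param X,y The data the model was fitted on.
#' @param config An [mcm_config()] supplying the thresholds.
#'
#' @return A list with `outliers` and `influential` (integer row indices)
#'   and `diagnostics`, a tibble of per-observation leverage, standardized
#'   residual and Cook's distance.
#' @export
diagnose_influence <- function(fit, X, y, config = mcm_config()) {
  if (!inherits(fit, "mcm_fit")) stop_validation("`fit` must be an mcm_fit")
  if (!fit$converged) {
    stop_computation("cannot compute diagnostics on a non-converged fit")
  }
  Xm <- build_model_matrix(X)
  y <- check_binary_response(y, nrow(Xm))
  eta <- pmin(30, pmax(-30, drop(Xm %*% fit$beta[colnames(Xm)])))
  p <- plogis(eta)
  w <- pmax(p * (1 - p), 1e-12)
  xw <- Xm * sqrt(w)
  h <- rowSums((xw %*% solve(crossprod(xw))) * xw)
  pearson <- (y - p) / sqrt(w)
  std_resid <- pearson / sqrt(pmax(1 - h, 1e-12))
  k <- ncol(Xm)
  cooks <- std_resid^2 * h / (k * pmax(1 - h, 1e-12))
  tab <- tibble::tibble(
    row = seq_along(y), leverage = h,
    std_pearson_residual = std_resid, cooks_distance = cooks
  )
  list(
    outliers = tab$row[abs(tab$std_pearson_residual) > config$residual_threshold],
    influential = tab$row[tab$cooks_distance > config$cooks_threshold],
    diagnostics = tab
  )
}

#' Backwards model reduction until convergence
#'
#' If the full model converges at the model level (likelihood-ratio p-value
#' below `config$alpha`), it is returned unchanged -- even when individual
#' coefficients are non-significant, which guards against overfitting by
#' variable shopping. Otherwise the predictor with the largest Wald p-value
#' is dropped and the model refitted on the same data, repeating until the
#' model converges or no predictors remain.
#'
#' @param X,y Training predictors and binary response.
#' @param config An [mcm_config()].
#' @param method `"standard"` or `"firth"`.
#'
#' @return The selected `mcm_fit`, with a `reduction_trace` element listing
#'   the variables dropped in order (empty when the full model was kept).
#' @export
reduce_model <- function(X, y, config = mcm_config(),
                         method = c("standard", "firth")) {
  method <- match.arg(method)
  fitter <- if (method == "firth") fit_firth else fit_logistic
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X)) X <- matrix(X, ncol = 1, dimnames = list(NULL, "x"))
  trace <- character(0)
  repeat {
    fit <- fitter(X, y)
    ok <- fit$converged && !is.na(fit$model_p) && fit$model_p < config$alpha
    if (ok) {
      fit$reduction_trace <- trace
      return(fit)
    }
    candidates <- setdiff(fit$variable_names, "(Intercept)")
    if (length(candidates) <= 1) {
      stop_computation("model reduction exhausted all predictors without convergence")
    }
    drop_var <- candidates[which.max(fit$wald_p[candidates])]
    trace <- c(trace, drop_var)
    X <- X[, setdiff(colnames(X), drop_var), drop = FALSE]
  }
}

#' Predict probabilities and classes from a fitted model
#'
#' Applies the inverse logit to the linear predictor formed from the fit's
#' coefficients; linear predictors are clipped at +/-30 so extreme fits
#' yield probabilities strictly inside (0, 1) without overflow. The class is
#' 1 when the probability reaches `config$classification_threshold`
#' (default 0.5).
#'
#' @param fit An `mcm_fit`.
#' @param X New data with exactly the predictor columns the model was
#'   fitted on.
#' @param config An [mcm_config()].
#'
#' @return A tibble with columns `probability` and `class`.
#' @export
predict_classes <- function(fit, X, config = mcm_config()) {
  if (!inherits(fit, "mcm_fit")) stop_validation("`fit` must be an mcm_fit")
  vars <- setdiff(fit$variable_names, "(Intercept)")
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X)) X <- matrix(X, ncol = 1, dimnames = list(NULL, vars[1]))
  if (!all(vars %in% colnames(X))) {
    rlang::abort(sprintf("new data lacks predictor column(s): %s",
                         paste(setdiff(vars, colnames(X)), collapse = ", ")),
                 class = c("metaprop_schema_error", "metaprop_validation_error"))
  }
  Xm <- cbind(1, X[, vars, drop = FALSE])
  eta <- drop(Xm %*% fit$beta[c("(Intercept)", vars)])
  eta <- pmin(30, pmax(-30, eta))
  prob <- plogis(eta)
  tibble::tibble(probability = prob,
                 class = as.integer(prob >= config$classification_threshold))
}
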