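#' The five baseline-handling strategies
#'
#' Closed enumeration of the analysis methods compared by the package:
#' \describe{
#'   \item{FINAL}{endpoint LAZ regressed on arm only.}
#'   \item{ADJUST}{endpoint LAZ regressed on arm and baseline LAZ (ANCOVA).}
#'   \item{DELTA}{change from baseline regressed on arm.}
#'   \item{DELTA_ADJUST}{change from baseline regressed on arm and baseline;
#'     an exact reparameterization of ADJUST.}
#'   \item{RESIDUALS}{two steps: endpoint regressed on baseline alone, then
#'     those residuals regressed on arm.}
#' }
#' @export
laz_methods <- c("FINAL", "ADJUST", "DELTA", "DELTA_ADJUST", "RESIDUALS")

#' Ordinary least squares with t-based inference
#'
#' Thin wrapper over the QR fitter in `stats::lm.fit`, returning estimates,
#' standard errors from the unbiased residual-variance estimator, and
#' two-sided t p-values.  Used instead of `stats::lm()` because the
#' simulation grids perform on the order of 10^5 fits; agreement with
#' `stats::lm` is exact (same QR path) and verified in the test suite.
#'
#' @param response Numeric response vector, no missing values.
#' @param predictors Named list of predictor vectors (an intercept is added).
#' @return List of class `laz_ols`: `estimate`, `se`, `t`, `p_value` (named,
#'   first name `(Intercept)`), `residuals`, `fitted`, `df`, `sigma`.
#' @export
least_squares <- function(response, predictors = list()) {
  y <- as.numeric(response)
  n <- length(y)
  X <- cbind(`(Intercept)` = rep(1, n))
  if (length(predictors)) {
    if (is.null(names(predictors)) || any(names(predictors) == ""))
      names(predictors) <- paste0("x", seq_along(predictors))
    for (nm in names(predictors)) {
      v <- as.numeric(predictors[[nm]])
      if (length(v) != n)
        stop("predictor `", nm, "` must match the response in length", call. = FALSE)
      X <- cbind(X, v)
    }
    colnames(X) <- c("(Intercept)", names(predictors))
  }
  if (anyNA(y) || anyNA(X))
    stop("missing values are not supported", call. = FALSE)
  k <- ncol(X)
  if (n <= k)
    stop("need more observations than coefficients (", n, " vs ", k, ")", call. = FALSE)
  fit <- stats::lm.fit(X, y)
  if (fit$rank < k) {
    piv <- fit$qr$pivot
    bad <- colnames(X)[piv[(fit$rank + 1):k]]
    stop("rank-deficient design: column(s) ", paste(bad, collapse = ", "),
         " are collinear", call. = FALSE)
  }
  df <- n - k
  s2 <- sum(fit$residuals^2) / df
  R <- qr.R(fit$qr)
  xtx_inv <- chol2inv(R)
  piv <- fit$qr$pivot
  cov <- matrix(0, k, k)
  cov[piv, piv] <- s2 * xtx_inv
  est <- fit$coefficients[colnames(X)]
  se <- sqrt(diag(cov))
  names(se) <- colnames(X)
  tval <- est / se
  structure(
    list(estimate = est, se = se, t = tval,
         p_value = 2 * stats::pt(-abs(tval), df),
         residuals = as.numeric(fit$residuals),
         fitted = as.numeric(fit$fitted.values),
         df = df, sigma = sqrt(s2)),
    class = "laz_ols"
  )
}

#' Estimate the intervention effect in one simulated trial
#'
#' Fits the requested baseline-handling strategy at a post-baseline
#' timepoint and returns the arm coefficient (the intervention effect on
#' LAZ) with its standard error, Wald t confidence interval and two-sided
#' p-value.
#'
#' The regressions, with `y_i` the endpoint LAZ, `y_0` the baseline and `x`
#' the arm indicator:
#' \itemize{
#'   \item FINAL:        `y_i ~ x`
#'   \item ADJUST:       `y_i ~ x + y_0`
#'   \item DELTA:        `(y_i - y_0) ~ x`
#'   \item DELTA_ADJUST: `(y_i - y_0) ~ x + y_0`
#'   \item RESIDUALS:    `y_i ~ y_0`, then its residuals `~ x`
#' }
#' The RESIDUALS second stage uses the naive OLS standard error, as the
#' two-step recipe is written; no first-stage degrees-of-freedom correction.
#'
#' @param trial A `laz_trial` from [simulate_trial()].
#' @param timepoint A post-baseline age (months) present in the trial.
#' @param method One of [laz_methods].
#' @param alpha Two-sided significance level for the confidence interval.
#' @return Object of class `laz_fit`: `method`, `timepoint`, `beta1`, `se`,
#'   `ci_low`, `ci_high`, `p_value`, `n_used`, plus the full auxiliary
#'   `coefficients` record of the fitted regression(s).
#' @examples
#' trial <- simulate_trial(n = 500, seed = 7)
#' estimate_effect(trial, 24, "ADJUST")
#' @export
estimate_effect <- function(trial, timepoint, method = laz_methods,
                            alpha = 0.05) {
  stopifnot(inherits(trial, "laz_trial"))
  method <- match.arg(method)
  j <- match(timepoint, trial$timepoints)
  if (is.na(j) || j == 1)
    stop("`timepoint` must be a post-baseline timepoint of the trial", call. = FALSE)
  arm <- trial$arm
  if (length(unique(arm)) < 2)
    stop("only one arm present: the intervention effect is undefined", call. = FALSE)
  y0 <- trial$laz[, 1]
  yi <- trial$laz[, j]
  aux <- NULL
  fit <- switch(
    method,
    FINAL = least_squares(yi, list(arm = arm)),
    ADJUST = least_squares(yi, list(arm = arm, baseline = y0)),
    DELTA = least_squares(yi - y0, list(arm = arm)),
    DELTA_ADJUST = least_squares(yi - y0, list(arm = arm, baseline = y0)),
    RESIDUALS = {
      stage1 <- least_squares(yi, list(baseline = y0))
      aux <- stage1
      least_squares(stage1$residuals, list(arm = arm))
    }
  )
  beta1 <- unname(fit$estimate["arm"])
  se <- unname(fit$se["arm"])
  crit <- stats::qt(1 - alpha / 2, fit$df)
  structure(
    list(method = method, timepoint = timepoint, beta1 = beta1, se = se,
         ci_low = beta1 - crit * se, ci_high = beta1 + crit * se,
         p_value = unname(fit$p_value["arm"]), n_used = trial$n,
         df = fit$df, alpha = alpha,
         coefficients = fit$estimate, coefficient_se = fit$se,
         stage1 = aux),
    class = "laz_fit"
  )
}

#' @export
print.laz_fit <- function(x, ...) {
  cat(sprintf("%s estimate at %g months (n = %d):\n", x$method, x$timepoint, x$n_used))
  cat(sprintf("  beta1 = %.4f (SE %.4f), %g%% CI [%.4f, %.4f], p = %.3g\n",
              x$beta1, x$se, 100 * (1 - x$alpha), x$ci_low, x$ci_high, x$p_value))
  invisible(x)
}

#' @export
coef.laz_fit <- function(object, ...) object$coefficients

#' @export
confint.laz_fit <- function(object, ...) {
  out <- matrix(c(object$ci_low, object$ci_high), 1,
                dimnames = list("arm", c("low", "high")))
  out
}

#' Collect fit results into a data frame
#'
#' One row per fit: `method`, `timepoint`, `beta1`, `se`, `ci_low`,
#' `ci_high`, `p_value`, `n_used` -- the layout used for CSV export.
#'
#' @param fits A list of `laz_fit` objects.
#' @export
fits_to_df <- function(fits) {
  stopifnot(length(fits) > 0, all(vapply(fits, inherits, TRUE, "laz_fit")))
  do.call(rbind, lapply(fits, function(f)
    data.frame(method = f$method, timepoint = f$timepoint, beta1 = f$beta1,
               se = f$se, ci_low = f$ci_low, ci_high = f$ci_high,
               p_value = f$p_value, n_used = f$n_used)))
}
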