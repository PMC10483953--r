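#' Expected baseline imbalance under linear selection
#'
#' Exact conditional-expectation algebra for a normal baseline under a
#' linear allocation probability `p(z) = a + b z`: with `pbar = a + b mu0`
#' and `E[Z p(Z)] = a mu0 + b (mu0^2 + sigma0^2)`, the expected difference
#' in mean baseline LAZ (intervention minus control) is
#' `E[Z p]/pbar - E[Z (1 - p)]/(1 - pbar)`, which simplifies to
#' `b sigma0^2 / (pbar (1 - pbar))`.  Clamping of the allocation
#' probability is ignored; it never binds for realistic LAZ.
#'
#' @param params A [laz_population()] object (only the baseline moments are
#'   used).
#' @param rule An [allocation_rule()] object.
#' @return Expected `mean(LAZ0 | arm = 1) - mean(LAZ0 | arm = 0)`.
#' @export
expected_baseline_imbalance <- function(params, rule) {
  stopifnot(inherits(params, "laz_population"), inherits(rule, "laz_allocation"))
  mu0 <- params$mu[1]
  s0 <- params$sigma[1]
  pbar <- rule$intercept + rule$slope * mu0
  if (pbar <= 0 || pbar >= 1)
    stop("mean allocation probability ", format(pbar), " lies outside (0, 1)",
         call. = FALSE)
  ezp <- rule$intercept * mu0 + rule$slope * (mu0^2 + s0^2)
  ezp / pbar - (mu0 - ezp) / (1 - pbar)
}

# Population regression slope of LAZ at `timepoint` on baseline LAZ:
# rho_{0i} * sigma_i / sigma_0.
baseline_slope <- function(params, timepoint) {
  j <- match(timepoint, params$timepoints)
  if (is.na(j) || j == 1)
    stop("unknown or baseline timepoint: ", timepoint, call. = FALSE)
  params$corr[1, j] * params$sigma[j] / params$sigma[1]
}

#' Expected estimator bias under a baseline imbalance
#'
#' First-order expected bias of the arm coefficient when the arms differ by
#' `delta0` in mean baseline LAZ.  FINAL inherits the imbalance propagated
#' through the population regression slope of endpoint on baseline
#' (`rho_{0i} sigma_i / sigma_0`); DELTA forces that slope to 1, so its bias
#' has the opposite sign whenever the slope is below 1; the covariate-
#' adjusted methods are unbiased.  RESIDUALS is 0 to first order: its exact
#' bias carries second-order terms of order `delta0^2 / sigma0^2` and
#' `delta * delta0 / sigma0^2`, negligible at the imbalances considered.
#'
#' @param method One of [laz_methods].
#' @param timepoint Post-baseline age in months.
#' @param params A [laz_population()] object.
#' @param delta0 Mean baseline difference, intervention minus control (LAZ).
#' @return Expected bias of the effect estimate (z-score units).
#' @export
expected_bias <- function(method = laz_methods, timepoint, params, delta0) {
  method <- match.arg(method)
  b <- baseline_slope(params, timepoint)
  switch(method,
         FINAL = b * delta0,
         DELTA = (b - 1) * delta0,
         ADJUST = 0,
         DELTA_ADJUST = 0,
         RESIDUALS = 0)
}

#' Per-arm residual variance of the analyzed outcome
#'
#' The variance governing the precision of each strategy's effect estimate:
#' `sigma_i^2` for FINAL, `sigma_i^2 + sigma_0^2 - 2 rho sigma_i sigma_0`
#' for DELTA (variance of the change score), and
#' `sigma_i^2 (1 - rho^2)` for the baseline-adjusted methods.  The sampling
#' variance of the arm coefficient is approximately `4 * factor / n` under
#' an even split.
#'
#' @inheritParams expected_bias
#' @return Variance in squared z-score units.
#' @export
variance_factor <- function(method = laz_methods, timepoint, params) {
  method <- match.arg(method)
  j <- match(timepoint, params$timepoints)
  if (is.na(j) || j == 1)
    stop("unknown or baseline timepoint: ", timepoint, call. = FALSE)
  si <- params$sigma[j]
  s0 <- params$sigma[1]
  rho <- params$corr[1, j]
  switch(method,
         FINAL = si^2,
         DELTA = si^2 + s0^2 - 2 * rho * si * s0,
         ADJUST = ,
         DELTA_ADJUST = ,
         RESIDUALS = si^2 * (1 - rho^2))
}

#' Normal-approximation power
#'
#' Two-tailed normal approximation to the power of the two-sided level-alpha
#' test of the arm coefficient, assuming an even split of `n` children:
#' with `lambda = |delta_i| / sqrt(4 * variance_factor / n)`, power is
#' `pnorm(lambda - z) + pnorm(-lambda - z)` where `z = qnorm(1 - alpha/2)`.
#' At a null effect this returns exactly `alpha`.  A validation aid for the
#' simulated power curves, not a replacement for them.
#'
#' @inheritParams expected_bias
#' @param n Total enrolment.
#' @param effect An [effect_profile()] object.
#' @param alpha Two-sided significance level.
#' @export
approximate_power <- function(method = laz_methods, timepoint, n, params,
                              effect, alpha = 0.05) {
  method <- match.arg(method)
  j <- match(timepoint, params$timepoints)
  if (is.na(j) || j == 1)
    stop("unknown or baseline timepoint: ", timepoint, call. = FALSE)
  vf <- variance_factor(method, timepoint, params)
  lambda <- abs(effect$delta[j]) / sqrt(4 * vf / n)
  z <- stats::qnorm(1 - alpha / 2)
  stats::pnorm(lambda - z) + stats::pnorm(-lambda - z)
}
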