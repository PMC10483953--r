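#' Growth-population parameters for the LAZ trial simulator
#'
#' Defines the joint distribution of length-for-age z-scores (LAZ) across
#' measurement ages: a mean and standard deviation per timepoint plus the
#' correlation matrix between timepoints.  Simulated children are drawn from
#' the multivariate normal distribution with these moments.
#'
#' The defaults are the moments of a South-Asian birth-cohort population with
#' progressive growth faltering: mean LAZ declines from -1.10 at birth to
#' -2.03 at 24 months, and the correlation between baseline and later
#' measurements decays from 0.61 (6 months) to 0.44 (24 months).
#'
#' @param timepoints Measurement ages in months, strictly increasing; the
#'   first is the baseline.
#' @param mu Mean LAZ at each timepoint (z-score units).
#' @param sigma Standard deviation of LAZ at each timepoint; all positive.
#' @param corr Correlation matrix between timepoints: symmetric, unit
#'   diagonal, positive semi-definite.
#'
#' @return An object of class `laz_population`.
#' @seealso [build_covariance()], [draw_growth_curves()]
#' @examples
#' pop <- laz_population()
#' pop$mu
#' build_covariance(pop)
#' @export
laz_population <- function(timepoints = c(0, 6, 12, 18, 24),
                           mu = c(-1.10, -1.19, -1.66, -1.95, -2.03),
                           sigma = c(1.03, 0.97, 0.93, 0.93, 0.94),
                           corr = default_laz_correlation()) {
  k <- length(timepoints)
  if (length(mu) != k || length(sigma) != k)
    stop("`timepoints`, `mu` and `sigma` must have the same length", call. = FALSE)
  if (k < 2 || is.unsorted(timepoints, strictly = TRUE))
    stop("`timepoints` must be at least two strictly increasing ages", call. = FALSE)
  if (any(!is.finite(sigma)) || any(sigma <= 0))
    stop("all `sigma` must be positive and finite", call. = FALSE)
  corr <- as.matrix(corr)
  if (!identical(dim(corr), c(k, k)))
    stop("`corr` must be a ", k, " x ", k, " matrix", call. = FALSE)
  if (max(abs(corr - t(corr))) > 1e-12)
    stop("`corr` must be symmetric", call. = FALSE)
  if (max(abs(diag(corr) - 1)) > 1e-12)
    stop("`corr` must have a unit diagonal", call. = FALSE)
  if (any(corr < -1 - 1e-12) || any(corr > 1 + 1e-12))
    stop("correlations must lie in [-1, 1]", call. = FALSE)
  ev <- min(eigen(corr, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-8)
    stop("`corr` is not positive semi-definite (smallest eigenvalue ",
         format(ev), ")", call. = FALSE)
  dimnames(corr) <- list(timepoints, timepoints)
  structure(
    list(timepoints = as.numeric(timepoints), mu = as.numeric(mu),
         sigma = as.numeric(sigma), corr = corr),
    class = "laz_population"
  )
}

#' Default inter-timepoint LAZ correlation matrix
#'
#' Lower-triangle entries, by row for ages (6, 12, 18, 24) months against all
#' earlier ages: 0.61; 0.47, 0.87; 0.46, 0.80, 0.90; 0.44, 0.76, 0.88, 0.95.
#'
#' @return A 5 x 5 correlation matrix.
#' @export
default_laz_correlation <- function() {
  correlation_from_lower(
    c(0.61,
      0.47, 0.87,
      0.46, 0.80, 0.90,
      0.44, 0.76, 0.88, 0.95),
    k = 5
  )
}

#' Assemble a correlation matrix from its strict lower triangle
#'
#' @param lower Strict lower-triangle entries in row-major order (row 2
#'   against column 1; row 3 against columns 1, 2; ...).
#' @param k Matrix dimension.
#' @return A symmetric `k` x `k` matrix with unit diagonal.
#' @export
correlation_from_lower <- function(lower, k) {
  if (length(lower) != k * (k - 1) / 2)
    stop("`lower` must have length k*(k-1)/2 = ", k * (k - 1) / 2, call. = FALSE)
  m <- diag(k)
  m[upper.tri(m)] <- 0
  idx <- which(lower.tri(m), arr.ind = TRUE)
  idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
  m[idx] <- lower
  m[idx[, c(2, 1), drop = FALSE]] <- lower
  m
}

#' Extract the strict lower triangle of a correlation matrix, row-major
#' @param corr A square symmetric matrix.
#' @return Numeric vector of the entries below the diagonal, by row.
#' @export
correlation_to_lower <- function(corr) {
  corr <- as.matrix(corr)
  idx <- which(lower.tri(corr), arr.ind = TRUE)
  idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
  unname(corr[idx])
}

#' Cumulative intervention-effect profile
#'
#' The intervention is modelled as an additive shift in mean LAZ that
#' accumulates over follow-up; the default is +0.05 LAZ per 6 months, i.e.
#' 0.05 at 6 months up to 0.20 at 24 months.  The baseline entry must be 0:
#' baseline precedes the intervention.
#'
#' @param delta Additive effect on LAZ at each timepoint (z-score units);
#'   first entry 0.
#' @param timepoints Ages the entries refer to (months).
#' @return An object of class `laz_effect_profile`.
#' @export
effect_profile <- function(delta = c(0, 0.05, 0.10, 0.15, 0.20),
                           timepoints = c(0, 6, 12, 18, 24)) {
  if (length(delta) != length(timepoints))
    stop("`delta` must match `timepoints` in length", call. = FALSE)
  if (delta[1] != 0)
    stop("the baseline effect must be exactly 0 (baseline precedes the intervention)",
         call. = FALSE)
  structure(list(delta = as.numeric(delta), timepoints = as.numeric(timepoints)),
            class = "laz_effect_profile")
}

#' Arm-allocation rule
#'
#' Children are assigned to the intervention arm by independent Bernoulli
#' draws.  Under the balanced rule the probability is 0.5 for everyone.
#' Under the imbalanced rule the probability is a linear function of baseline
#' LAZ, `intercept + slope * LAZ0` (default 0.47 - 0.03 * LAZ0, so shorter
#' children are more likely to receive the intervention, inducing a baseline
#' imbalance of about -0.13 LAZ in the intervention arm).  The reversed
#' variant flips the slope sign, putting the imbalance in the direction of
#' the intervention effect.
#'
#' Probabilities are clamped to \[0.01, 0.99\] before the draw; with the
#' default baseline distribution the clamp never binds in practice.
#'
#' @param kind One of `"balanced"`, `"imbalanced"`, `"imbalanced_reversed"`.
#' @param intercept,slope Override the linear allocation probability; ignored
#'   for `"balanced"` (which is always 0.5).
#' @return An object of class `laz_allocation`.
#' @export
allocation_rule <- function(kind = c("balanced", "imbalanced", "imbalanced_reversed"),
                            intercept = NULL, slope = NULL) {
  kind <- match.arg(kind)
  if (kind == "balanced") {
    if (!is.null(intercept) || !is.null(slope))
      stop("the balanced rule has intercept 0.5 and slope 0; do not override",
           call. = FALSE)
    intercept <- 0.5
    slope <- 0
  } else {
    if (is.null(intercept)) intercept <- 0.47
    if (is.null(slope)) slope <- if (kind == "imbalanced_reversed") 0.03 else -0.03
    if (kind == "imbalanced" && slope > 0)
      warning("positive slope under kind = 'imbalanced' reverses the imbalance direction")
  }
  structure(list(kind = kind, intercept = intercept, slope = slope),
            class = "laz_allocation")
}

#' Covariance matrix implied by population parameters
#'
#' Converts the (SD, correlation) parameterization into the sampling
#' covariance, `Sigma[s, t] = corr[s, t] * sigma[s] * sigma[t]`.
#'
#' @param params A [laz_population()] object.
#' @return Symmetric positive semi-definite matrix with diagonal `sigma^2`.
#' @export
build_covariance <- function(params) {
  stopifnot(inherits(params, "laz_population"))
  sigma <- outer(params$sigma, params$sigma) * params$corr
  ev <- min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-8)
    stop("assembled covariance is not positive semi-definite (smallest eigenvalue ",
         format(ev), "); check the supplied correlation matrix", call. = FALSE)
  dimnames(sigma) <- dimnames(params$corr)
  sigma
}

#' @export
print.laz_population <- function(x, ...) {
  cat("LAZ growth population over", length(x$timepoints), "timepoints (months):",
      paste(x$timepoints, collapse = ", "), "\n")
  tab <- rbind(mean = x$mu, sd = x$sigma)
  colnames(tab) <- x$timepoints
  print(round(tab, 3))
  cat("correlation:\n")
  print(round(x$corr, 2))
  invisible(x)
}

#' @export
print.laz_effect_profile <- function(x, ...) {
  cat("Cumulative intervention effect on LAZ:\n")
  tab <- rbind(delta = x$delta)
  colnames(tab) <- x$timepoints
  print(tab)
  invisible(x)
}

#' @export
print.laz_allocation <- function(x, ...) {
  cat("Allocation rule:", x$kind, "\n")
  cat(sprintf("  P(intervention | LAZ0) = %g %+g * LAZ0 (clamped to [0.01, 0.99])\n",
              x$intercept, x$slope))
  invisible(x)
}
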