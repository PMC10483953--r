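#' Draw correlated LAZ growth curves
#'
#' Samples `n` children i.i.d. from the multivariate normal distribution with
#' mean `params$mu` and covariance [build_covariance()]. Uses the current RNG
#' stream; seed it (or use [simulate_trial()]) for reproducibility.
#'
#' @param params A [laz_population()] object.
#' @param n Number of children; at least 2 (regressions are fit later).
#' @return An `n` x T matrix of LAZ values, columns named `laz_<age>`.
#' @export
draw_growth_curves <- function(params, n) {
  stopifnot(inherits(params, "laz_population"))
  if (!is.numeric(n) || length(n) != 1 || n < 2)
    stop("`n` must be a single count >= 2", call. = FALSE)
  sigma <- build_covariance(params)
  curves <- MASS::mvrnorm(n, mu = params$mu, Sigma = sigma)
  colnames(curves) <- paste0("laz_", params$timepoints)
  curves
}

#' Per-child intervention-allocation probabilities
#'
#' @param rule An [allocation_rule()] object.
#' @param baseline_laz Baseline LAZ values.
#' @return Probabilities clamped to \[0.01, 0.99\].
#' @export
allocation_prob <- function(rule, baseline_laz) {
  stopifnot(inherits(rule, "laz_allocation"))
  if (any(!is.finite(baseline_laz)))
    stop("`baseline_laz` must be finite", call. = FALSE)
  pmin(pmax(rule$intercept + rule$slope * baseline_laz, 0.01), 0.99)
}

#' Assign children to trial arms
#'
#' Independent Bernoulli assignment with probability [allocation_prob()];
#' under the balanced rule every child has probability exactly 0.5.
#'
#' @inheritParams allocation_prob
#' @return Integer 0/1 vector (1 = intervention).
#' @export
allocate_arms <- function(baseline_laz, rule) {
  p <- allocation_prob(rule, baseline_laz)
  stats::rbinom(length(baseline_laz), 1L, p)
}

#' Add the intervention effect to simulated curves
#'
#' Adds `effect$delta[t]` to column `t` for intervention-arm children.
#' Control-arm rows and the baseline column are unchanged (bitwise: adding
#' zero).
#'
#' @param curves Matrix from [draw_growth_curves()].
#' @param arm 0/1 vector, one entry per row of `curves`.
#' @param effect An [effect_profile()] object.
#' @return Matrix of the same shape as `curves`.
#' @export
apply_intervention <- function(curves, arm, effect) {
  stopifnot(inherits(effect, "laz_effect_profile"))
  if (nrow(curves) != length(arm))
    stop("`arm` must have one entry per row of `curves`", call. = FALSE)
  if (ncol(curves) != length(effect$delta))
    stop("`effect` must cover every timepoint column of `curves`", call. = FALSE)
  if (effect$delta[1] != 0)
    stop("nonzero effect at baseline: baseline precedes the intervention", call. = FALSE)
  if (!all(arm %in% c(0, 1)))
    stop("`arm` must contain only 0/1", call. = FALSE)
  curves + outer(as.numeric(arm), effect$delta)
}

#' Simulate one two-arm growth trial
#'
#' Composes the generator: draw correlated growth curves, allocate arms on
#' the (pre-effect) baseline column, then add the intervention effect.
#' Deterministic given `seed`; the caller's RNG state is restored on exit
#' when a seed is supplied.
#'
#' @param params A [laz_population()] object.
#' @param effect An [effect_profile()] object.
#' @param rule An [allocation_rule()] object.
#' @param n Number of children enrolled.
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @return An object of class `laz_trial`: list with `laz` (n x T matrix),
#'   `arm` (0/1), `n`, `timepoints`, and `seed_record`.
#' @examples
#' trial <- simulate_trial(n = 200, seed = 1)
#' summary(trial)
#' @export
simulate_trial <- function(params = laz_population(),
                           effect = effect_profile(),
                           rule = allocation_rule("balanced"),
                           n, seed = NULL) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed), kind = "Mersenne-Twister",
             normal.kind = "Inversion", sample.kind = "Rejection")
  }
  curves <- draw_growth_curves(params, n)
  arm <- allocate_arms(curves[, 1], rule)
  laz <- apply_intervention(curves, arm, effect)
  structure(
    list(laz = laz, arm = arm, n = as.integer(n),
         timepoints = params$timepoints,
         seed_record = if (is.null(seed)) NA_integer_ else as.integer(seed)),
    class = "laz_trial"
  )
}

#' @export
print.laz_trial <- function(x, ...) {
  cat("Simulated two-arm LAZ trial:", x$n, "children,",
      sum(x$arm), "intervention /", sum(x$arm == 0), "control\n")
  cat("timepoints (months):", paste(x$timepoints, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.laz_trial <- function(object, ...) {
  by_arm <- rbind(
    control = colMeans(object$laz[object$arm == 0, , drop = FALSE]),
    intervention = colMeans(object$laz[object$arm == 1, , drop = FALSE])
  )
  out <- list(n = object$n, n_intervention = sum(object$arm),
              mean_laz_by_arm = by_arm,
              baseline_difference = by_arm[2, 1] - by_arm[1, 1])
  class(out) <- "summary.laz_trial"
  out
}

#' @export
print.summary.laz_trial <- function(x, ...) {
  cat("Two-arm LAZ trial,", x$n, "children (", x$n_intervention, "intervention )\n")
  cat("mean LAZ by arm:\n")
  print(round(x$mean_laz_by_arm, 3))
  cat(sprintf("baseline difference (intervention - control): %.3f LAZ\n",
              x$baseline_difference))
  invisible(x)
}

#' Convert a simulated trial to a data frame
#'
#' Columns: `child_id`, `arm`, then one `laz_<age>` column per timepoint --
#' the layout used for CSV export.
#'
#' @param x A `laz_trial` object.
#' @param ... Unused.
#' @export
as.data.frame.laz_trial <- function(x, ...) {
  data.frame(child_id = seq_len(x$n), arm = x$arm, x$laz)
}

#' Write a simulated trial to CSV
#'
#' One header row, UTF-8, '.' decimal separator.
#'
#' @param trial A `laz_trial` object.
#' @param path Output file path.
#' @export
write_trial <- function(trial, path) {
  utils::write.csv(as.data.frame(trial), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
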