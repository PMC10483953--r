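#' Operating characteristics of a replicate set
#'
#' Summarizes the effect estimates of one (method, timepoint, n) cell over
#' simulation replicates: median estimate, empirical 95% uncertainty
#' interval (2.5th/97.5th percentiles, linear-interpolation convention),
#' bias (median minus truth), mean standard error, power (fraction of
#' two-sided p below `alpha`) and coverage (fraction of confidence
#' intervals containing the truth).
#'
#' @param fits List of `laz_fit` objects (or a data frame from
#'   [fits_to_df()]) sharing method, timepoint and n.
#' @param true_effect The simulated effect at this timepoint (z-score units).
#' @param alpha Significance level used for the power criterion.
#' @return One-row data frame with columns `method`, `timepoint`,
#'   `true_effect`, `median_estimate`, `ui_low`, `ui_high`, `bias`,
#'   `mean_se`, `power`, `coverage`, `n_replicates`.
#' @export
summarize_replicates <- function(fits, true_effect, alpha = 0.05) {
  df <- if (is.data.frame(fits)) fits else fits_to_df(fits)
  if (nrow(df) < 2)
    stop("need at least 2 replicates to summarize", call. = FALSE)
  if (length(unique(df$method)) != 1 || length(unique(df$timepoint)) != 1 ||
      length(unique(df$n_used)) != 1)
    stop("all fits must share method, timepoint and n", call. = FALSE)
  ui <- unname(stats::quantile(df$beta1, c(0.025, 0.975), type = 7))
  med <- stats::median(df$beta1)
  data.frame(
    method = df$method[1],
    timepoint = df$timepoint[1],
    true_effect = true_effect,
    median_estimate = med,
    ui_low = ui[1],
    ui_high = ui[2],
    bias = med - true_effect,
    mean_se = mean(df$se),
    power = mean(df$p_value < alpha),
    coverage = mean(df$ci_low <= true_effect & true_effect <= df$ci_high),
    n_replicates = nrow(df)
  )
}

#' Test for baseline imbalance between arms
#'
#' Regresses baseline LAZ on the arm indicator.  The slope is the mean
#' baseline difference (intervention minus control); its two-sided t test is
#' the imbalance diagnostic reported per trial.
#'
#' @param trial A `laz_trial` object with both arms present.
#' @param alpha Significance level for the flag.
#' @return List with `difference` (LAZ), `p_value`, and `significant`.
#' @export
baseline_imbalance_test <- function(trial, alpha = 0.05) {
  stopifnot(inherits(trial, "laz_trial"))
  if (length(unique(trial$arm)) < 2)
    stop("only one arm present: imbalance is undefined", call. = FALSE)
  fit <- least_squares(trial$laz[, 1], list(arm = trial$arm))
  list(difference = unname(fit$estimate["arm"]),
       p_value = unname(fit$p_value["arm"]),
       significant = unname(fit$p_value["arm"]) < alpha)
}
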