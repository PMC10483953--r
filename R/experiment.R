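#' Configuration of a simulation experiment
#'
#' Bundles everything a grid run needs: scenarios, sample sizes, replicate
#' count, master seed, significance level, timepoints and methods of
#' interest, the power target and search bounds for sample-size estimation,
#' and the population / effect / allocation components.
#'
#' @param scenarios Subset of `"balanced"`, `"imbalanced"`,
#'   `"imbalanced_reversed"`.
#' @param n_grid Enrolments to simulate; the canonical study grid is
#'   100-1500 by 100.
#' @param n_replicates Simulated trials per (scenario, n) cell.
#' @param master_seed Integer; every replicate's substream derives from it.
#' @param alpha Two-sided significance level.
#' @param timepoints_of_interest Post-baseline ages to analyze (months).
#' @param methods Subset of [laz_methods].
#' @param power_target Target power for sample-size search.
#' @param n_search_max,n_search_step Cap and granularity of the search grid.
#' @param population A [laz_population()] object.
#' @param effect An [effect_profile()] object.
#' @param allocation The imbalanced-scenario [allocation_rule()]; the
#'   balanced scenario always uses probability 0.5, and the reversed
#'   scenario flips this rule's slope sign.
#' @return Object of class `laz_config`.
#' @export
experiment_config <- function(scenarios = c("balanced", "imbalanced"),
                              n_grid = seq(100, 1500, by = 100),
                              n_replicates = 1000,
                              master_seed = 1L,
                              alpha = 0.05,
                              timepoints_of_interest = c(6, 12, 18, 24),
                              methods = laz_methods,
                              power_target = 0.80,
                              n_search_max = 12000,
                              n_search_step = 100,
                              population = laz_population(),
                              effect = effect_profile(),
                              allocation = allocation_rule("imbalanced")) {
  scenarios <- match.arg(scenarios,
                         c("balanced", "imbalanced", "imbalanced_reversed"),
                         several.ok = TRUE)
  stopifnot(inherits(population, "laz_population"),
            inherits(effect, "laz_effect_profile"),
            inherits(allocation, "laz_allocation"))
  if (n_replicates < 1) stop("`n_replicates` must be >= 1", call. = FALSE)
  if (any(n_grid < 2)) stop("`n_grid` entries must be >= 2", call. = FALSE)
  if (any(n_grid < 100))
    warning("sample sizes below 100 give unstable operating characteristics")
  if (power_target <= 0 || power_target >= 1)
    stop("`power_target` must lie in (0, 1)", call. = FALSE)
  if (!all(timepoints_of_interest %in% population$timepoints[-1]))
    stop("`timepoints_of_interest` must be post-baseline population timepoints",
         call. = FALSE)
  methods <- match.arg(methods, laz_methods, several.ok = TRUE)
  structure(
    list(scenarios = scenarios, n_grid = sort(as.integer(n_grid)),
         n_replicates = as.integer(n_replicates),
         master_seed = as.integer(master_seed), alpha = alpha,
         timepoints_of_interest = timepoints_of_interest, methods = methods,
         power_target = power_target,
         n_search_max = as.integer(n_search_max),
         n_search_step = as.integer(n_search_step),
         population = population, effect = effect, allocation = allocation),
    class = "laz_config"
  )
}

#' @export
print.laz_config <- function(x, ...) {
  cat("Simulation experiment configuration\n")
  cat("  scenarios:   ", paste(x$scenarios, collapse = ", "), "\n")
  cat("  n grid:      ", paste(range(x$n_grid), collapse = "-"),
      " (", length(x$n_grid), " sizes), ", x$n_replicates,
      " replicates each\n", sep = "")
  cat("  methods:     ", paste(x$methods, collapse = ", "), "\n")
  cat("  timepoints:  ", paste(x$timepoints_of_interest, collapse = ", "), "months\n")
  cat("  alpha:       ", x$alpha, "  master seed:", x$master_seed, "\n")
  invisible(x)
}

# Allocation rule for a named scenario.
scenario_rule <- function(scenario, config) {
  switch(scenario,
         balanced = allocation_rule("balanced"),
         imbalanced = config$allocation,
         imbalanced_reversed = {
           r <- config$allocation
           allocation_rule("imbalanced_reversed",
                           intercept = r$intercept, slope = -r$slope)
         },
         stop("unknown scenario: ", scenario, call. = FALSE))
}

#' Deterministic per-replicate seed
#'
#' Derives the seed of one simulated trial from the master seed and the
#' cell coordinates (scenario, n, replicate) with a Lehmer-style mixing
#' recurrence modulo 2^31 - 19.  Keying on the coordinates, not the loop
#' position, makes cell results independent of execution order, and the
#' linear form guarantees no two cells of a grid collide.
#'
#' @param master_seed Integer master seed.
#' @param scenario Scenario name.
#' @param n Enrolment of the cell.
#' @param replicate Replicate index (1-based).
#' @return An integer seed in \[0, 2^31).
#' @export
replicate_seed <- function(master_seed, scenario, n, replicate) {
  m <- 2147483629
  x <- as.double(master_seed) %% m
  for (v in c(sum(utf8ToInt(as.character(scenario))), n, replicate))
    x <- (x * 48271 + as.double(v)) %% m
  as.integer(x)
}

# Simulate one grid cell: n_replicates trials, all requested methods and
# timepoints fit on the same trials (paired).  Returns the per-replicate fit
# table plus the imbalance diagnostics.
simulate_cell <- function(config, scenario, n, timepoints = NULL,
                          methods = NULL) {
  if (is.null(timepoints)) timepoints <- config$timepoints_of_interest
  if (is.null(methods)) methods <- config$methods
  rule <- scenario_rule(scenario, config)
  reps <- config$n_replicates
  combos <- expand.grid(method = methods, timepoint = timepoints,
                        stringsAsFactors = FALSE)
  nc <- nrow(combos)
  beta <- se <- lo <- hi <- pv <- matrix(NA_real_, reps, nc)
  imb_diff <- imb_p <- numeric(reps)
  for (r in seq_len(reps)) {
    trial <- simulate_trial(config$population, config$effect, rule, n,
                            seed = replicate_seed(config$master_seed, scenario, n, r))
    imb <- baseline_imbalance_test(trial, config$alpha)
    imb_diff[r] <- imb$difference
    imb_p[r] <- imb$p_value
    for (c in seq_len(nc)) {
      f <- estimate_effect(trial, combos$timepoint[c], combos$method[c],
                           config$alpha)
      beta[r, c] <- f$beta1
      se[r, c] <- f$se
      lo[r, c] <- f$ci_low
      hi[r, c] <- f$ci_high
      pv[r, c] <- f$p_value
    }
  }
  list(combos = combos, beta = beta, se = se, ci_low = lo, ci_high = hi,
       p_value = pv, imbalance_difference = imb_diff, imbalance_p = imb_p)
}

#' Run the full scenario x sample-size grid
#'
#' For every (scenario, n) cell, simulates `n_replicates` trials, applies
#' all requested methods at all requested timepoints to the *same* trials
#' (paired comparisons), and summarizes the operating characteristics.
#' Deterministic given the master seed, independent of cell order.
#'
#' @param config An [experiment_config()] object.
#' @param quiet Suppress per-cell progress messages on standard error.
#' @return A data frame of class `laz_results`, one row per
#'   (scenario, n, timepoint, method), with operating characteristics,
#'   baseline-imbalance diagnostics (`prop_significant_imbalance`,
#'   `mean_baseline_diff`) and analytic companion columns (`oracle_bias`,
#'   `oracle_se`, `oracle_power`).  Metadata (config, seed, package version,
#'   timestamp) is attached as the `"metadata"` attribute.
#' @examples
#' cfg <- experiment_config(scenarios = "balanced", n_grid = 300,
#'                          n_replicates = 20, master_seed = 9,
#'                          timepoints_of_interest = 24, methods = "ADJUST")
#' run_grid(cfg)
#' @export
run_grid <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "laz_config"))
  rows <- list()
  for (scenario in config$scenarios) {
    d0 <- if (scenario == "balanced") 0 else
      expected_baseline_imbalance(config$population,
                                  scenario_rule(scenario, config))
    for (n in config$n_grid) {
      t0 <- proc.time()[["elapsed"]]
      cell <- tryCatch(
        simulate_cell(config, scenario, n),
        error = function(e) e
      )
      if (inherits(cell, "error")) {
        message("cell (", scenario, ", n = ", n, ") failed: ",
                conditionMessage(cell), "; continuing")
        rows[[length(rows) + 1]] <- data.frame(
          scenario = scenario, n = n, method = NA_character_,
          timepoint = NA_real_, failed = TRUE)
        next
      }
      prop_sig <- mean(cell$imbalance_p < config$alpha)
      mean_diff <- mean(cell$imbalance_difference)
      for (c in seq_len(nrow(cell$combos))) {
        m <- cell$combos$method[c]
        tp <- cell$combos$timepoint[c]
        j <- match(tp, config$population$timepoints)
        fits <- data.frame(method = m, timepoint = tp, beta1 = cell$beta[, c],
                           se = cell$se[, c], ci_low = cell$ci_low[, c],
                           ci_high = cell$ci_high[, c],
                           p_value = cell$p_value[, c], n_used = n)
        s <- summarize_replicates(fits, config$effect$delta[j], config$alpha)
        s <- cbind(data.frame(scenario = scenario, n = n), s)
        s$prop_significant_imbalance <- prop_sig
        s$mean_baseline_diff <- mean_diff
        s$oracle_bias <- expected_bias(m, tp, config$population, d0)
        s$oracle_se <- sqrt(4 * variance_factor(m, tp, config$population) / n)
        s$oracle_power <- approximate_power(m, tp, n, config$population,
                                            config$effect, config$alpha)
        s$failed <- FALSE
        rows[[length(rows) + 1]] <- s
      }
      if (!quiet)
        message(sprintf("[%s n=%d] %d replicates in %.1fs", scenario, n,
                        config$n_replicates,
                        proc.time()[["elapsed"]] - t0))
    }
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    miss <- setdiff(results_columns(), names(r))
    for (m in miss) r[[m]] <- NA
    r[results_columns()]
  }))
  rownames(out) <- NULL
  attr(out, "metadata") <- list(
    master_seed = config$master_seed,
    config = config,
    package_version = as.character(utils::packageVersion("lazsim")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  class(out) <- c("laz_results", "data.frame")
  out
}

results_columns <- function() {
  c("scenario", "n", "timepoint", "method", "true_effect", "median_estimate",
    "ui_low", "ui_high", "bias", "mean_se", "power", "coverage",
    "n_replicates", "prop_significant_imbalance", "mean_baseline_diff",
    "oracle_bias", "oracle_se", "oracle_power", "failed")
}

#' @export
print.laz_results <- function(x, digits = 3, ...) {
  meta <- attr(x, "metadata")
  cat("Simulation results:", nrow(x), "cells",
      if (!is.null(meta)) paste0("(master seed ", meta$master_seed, ")"), "\n")
  print.data.frame(round_results(as.data.frame(x), digits), row.names = FALSE)
  invisible(x)
}

round_results <- function(df, digits) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], round, digits = digits)
  df
}

#' Two-decimal presentation view of a results table
#'
#' Rounds the estimate, uncertainty-interval, bias, mean-SE, power and
#' coverage columns to two decimals, the convention used for published
#' operating-characteristic tables.
#'
#' @param results A `laz_results` data frame.
#' @export
rounded_view <- function(results) {
  cols <- c("true_effect", "median_estimate", "ui_low", "ui_high", "bias",
            "mean_se", "power", "coverage", "prop_significant_imbalance",
            "mean_baseline_diff")
  out <- as.data.frame(results)
  out[cols] <- lapply(out[cols], round, digits = 2)
  out[c("scenario", "n", "timepoint", "method", cols)]
}

#' Write a results table (CSV plus JSON metadata sidecar)
#'
#' Writes the full-precision table to `path`, run metadata (master seed,
#' serialized configuration, package version, timestamp) to
#' `<path>.meta.json`, and optionally the two-decimal [rounded_view()] to
#' `<path minus .csv>_rounded.csv`.
#'
#' @param results A `laz_results` data frame.
#' @param path CSV output path.
#' @param rounded Also write the rounded presentation view.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, rounded = FALSE) {
  stopifnot(inherits(results, "laz_results"), nrow(results) > 0)
  utils::write.csv(as.data.frame(results), path, row.names = FALSE)
  meta <- attr(results, "metadata")
  meta$config <- config_to_list(meta$config)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  if (rounded)
    utils::write.csv(rounded_view(results),
                     sub("\\.csv$", "_rounded.csv", path), row.names = FALSE)
  invisible(path)
}

#' Read back a results table written by [write_results()]
#' @param path CSV path.
#' @export
read_results <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path))
    attr(out, "metadata") <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  class(out) <- c("laz_results", "data.frame")
  out
}

#' Simulated power across an enrolment grid
#'
#' Simulates `n_replicates` trials at each grid enrolment and returns the
#' rejection fraction per method, all methods fit on the same trials.
#'
#' @param config An [experiment_config()] object.
#' @param scenario Scenario name.
#' @param methods Methods to evaluate.
#' @param timepoint Endpoint age (months).
#' @param n_grid Enrolments; defaults to the config's search grid
#'   (`n_search_step` up to `n_search_max`).
#' @param quiet Suppress progress messages.
#' @return Data frame with `n` and one power column per method.
#' @export
power_curve <- function(config, scenario, methods, timepoint, n_grid = NULL,
                        quiet = TRUE) {
  stopifnot(inherits(config, "laz_config"))
  if (is.null(n_grid))
    n_grid <- seq(config$n_search_step, config$n_search_max,
                  by = config$n_search_step)
  out <- data.frame(n = as.integer(n_grid))
  for (m in methods) out[[m]] <- NA_real_
  for (i in seq_along(n_grid)) {
    t0 <- proc.time()[["elapsed"]]
    cell <- simulate_cell(config, scenario, n_grid[i], timepoints = timepoint,
                          methods = methods)
    for (m in methods) {
      c <- which(cell$combos$method == m)
      out[i, m] <- mean(cell$p_value[, c] < config$alpha)
    }
    if (!quiet)
      message(sprintf("[power %s n=%d] %.1fs", scenario, n_grid[i],
                      proc.time()[["elapsed"]] - t0))
  }
  out
}

#' Smallest grid enrolment reaching a power target
#'
#' Applies isotonic (monotone non-decreasing) regression to a simulated
#' power-vs-n sequence and returns the smallest grid value whose smoothed
#' power reaches the target, or `NA` when the grid cap is hit.  Isotonic
#' smoothing makes the grid search deterministic and insensitive to Monte
#' Carlo wiggle around the crossing.
#'
#' @param n Enrolment grid (increasing).
#' @param power Simulated power at each `n`.
#' @param target Power target in (0, 1).
#' @return Integer enrolment, or `NA_integer_` if the target is not reached.
#' @export
sample_size_from_curve <- function(n, power, target = 0.80) {
  stopifnot(length(n) == length(power), !is.unsorted(n))
  smoothed <- stats::isoreg(n, power)$yf
  hit <- which(smoothed >= target)
  if (!length(hit)) NA_integer_ else as.integer(n[hit[1]])
}

#' Enrolment required to reach the power target
#'
#' Simulates the power curve on the search grid (all requested methods on
#' the same trials) and applies [sample_size_from_curve()].
#'
#' @inheritParams power_curve
#' @param methods One or more methods; a named vector is returned.
#' @return Named integer vector of enrolments (`NA` = target not reached
#'   within `n_search_max`), with the simulated power curve attached as the
#'   `"power_curve"` attribute.
#' @export
find_sample_size_for_power <- function(config, scenario, methods, timepoint,
                                       quiet = TRUE) {
  j <- match(timepoint, config$population$timepoints)
  if (is.na(j) || config$effect$delta[j] == 0)
    stop("the simulated effect at ", timepoint,
         " months is zero: power never systematically exceeds alpha",
         call. = FALSE)
  curve <- power_curve(config, scenario, methods, timepoint, quiet = quiet)
  out <- vapply(methods, function(m)
    sample_size_from_curve(curve$n, curve[[m]], config$power_target),
    integer(1))
  attr(out, "power_curve") <- curve
  out
}
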