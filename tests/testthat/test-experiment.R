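small_config <- function(...) {
  experiment_config(scenarios = "balanced", n_grid = 200, n_replicates = 20,
                    master_seed = 5, timepoints_of_interest = c(6, 24),
                    methods = c("FINAL", "ADJUST", "DELTA_ADJUST"), ...)
}

test_that("configuration validation catches bad settings", {
  expect_error(experiment_config(n_replicates = 0), "n_replicates")
  expect_error(experiment_config(power_target = 1.2), "power_target")
  expect_error(experiment_config(timepoints_of_interest = c(6, 7)),
               "post-baseline")
  expect_warning(experiment_config(n_grid = c(50, 200)), "below 100")
  expect_error(experiment_config(scenarios = "crossover"))
})

test_that("per-replicate seeds are stable, order-free and collision-free", {
  s1 <- replicate_seed(1, "balanced", 1000, 3)
  expect_identical(s1, replicate_seed(1, "balanced", 1000, 3))
  expect_true(s1 >= 0 && s1 < 2^31)
  grid <- expand.grid(scenario = c("balanced", "imbalanced"),
                      n = seq(100, 1500, 100), rep = 1:50,
                      stringsAsFactors = FALSE)
  seeds <- mapply(replicate_seed, 1, grid$scenario, grid$n, grid$rep)
  expect_false(anyDuplicated(seeds) > 0)
})

test_that("grid runs are deterministic and independent of cell order", {
  cfg <- small_config()
  r1 <- run_grid(cfg)
  r2 <- run_grid(cfg)
  attr(r1, "metadata") <- attr(r2, "metadata") <- NULL
  expect_equal(r1, r2)

  cfg_a <- experiment_config(scenarios = "balanced", n_grid = c(150, 250),
                             n_replicates = 10, master_seed = 5,
                             timepoints_of_interest = 24, methods = "FINAL")
  cfg_b <- experiment_config(scenarios = "balanced", n_grid = c(250, 150),
                             n_replicates = 10, master_seed = 5,
                             timepoints_of_interest = 24, methods = "FINAL")
  ra <- run_grid(cfg_a)
  rb <- run_grid(cfg_b)
  ra <- ra[order(ra$n), ]; rb <- rb[order(rb$n), ]
  rownames(ra) <- rownames(rb) <- NULL
  attr(ra, "metadata") <- attr(rb, "metadata") <- NULL
  expect_equal(ra, rb)
})

test_that("results tables have one row per cell with sane entries", {
  res <- run_grid(small_config())
  expect_s3_class(res, "laz_results")
  expect_equal(nrow(res), 2 * 3)  # 2 timepoints x 3 methods
  expect_true(all(res$power >= 0 & res$power <= 1))
  expect_true(all(res$coverage >= 0 & res$coverage <= 1))
  expect_true(all(res$ui_low <= res$median_estimate &
                    res$median_estimate <= res$ui_high))
  expect_equal(res$bias, res$median_estimate - res$true_effect)
  # pairing: DELTA_ADJUST and ADJUST see identical trials, so identical cells
  adj <- res[res$method == "ADJUST", c("median_estimate", "power", "coverage")]
  dad <- res[res$method == "DELTA_ADJUST", c("median_estimate", "power", "coverage")]
  expect_equal(unname(as.matrix(adj)), unname(as.matrix(dad)), tolerance = 1e-10)
})

test_that("results round-trip through CSV and carry reproducibility metadata", {
  res <- run_grid(small_config())
  path <- withr::local_tempfile(fileext = ".csv")
  write_results(res, path, rounded = TRUE)
  back <- read_results(path)
  expect_equal(as.data.frame(back)[results_cols <- names(back)],
               as.data.frame(res)[results_cols], tolerance = 1e-12)
  meta <- attr(back, "metadata")
  expect_equal(meta$master_seed, 5)
  expect_true(file.exists(sub("\\.csv$", "_rounded.csv", path)))
  rv <- rounded_view(res)
  expect_true(all(rv$bias == round(rv$bias, 2)))
})

test_that("configurations round-trip through YAML and unknown keys fail loudly", {
  cfg <- experiment_config(scenarios = c("balanced", "imbalanced"),
                           n_grid = c(300, 600), n_replicates = 12,
                           master_seed = 77, alpha = 0.01,
                           timepoints_of_interest = c(12, 24),
                           methods = c("FINAL", "DELTA"))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config_yaml(cfg, path)
  back <- read_config_yaml(path)
  expect_equal(lazsim:::config_to_list(back), lazsim:::config_to_list(cfg), tolerance = 1e-12)

  writeLines(c("n_replicates: 5", "reps: 7"), path)
  expect_error(read_config_yaml(path), "unknown configuration key.*reps")
  writeLines(c("population:", "  mu: [0]", "  typo_key: 1"), path)
  expect_error(read_config_yaml(path), "unknown population key")
})

test_that("the sample-size crossing rule is isotonic and respects the cap", {
  n <- seq(100, 1000, 100)
  # monotone curve: first crossing at 600
  pow <- c(0.2, 0.3, 0.4, 0.5, 0.7, 0.82, 0.85, 0.9, 0.92, 0.95)
  expect_identical(sample_size_from_curve(n, pow, 0.8), 600L)
  # Monte Carlo wiggle around the crossing is smoothed away
  wiggly <- c(0.2, 0.3, 0.45, 0.42, 0.7, 0.83, 0.80, 0.9, 0.92, 0.95)
  expect_identical(sample_size_from_curve(n, wiggly, 0.8), 600L)
  # cap never reached -> sentinel
  expect_identical(sample_size_from_curve(n, pow / 2, 0.8), NA_integer_)
})

test_that("sample-size search refuses a null effect", {
  cfg <- experiment_config(effect = effect_profile(rep(0, 5)),
                           n_replicates = 5)
  expect_error(find_sample_size_for_power(cfg, "balanced", "ADJUST", 18),
               "zero")
})
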