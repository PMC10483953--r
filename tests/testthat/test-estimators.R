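test_that("least_squares agrees with stats::lm and the normal equations", {
  set.seed(21)
  for (k in 1:3) {
    n <- 40
    X <- replicate(k, rnorm(n))
    y <- 1 + X %*% rnorm(k) + rnorm(n)
    preds <- as.list(as.data.frame(X))
    fit <- least_squares(y, preds)
    ref <- summary(lm(y ~ X))
    expect_equal(unname(fit$estimate), unname(coef(ref)[, 1]), tolerance = 1e-10)
    expect_equal(unname(fit$se), unname(coef(ref)[, 2]), tolerance = 1e-10)
    expect_equal(unname(fit$p_value), unname(coef(ref)[, 4]), tolerance = 1e-10)
    expect_equal(fit$df, ref$df[2])
    expect_equal(fit$sigma, ref$sigma, tolerance = 1e-12)
    bf <- bf_ols(y, cbind(1, X))
    expect_equal(unname(fit$estimate), bf$beta, tolerance = 1e-10)
    expect_equal(unname(fit$se), unname(bf$se), tolerance = 1e-10)
  }
})

test_that("least_squares handles the textbook cases", {
  # hand OLS on 4 points: slope 2, intercept 1.5
  fit <- least_squares(c(1, 2, 3, 4), list(x = c(0, 0, 1, 1)))
  expect_equal(unname(fit$estimate), c(1.5, 2.0))
  # perfect fit: slope 1, zero residuals
  fit <- least_squares(1:10, list(x = 1:10))
  expect_equal(unname(fit$estimate["x"]), 1)
  expect_equal(fit$residuals, rep(0, 10), tolerance = 1e-12)
  # intercept-only fit is the sample mean
  y <- c(2, 4, 9)
  expect_equal(unname(least_squares(y)$estimate), mean(y))
})

test_that("least_squares rejects bad designs with informative errors", {
  expect_error(least_squares(c(1, NA, 3), list(x = 1:3)), "missing")
  expect_error(least_squares(1:2, list(a = 1:2, b = 2:3)), "more observations")
  expect_error(least_squares(rnorm(10), list(a = 1:10, twice_a = 2 * (1:10))),
               "collinear")
  expect_error(least_squares(rnorm(10), list(a = 1:10, twice_a = 2 * (1:10))),
               "twice_a")
})

test_that("FINAL and DELTA reduce to the corresponding mean differences", {
  for (s in 1:10) {
    tr <- simulate_trial(n = 60, seed = 300 + s,
                         rule = allocation_rule("imbalanced"))
    i1 <- tr$arm == 1
    fin <- estimate_effect(tr, 24, "FINAL")
    expect_equal(fin$beta1, mean(tr$laz[i1, 5]) - mean(tr$laz[!i1, 5]),
                 tolerance = 1e-10)
    del <- estimate_effect(tr, 24, "DELTA")
    chg <- tr$laz[, 5] - tr$laz[, 1]
    expect_equal(del$beta1, mean(chg[i1]) - mean(chg[!i1]), tolerance = 1e-10)
  }
})

test_that("DELTA+ADJUST is an exact reparameterization of ADJUST", {
  for (s in 1:10) {
    tr <- simulate_trial(n = 60, seed = 400 + s,
                         rule = allocation_rule("imbalanced"))
    a <- estimate_effect(tr, 18, "ADJUST")
    da <- estimate_effect(tr, 18, "DELTA_ADJUST")
    expect_equal(da$beta1, a$beta1, tolerance = 1e-10)
    expect_equal(da$se, a$se, tolerance = 1e-10)
    expect_equal(da$p_value, a$p_value, tolerance = 1e-10)
    # baseline coefficients differ by exactly 1
    expect_equal(unname(a$coefficients["baseline"] - da$coefficients["baseline"]),
                 1, tolerance = 1e-10)
  }
})

test_that("RESIDUALS equals ADJUST when arm and baseline are sample-orthogonal", {
  # mirrored baselines, identical in both arms: cov(arm, baseline) = 0
  base <- c(-1, -0.5, 0.5, 1, -1, -0.5, 0.5, 1)
  set.seed(17)
  endpoint <- -1.5 + 0.4 * base + rnorm(8, sd = 0.3)
  tr <- make_trial(cbind(base, endpoint), arm = rep(c(0, 1), each = 4))
  expect_equal(cov(tr$arm, base), 0)
  r <- estimate_effect(tr, 24, "RESIDUALS")
  a <- estimate_effect(tr, 24, "ADJUST")
  expect_equal(r$beta1, a$beta1, tolerance = 1e-10)
})

test_that("all five methods match a brute-force normal-equations solve on the 8-child fixture", {
  tr <- fixture8()
  y0 <- tr$laz[, 1]; yi <- tr$laz[, 2]; x <- tr$arm
  one <- rep(1, 8)
  expected <- c(
    FINAL = unname(bf_ols(yi, cbind(one, x))$beta[2]),
    ADJUST = unname(bf_ols(yi, cbind(one, x, y0))$beta[2]),
    DELTA = unname(bf_ols(yi - y0, cbind(one, x))$beta[2]),
    DELTA_ADJUST = unname(bf_ols(yi - y0, cbind(one, x, y0))$beta[2]),
    RESIDUALS = {
      s1 <- bf_ols(yi, cbind(one, y0))
      res <- yi - cbind(one, y0) %*% c(s1$beta)
      unname(bf_ols(res, cbind(one, x))$beta[2])
    }
  )
  for (m in laz_methods) {
    f <- estimate_effect(tr, 24, m)
    expect_equal(f$beta1, unname(expected[m]), tolerance = 1e-10, label = m)
    expect_true(f$ci_low <= f$beta1 && f$beta1 <= f$ci_high)
    expect_gt(f$se, 0)
    expect_true(f$p_value >= 0 && f$p_value <= 1)
  }
})

test_that("effect estimation rejects degenerate inputs", {
  tr <- fixture8()
  tr$arm <- rep(1L, 8)
  expect_error(estimate_effect(tr, 24, "FINAL"), "one arm")
  expect_error(estimate_effect(fixture8(), 0, "FINAL"), "post-baseline")
  expect_error(estimate_effect(fixture8(), 7, "FINAL"), "post-baseline")
})

test_that("median estimates are centred on zero for null balanced trials", {
  betas <- sapply(1:200, function(r) {
    tr <- simulate_trial(effect = effect_profile(rep(0, 5)), n = 200,
                         seed = 7000 + r)
    vapply(c("FINAL", "ADJUST", "DELTA"),
           function(m) estimate_effect(tr, 24, m)$beta1, numeric(1))
  })
  # Monte Carlo SE of a median of 200 draws with per-trial SE ~ 0.13
  expect_true(all(abs(apply(betas, 1, median)) < 0.035))
})
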