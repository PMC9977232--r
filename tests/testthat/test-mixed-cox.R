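test_that("inner penalized fit matches a brute-force grid search on toy data", {
  # 2 strains, 10 records, slope variance fixed: the penalized partial
  # likelihood maximizer over (beta, u1, u2) from the Newton solver must
  # agree with an iteratively refined dense grid using the naive likelihood
  set.seed(41)
  d <- data.frame(strain = rep(1:2, each = 5),
                  diet = c(0, 0, 1, 1, 1, 0, 0, 0, 1, 1),
                  age = round(runif(10, 100, 1000)), event = 1L)
  for (s2 in c(0.25, 1)) {
    fit <- fit_mixed_cox(d, sigma2 = s2)
    ref <- grid_search_ppl2(d, s2)
    expect_lt(max(abs(c(fit$overall, fit$strain_effects) - ref$par)), 1e-3)
  }
})

test_that("the penalty-free limit is the common-baseline interaction Cox model", {
  skip_if_not_installed("survival")
  d <- simulate_panel(panel_design(6, 20), effect_model(-0.5, 0.4), seed = 8)
  big <- fit_mixed_cox(d, sigma2 = 1e6)
  joint <- big$overall + big$strain_effects
  ref <- survival::coxph(survival::Surv(age, event) ~ factor(strain):diet,
                         data = d, ties = "efron")
  expect_equal(unname(joint), unname(coef(ref)), tolerance = 1e-5)
  # the per-strain stratified fits estimate the same quantities and agree
  # up to finite-sample baseline differences
  np <- fit_panel(d, "lnhr", "none")
  expect_lt(max(abs(joint - np$strains$estimate)), 0.5)
  # at large per-strain n the two families of estimates converge
  d2 <- simulate_panel(panel_design(6, 400), effect_model(-0.5, 0.4),
                       seed = 8)
  b2 <- fit_mixed_cox(d2, sigma2 = 1e6)
  np2 <- fit_panel(d2, "lnhr", "none")
  expect_lt(max(abs(b2$overall + b2$strain_effects -
                      np2$strains$estimate)), 0.1)
})

test_that("shrinkage strengthens monotonically as the variance shrinks", {
  d <- simulate_panel(panel_design(6, 20), effect_model(-0.5, 0.4), seed = 8)
  s2_grid <- c(1e4, 1, 0.25, 0.04, 0.01, 1e-3)
  mx <- vapply(s2_grid, function(s2)
    max(abs(fit_mixed_cox(d, sigma2 = s2)$strain_effects)), numeric(1))
  expect_true(all(diff(mx) < 0))
})

test_that("a boundary solution collapses exactly to the pooled Cox fit", {
  # tiny homogeneous panel: the variance optimum sits at the lower bound
  d <- simulate_panel(panel_design(5, 4), effect_model(-0.5, 0), seed = 101)
  fit <- fit_mixed_cox(d, baseline = FALSE)
  if (fit$boundary) {
    expect_equal(fit$sigma_hat, 0)
    expect_true(all(fit$strain_effects == 0))
    expect_equal(fit$variance_test$statistic, 0)
    pooled <- fit_cox(d)
    expect_equal(fit$overall, pooled$lnhr, tolerance = 1e-6)
    expect_equal(fit$integrated_loglik, pooled$loglik, tolerance = 1e-6)
  } else {
    # not at the boundary for this draw; the stat must still be tiny
    expect_lt(fit$variance_test$statistic, 3.9)
  }
})

test_that("shrunken deviations centre near zero and recover the truth at scale", {
  d <- simulate_panel(panel_design(40, 40), effect_model(-0.5, 0.5), seed = 7)
  fit <- fit_mixed_cox(d)
  expect_lt(abs(mean(fit$strain_effects)), 0.05)
  expect_gt(fit$sigma_hat, 0.3)
  expect_lt(fit$sigma_hat, 0.7)
  expect_lt(abs(fit$overall - (-0.5)), 0.2)
  # true deviations and shrunken predictions are strongly aligned
  truth <- attr(d, "strain_effects")$delta
  expect_gt(cor(truth, fit$strain_effects), 0.8)
})

test_that("variance test distinguishes presence from absence of strain variation", {
  d1 <- simulate_panel(panel_design(30, 20), effect_model(-0.5, 0.4),
                       seed = 51)
  f1 <- fit_mixed_cox(d1)
  expect_lt(f1$variance_test$p_value, 0.01)
  expect_equal(f1$variance_test$df, 1L)
  d0 <- simulate_panel(panel_design(10, 5), effect_model(-0.5, 0), seed = 52)
  f0 <- fit_mixed_cox(d0)
  expect_gt(f0$variance_test$p_value, 0.05)
  # mixture reference is never larger than the chi-square reference
  f1m <- fit_mixed_cox(d1, test = "mixture")
  expect_lte(f1m$variance_test$p_value, f1$variance_test$p_value)
})
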