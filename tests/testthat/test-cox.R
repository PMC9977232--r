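test_that("four-record fit matches a dense grid search of the partial likelihood", {
  d <- data.frame(diet = c(0, 0, 1, 1), age = c(1, 3, 2, 4), event = 1L)
  fit <- fit_cox(d)
  expect_equal(fit$lnhr, grid_search_lnhr(d), tolerance = 1e-4)
  # and the maximized loglik agrees with the naive evaluator at the optimum
  expect_equal(fit$loglik,
               naive_cox_loglik(fit$lnhr * d$diet, d$age, d$event),
               tolerance = 1e-8)
})

test_that("several small datasets match grid search to 1e-3", {
  for (k in 1:5) {
    set.seed(k)
    n <- sample(6:10, 1)
    d <- data.frame(diet = rep(c(0, 1), length.out = n),
                    age = round(runif(n, 100, 1000)), event = 1L)
    if (length(unique(d$diet[d$event == 1])) < 2) next
    fit <- fit_cox(d)
    if (fit$separation) next
    expect_equal(fit$lnhr, grid_search_lnhr(d), tolerance = 1e-3)
  }
})

test_that("fit agrees with survival::coxph under Efron ties", {
  skip_if_not_installed("survival")
  d <- simulate_panel(panel_design(1, 30), effect_model(-0.5, 0), seed = 17)
  d$age <- round(d$age, -1)  # force heavy ties
  fit <- fit_cox(d)
  ref <- survival::coxph(survival::Surv(age, event) ~ diet, data = d,
                         ties = "efron")
  expect_equal(fit$lnhr, unname(coef(ref)), tolerance = 1e-7)
  expect_equal(fit$se, unname(sqrt(vcov(ref)[1, 1])), tolerance = 1e-7)
  expect_equal(fit$loglik, ref$loglik[2], tolerance = 1e-8)
})

test_that("identical death-time multisets give lnHR 0", {
  d <- data.frame(diet = rep(c(0, 1), each = 4),
                  age = rep(c(500, 600, 700, 800), 2), event = 1L)
  fit <- fit_cox(d)
  expect_equal(fit$lnhr, 0, tolerance = 1e-8)
})

test_that("the estimator is consistent at large n", {
  d <- simulate_panel(panel_design(1, 1e4), effect_model(-0.5, 0), seed = 19)
  fit <- fit_cox(d)
  expect_lt(abs(fit$lnhr - (-0.5)), 0.05)
})

test_that("monotone likelihood is flagged as separation, not an endless loop", {
  # every AL death strictly before every DR death
  d <- data.frame(diet = rep(c(0, 1), each = 3),
                  age = c(100, 110, 120, 500, 510, 520), event = 1L)
  fit <- fit_cox(d)
  expect_true(fit$separation)
  expect_false(fit$converged)
  expect_equal(abs(fit$lnhr), 15)
  expect_error(fit_cox(data.frame(diet = c(0, 0, 1), age = c(1, 2, 3),
                                  event = c(1, 1, 0))),
               "each diet arm")
})

test_that("no-pooling panel fit wraps per-strain Cox fits", {
  d <- simulate_panel(panel_design(8, 6), effect_model(-0.5, 0.3), seed = 23)
  fit <- fit_panel(d, "lnhr", "none")
  expect_equal(nrow(fit$strains), 8)
  s3 <- d[d$strain == 3, ]
  expect_equal(fit$strains$estimate[fit$strains$strain == "3"],
               fit_cox(s3)$lnhr)
  est <- fit$strains$estimate[!fit$strains$flagged]
  expect_equal(fit$overall, mean(est))
  expect_equal(fit$sigma_hat, sd(est))
  expect_equal(fit$cv_g, sd(est) / abs(mean(est)))
  # runs on the same toy fixture as the MD estimators, one row per strain;
  # both toy strains have perfectly ordered arms, so both are flagged and
  # the spread is not estimable
  expect_warning(toy <- fit_panel(toy_md_panel(), "lnhr", "none"),
                 "stable Cox fit")
  expect_equal(nrow(toy$strains), 2)
  expect_true(all(toy$strains$flagged))
  expect_true(is.na(toy$sigma_hat))
})

test_that("strains with separation are excluded from the spread with a count", {
  good <- simulate_panel(panel_design(3, 5), effect_model(-0.5, 0), seed = 29)
  sep <- data.frame(strain = 99, diet = rep(c(0, 1), each = 5),
                    age = c(101:105, 901:905), event = 1L)
  d <- rbind(good[, c("strain", "diet", "age", "event")], sep)
  fit <- fit_panel(d, "lnhr", "none")
  expect_equal(fit$n_flagged, 1L)
  flagged <- fit$strains[fit$strains$flagged, ]
  expect_equal(as.character(flagged$strain), "99")
  est <- fit$strains$estimate[!fit$strains$flagged]
  expect_equal(fit$sigma_hat, sd(est))
})
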