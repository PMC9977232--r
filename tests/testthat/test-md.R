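test_that("no-pooling mean differences match hand arithmetic", {
  fit <- fit_panel(toy_md_panel(), "md", "none")
  s <- fit$strains[order(fit$strains$strain), ]
  expect_equal(s$estimate, c(110, 60))        # 920-810 and 780-720
  expect_equal(fit$overall, 85)
  expect_equal(fit$sigma_hat, sd(c(110, 60))) # two-point SD = 35.355...
  # canonical two-point case {100, 60}: overall 80, SD 28.284
  expect_equal(sd(c(100, 60)), 28.284, tolerance = 1e-4)
  # se and p agree with the pooled-variance two-sample t-test
  tt <- t.test(age ~ diet, data = toy_md_panel()[1:4, ], var.equal = TRUE)
  expect_equal(s$p_value[1], tt$p.value)
  expect_equal(s$se[1], abs(diff(tt$estimate)) / abs(tt$statistic),
               ignore_attr = TRUE)
})

test_that("identical arms give zero estimates and zero spread", {
  d <- data.frame(strain = rep(1:3, each = 4),
                  diet = rep(c(0, 0, 1, 1), 3),
                  age = rep(c(700, 900, 700, 900), 3), event = 1L)
  # a zero overall effect makes CV_G undefined, which is warned about
  expect_warning(fit <- fit_panel(d, "md", "none"), "undefined")
  expect_true(all(fit$strains$estimate == 0))
  expect_equal(fit$sigma_hat, 0)
  expect_identical(fit$cv_g, Inf)
})

test_that("no-pooling estimates are location-equivariant and order-invariant", {
  d <- simulate_panel(panel_design(6, 4), effect_model(-0.5, 0.3), seed = 21)
  f1 <- fit_panel(d, "md", "none")
  d2 <- d; d2$age <- d2$age + 100
  f2 <- fit_panel(d2, "md", "none")
  expect_equal(f1$strains$estimate, f2$strains$estimate, tolerance = 1e-10)
  d3 <- d[sample(nrow(d)), ]
  f3 <- fit_panel(d3, "md", "none")
  expect_equal(f1$strains[order(f1$strains$strain), "estimate"],
               f3$strains[order(f3$strains$strain), "estimate"])
})

test_that("strains with a single animal per arm are flagged without a p-value", {
  d <- data.frame(strain = rep(1:2, each = 4),
                  diet = rep(c(0, 0, 1, 1), 2),
                  age = c(700, 720, 800, 840, 600, 600, 700, 700), event = 1L)
  d <- d[-1, ]  # strain 1 now has one AL animal
  fit <- fit_panel(d, "md", "none")
  s1 <- fit$strains[fit$strains$strain == "1", ]
  expect_true(s1$flagged)
  expect_true(is.na(s1$p_value))
  expect_equal(s1$estimate, 820 - 720)
  expect_equal(fit$n_flagged, 1L)
})

test_that("partial pooling shrinks every strain toward the overall effect", {
  d <- simulate_panel(panel_design(20, 5), effect_model(-0.5, 0.2), seed = 31)
  none <- fit_panel(d, "md", "none")
  part <- fit_panel(d, "md", "partial", test = FALSE)
  m <- merge(none$strains, part$strains, by = "strain")
  expect_true(all(abs(m$estimate.y - part$overall) <=
                    abs(m$estimate.x - none$overall) + 1e-8))
  expect_lte(part$sigma_hat, none$sigma_hat)
})

test_that("with no true variance the mixed model shrinks the spread in nearly every dataset", {
  # 200 homogeneous panels at the small-study size: partial-pooling SD below
  # the no-pooling SD in at least 95% of datasets
  wins <- logical(200)
  for (k in 1:200) {
    d <- simulate_panel(panel_design(10, 5), effect_model(-0.5, 0),
                        seed = child_seed(77, k))
    none <- fit_panel(d, "md", "none")
    part <- fit_panel(d, "md", "partial", test = FALSE)
    wins[k] <- part$sigma_hat <= none$sigma_hat
  }
  expect_gte(mean(wins), 0.95)
})

test_that("the mixed model recovers a known mean-difference SD", {
  # calibrate the true MD-scale SD by integrating the Gompertz mean lifespan
  # over the strain-effect distribution
  sigma_delta <- 0.3; mu <- -0.5
  m_of_delta <- function(delta)
    vapply(delta, function(dl)
      gompertz_mean_oracle(-11.57, -4.9, mu + dl) -
        gompertz_mean_oracle(-11.57, -4.9, 0), numeric(1))
  mom <- function(f) integrate(function(z) f(z) * dnorm(z, 0, sigma_delta),
                               -4 * sigma_delta, 4 * sigma_delta,
                               rel.tol = 1e-8)$value
  m1 <- mom(m_of_delta)
  true_sd <- sqrt(mom(function(z) m_of_delta(z)^2) - m1^2)
  sds <- vapply(1:12, function(k) {
    d <- simulate_panel(panel_design(40, 40),
                        effect_model(mu, sigma_delta), seed = child_seed(55, k))
    fit_panel(d, "md", "partial", test = FALSE)$sigma_hat
  }, numeric(1))
  q <- quantile(sds, c(0.25, 0.75))
  expect_gt(true_sd, q[1] - 2 * (q[2] - q[1]))
  expect_lt(true_sd, q[2] + 2 * (q[2] - q[1]))
  expect_lt(abs(median(sds) - true_sd) / true_sd, 0.35)
})

test_that("variance LRT p-value is small when variance is present, large when absent", {
  d1 <- simulate_panel(panel_design(30, 20), effect_model(-0.5, 0.4),
                       seed = 61)
  f1 <- fit_panel(d1, "md", "partial")
  expect_lt(f1$variance_test$p_value, 0.01)
  d0 <- simulate_panel(panel_design(10, 5), effect_model(-0.5, 0), seed = 62)
  f0 <- fit_panel(d0, "md", "partial")
  expect_gt(f0$variance_test$p_value, 0.05)
  # mixture reference halves a positive chi-square tail probability
  f1m <- fit_panel(d1, "md", "partial", test_ref = "mixture")
  expect_equal(f1m$variance_test$p_value, f1$variance_test$p_value / 2)
})
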