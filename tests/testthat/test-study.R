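cfg_small <- study_config(n_strains = 8, n_per_arm = 4, cv_g = 0.4,
                          n_replicates = 4, seed = 11,
                          estimators = c("md_none", "lnhr_partial"))

test_that("worked example produces a sorted waterfall over all strains", {
  cfg <- study_config(n_strains = 12, n_per_arm = 5, cv_g = 0, seed = 2)
  tab <- run_worked_example(cfg)
  expect_equal(nrow(tab), 12)
  expect_true(all(diff(tab$md_none) <= 0))       # waterfall order
  fits <- attr(tab, "fits")
  expect_named(fits, c("md_none", "md_partial", "lnhr_none", "lnhr_partial"))
  # homogeneous truth: no-pooling MD spread is wide (sampling noise alone)
  # while the partial-pooling hazard fit shrinks the response variance away
  expect_gt(diff(range(tab$md_none)), 100)
  expect_lt(fits$lnhr_partial$sigma_hat, fits$lnhr_none$sigma_hat)
})

test_that("the simulation grid returns one summarised row per cell and is deterministic", {
  g1 <- suppressMessages(run_grid(cfg_small, progress = FALSE))
  expect_equal(nrow(g1), 2)  # 1 n x 1 cv_g x 2 estimators
  expect_true(all(c("cvg_median", "cvg_iqr", "bias_median", "replicability",
                    "power", "n_converged") %in% names(g1)))
  expect_true(all(is.na(g1$power[g1$pooling == "none"])))
  expect_true(all(g1$power[g1$pooling == "partial"] >= 0 &
                    g1$power[g1$pooling == "partial"] <= 1, na.rm = TRUE))
  g2 <- suppressMessages(run_grid(cfg_small, progress = FALSE))
  expect_identical(g1, g2)
})

test_that("power curve runs per sample size with binomial uncertainty", {
  cfg <- study_config(n_strains = 8, n_per_arm = c(4, 6), cv_g = 1,
                      n_replicates = 5, seed = 3)
  pc <- suppressMessages(run_power_curve(cfg, progress = FALSE))
  expect_equal(pc$n_per_arm, c(4, 6))
  expect_true(all(pc$power >= 0 & pc$power <= 1))
  expect_true(all(pc$n_converged == 5))
  expect_true(all(pc$power_se >= 0))
})

test_that("re-analysis of a written CSV reproduces the in-memory fits", {
  d <- simulate_panel(panel_design(10, 8),
                      effect_model(-0.5, sigma_delta = 0.25), seed = 19)
  f <- withr::local_tempfile(fileext = ".csv")
  write_panel_csv(d, f)
  ra <- reanalyze(f)
  direct <- fit_panel(read_panel_csv(f), "lnhr", "partial")
  expect_equal(ra$fits$lnhr_partial$sigma_hat, direct$sigma_hat,
               tolerance = 1e-10)
  expect_equal(ra$cvg_table$cv_g[ra$cvg_table$estimator == "md_none"],
               fit_panel(d, "md", "none")$cv_g, tolerance = 1e-10)
  # partial pooling is at least as conservative on both scales
  ct <- ra$cvg_table
  expect_lte(ct$cv_g[ct$estimator == "md_partial"],
             ct$cv_g[ct$estimator == "md_none"])
  expect_lte(ct$cv_g[ct$estimator == "lnhr_partial"],
             ct$cv_g[ct$estimator == "lnhr_none"])
  # waterfall tables are strain-complete and ordered
  expect_equal(nrow(ra$waterfall$md), 10)
  expect_true(all(diff(ra$waterfall$lnhr$no_pooling) <= 0))
})

test_that("single-strain input is rejected with a clear message", {
  d <- simulate_panel(panel_design(2, 6), effect_model(-0.5, 0), seed = 23)
  expect_error(reanalyze(d[d$strain == 1, ]), "at least 2 strains")
})

test_that("fixture generation is byte-deterministic with the documented header", {
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  des <- panel_design(6, 5)
  generate_fixture(f1, design = des, seed = 99)
  generate_fixture(f2, design = des, seed = 99)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(f1, n = 1), "strain,diet,age,event")
  d <- read_panel_csv(f1)
  expect_equal(nrow(d), 6 * 2 * 5)
})

test_that("YAML configuration round-trips into a study_config", {
  f <- withr::local_tempfile(fileext = ".yml")
  writeLines(c("n_strains: 12", "n_per_arm: [5, 10]", "cv_g: [0, 1]",
               "mu: -0.4", "n_replicates: 7", "seed: 5",
               "estimators: [lnhr_partial]",
               "gompertz: {log_a: -11.0, log_b: -5.0}"), f)
  cfg <- read_study_config(f)
  expect_equal(cfg$n_strains, 12L)
  expect_equal(cfg$n_per_arm, c(5L, 10L))
  expect_equal(cfg$mu, -0.4)
  expect_equal(cfg$gompertz$log_a, -11)
  expect_equal(cfg$estimators, "lnhr_partial")
  writeLines("bogus_field: 3", f)
  expect_error(read_study_config(f), "unknown config field")
})
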