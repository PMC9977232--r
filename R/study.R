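#' Configuration of a replicated simulation study
#'
#' Holds the full design of a simulation study over a grid of per-arm
#' sample sizes and true CV_G levels. Each grid cell simulates
#' `n_replicates` paired experiments (shared strain effects, independent
#' death times) at `n_strains` strains, overall log hazard ratio `mu`, and
#' among-strain SD `sigma_delta = cv_g * |mu|`, then summarises each
#' requested estimator's CV_G bias, between-pair replicability and variance
#' -test power.
#'
#' @param n_strains Strains per experiment. Default 40.
#' @param n_per_arm Grid of animals per strain per diet. Default
#'   `c(5, 10, 20, 40)`.
#' @param cv_g Grid of true CV_G levels. Default `c(0, 0.2, 0.4, 1)`.
#' @param mu Overall log hazard ratio of DR vs AL. Default -0.5.
#' @param sigma_alpha SD of strain baseline deviations (0 in the main
#'   model).
#' @param gompertz Baseline mortality parameters.
#' @param n_replicates Replicates (pairs) per cell. Default 1000.
#' @param alpha Significance level of the variance test. Default 0.05.
#' @param seed Master seed; every replicate derives its own child seeds.
#' @param estimators Subset of
#'   `c("md_none", "md_partial", "lnhr_none", "lnhr_partial")`.
#' @return An object of class `"study_config"`.
#' @export
study_config <- function(n_strains = 40, n_per_arm = c(5, 10, 20, 40),
                         cv_g = c(0, 0.2, 0.4, 1), mu = -0.5,
                         sigma_alpha = 0, gompertz = gompertz_params(),
                         n_replicates = 1000, alpha = 0.05, seed = 1,
                         estimators = c("md_none", "md_partial",
                                        "lnhr_none", "lnhr_partial")) {
  estimators <- match.arg(estimators, several.ok = TRUE)
  stopifnot(n_strains >= 1, all(n_per_arm >= 1), all(cv_g >= 0),
            is.finite(mu), n_replicates >= 1, alpha > 0, alpha < 1)
  structure(list(n_strains = as.integer(n_strains),
                 n_per_arm = as.integer(n_per_arm), cv_g = cv_g, mu = mu,
                 sigma_alpha = sigma_alpha, gompertz = gompertz,
                 n_replicates = as.integer(n_replicates), alpha = alpha,
                 seed = as.integer(seed), estimators = estimators),
            class = "study_config")
}

#' Read a study configuration from YAML
#'
#' Field names mirror the arguments of [study_config()]; `gompertz` may be
#' a mapping with `log_a` and `log_b`. Missing fields take the defaults.
#'
#' @param path Path to a YAML file.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$gompertz))
    y$gompertz <- gompertz_params(log_a = y$gompertz$log_a,
                                  log_b = y$gompertz$log_b)
  known <- names(formals(study_config))
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  do.call(study_config, y)
}

.estimator_parts <- function(est) {
  list(scale = if (startsWith(est, "md")) "md" else "lnhr",
       pooling = if (endsWith(est, "none")) "none" else "partial")
}

#' Simulated worked example: one small panel experiment, four estimators
#'
#' Simulates a single experiment (by default 40 strains, 5 animals per
#' strain per diet, no true among-strain variation) and fits all four
#' estimators, returning a waterfall table sorted by the no-pooling
#' mean-difference estimate. This reproduces, for one seed, the canonical
#' demonstration that a no-pooling analysis of a homogeneous panel shows
#' wide, partly "significant" spread while partial pooling shrinks the
#' spread away.
#'
#' @param config A [study_config()]; the first elements of `n_per_arm` and
#'   `cv_g` are used.
#' @param seed Seed for the simulated experiment (defaults to
#'   `config$seed`).
#' @return A data.frame with one row per strain, sorted by `md_none`
#'   descending: per-strain estimates from all four estimators, the
#'   no-pooling p-values and significance stars. The four `panel_fit`
#'   objects are attached as `attr(, "fits")`, and the simulated data as
#'   `attr(, "data")`.
#' @export
run_worked_example <- function(config = study_config(cv_g = 0, n_per_arm = 5),
                               seed = config$seed) {
  design <- panel_design(config$n_strains, config$n_per_arm[1],
                         config$gompertz)
  effect <- effect_model(config$mu,
                         sigma_for_cvg(config$cv_g[1], config$mu),
                         config$sigma_alpha)
  data <- simulate_panel(design, effect, seed = seed)
  fits <- list(md_none = fit_panel(data, "md", "none"),
               md_partial = fit_panel(data, "md", "partial", test = FALSE),
               lnhr_none = fit_panel(data, "lnhr", "none"),
               lnhr_partial = fit_panel(data, "lnhr", "partial",
                                        test = FALSE))
  key <- fits$md_none$strains
  tab <- data.frame(strain = key$strain,
                    md_none = key$estimate,
                    md_none_p = key$p_value,
                    sig = ifelse(!is.na(key$p_value) & key$p_value < 0.05,
                                 "*", ""),
                    md_partial = fits$md_partial$strains$estimate[
                      match(key$strain, fits$md_partial$strains$strain)],
                    lnhr_none = fits$lnhr_none$strains$estimate[
                      match(key$strain, fits$lnhr_none$strains$strain)],
                    lnhr_none_p = fits$lnhr_none$strains$p_value[
                      match(key$strain, fits$lnhr_none$strains$strain)],
                    lnhr_partial = fits$lnhr_partial$strains$estimate[
                      match(key$strain, fits$lnhr_partial$strains$strain)])
  tab <- tab[order(-tab$md_none), ]
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits
  attr(tab, "data") <- data
  tab
}

# Fit one estimator, returning NULL on failure (counted as non-convergence).
.try_fit <- function(data, est, test) {
  parts <- .estimator_parts(est)
  tryCatch(fit_panel(data, parts$scale, parts$pooling, test = test),
           error = function(e) NULL)
}

#' Run the replicated bias/replicability grid
#'
#' For every combination of per-arm sample size, true CV_G and estimator in
#' the configuration: simulates `n_replicates` paired experiments, fits the
#' estimator to both members, and summarises (i) the median and IQR of the
#' estimated CV_G from the first member with the bias of the median, (ii)
#' the mean between-pair correlation of strain-level estimates
#' (replicability), and (iii) for partial-pooling estimators the power of
#' the among-strain variance test at level `alpha`.
#'
#' Replicate `k` uses child seeds derived from `(seed, n, cv_g, k)`, so
#' results for a replicate are invariant to `n_replicates` and cells can be
#' recomputed independently.
#'
#' @param config A [study_config()].
#' @param progress Emit per-cell progress lines to stderr. Default TRUE.
#' @return A data.frame with one row per (n_per_arm, cv_g, estimator) cell:
#'   `cvg_median`, `cvg_q1`, `cvg_q3`, `cvg_iqr`, `bias_median`,
#'   `replicability`, `n_pairs_dropped`, `power` (NA for no-pooling
#'   estimators), `n_converged`, `n_replicates`, `flagged_cell` (TRUE when
#'   more than 20% of replicates failed to converge).
#' @export
run_grid <- function(config, progress = TRUE) {
  stopifnot(inherits(config, "study_config"))
  cells <- expand.grid(n_per_arm = config$n_per_arm, cv_g = config$cv_g,
                       KEEP.OUT.ATTRS = FALSE)
  out <- list()
  for (ci in seq_len(nrow(cells))) {
    n <- cells$n_per_arm[ci]
    cvg <- cells$cv_g[ci]
    design <- panel_design(config$n_strains, n, config$gompertz)
    effect <- effect_model(config$mu, sigma_for_cvg(cvg, config$mu),
                           config$sigma_alpha)
    acc <- lapply(config$estimators, function(e)
      list(cvg = rep(NA_real_, config$n_replicates),
           cor = rep(NA_real_, config$n_replicates),
           p = rep(NA_real_, config$n_replicates),
           conv = logical(config$n_replicates)))
    names(acc) <- config$estimators
    for (k in seq_len(config$n_replicates)) {
      pair <- simulate_panel_pair(design, effect,
                                  seed = child_seed(config$seed,
                                                    round(n), round(cvg * 1000), k))
      for (e in config$estimators) {
        needs_test <- endsWith(e, "partial")
        f1 <- .try_fit(pair[[1]], e, test = needs_test)
        f2 <- .try_fit(pair[[2]], e, test = FALSE)
        if (is.null(f1) || is.null(f2)) next
        acc[[e]]$cvg[k] <- f1$cv_g
        acc[[e]]$cor[k] <- pair_correlation(f1, f2)
        acc[[e]]$conv[k] <- f1$converged && f2$converged
        if (needs_test && !is.null(f1$variance_test))
          acc[[e]]$p[k] <- f1$variance_test$p_value
      }
    }
    for (e in config$estimators) {
      a <- acc[[e]]
      ok <- !is.na(a$cvg) & is.finite(a$cvg)
      bs <- bias_summary(a$cvg[ok], cvg)
      rep_res <- tryCatch(replicability(a$cor), error = function(e) NULL)
      pow <- if (endsWith(e, "partial") && any(!is.na(a$p)))
        power_estimate(a$p, config$alpha) else NA_real_
      n_conv <- sum(a$conv)
      parts <- .estimator_parts(e)
      out[[length(out) + 1L]] <- data.frame(
        estimator = e, scale = parts$scale, pooling = parts$pooling,
        n_per_arm = n, true_cv_g = cvg,
        cvg_median = bs$median, cvg_q1 = bs$q1, cvg_q3 = bs$q3,
        cvg_iqr = bs$iqr, bias_median = bs$bias,
        replicability = if (is.null(rep_res)) NA_real_ else rep_res$mean,
        n_pairs_dropped = if (is.null(rep_res)) config$n_replicates
                          else rep_res$n_dropped,
        power = pow, n_converged = n_conv,
        n_replicates = config$n_replicates,
        flagged_cell = n_conv < 0.8 * config$n_replicates)
      if (progress)
        message(sprintf(
          "cell n=%d cv_g=%.2f %s: median CV_G %.3f, repl %.3f, power %s (%d/%d converged)",
          n, cvg, e, bs$median,
          if (is.null(rep_res)) NA else rep_res$mean,
          if (is.na(pow)) "-" else sprintf("%.2f", pow),
          n_conv, config$n_replicates))
    }
  }
  do.call(rbind, out)
}

#' Power curve for detecting among-strain variance with the mixed Cox model
#'
#' For each per-arm sample size in the configuration, simulates
#' `n_replicates` experiments at the first `cv_g` level and computes the
#' power of the mixed-effects Cox variance LRT at level `alpha`.
#'
#' @param config A [study_config()]; `cv_g[1]` is the assumed true CV_G.
#' @param progress Emit progress to stderr. Default TRUE.
#' @return A data.frame: `n_per_arm`, `cv_g`, `power`, `power_se`
#'   (binomial), `n_converged`, `n_replicates`.
#' @export
run_power_curve <- function(config, progress = TRUE) {
  stopifnot(inherits(config, "study_config"))
  cvg <- config$cv_g[1]
  effect <- effect_model(config$mu, sigma_for_cvg(cvg, config$mu),
                         config$sigma_alpha)
  out <- lapply(config$n_per_arm, function(n) {
    design <- panel_design(config$n_strains, n, config$gompertz)
    pvals <- vapply(seq_len(config$n_replicates), function(k) {
      d <- simulate_panel(design, effect,
                          seed = child_seed(config$seed, 7L, round(n),
                                            round(cvg * 1000), k))
      fit <- tryCatch(fit_mixed_cox(d), error = function(e) NULL)
      if (is.null(fit)) NA_real_ else fit$variance_test$p_value
    }, numeric(1))
    pow <- power_estimate(pvals, config$alpha)
    n_ok <- sum(!is.na(pvals))
    if (progress)
      message(sprintf("power: n=%d cv_g=%.2f -> %.3f (%d/%d replicates)",
                      n, cvg, pow, n_ok, config$n_replicates))
    data.frame(n_per_arm = n, cv_g = cvg, power = pow,
               power_se = sqrt(pow * (1 - pow) / n_ok),
               n_converged = n_ok, n_replicates = config$n_replicates)
  })
  do.call(rbind, out)
}

#' Re-analyse a strain-by-diet survival CSV
#'
#' Runs all four estimators on user-supplied survival records (format of
#' [read_panel_csv()]: `strain,diet,age,event`), returning the CV_G
#' comparison across scales and pooling schemes together with per-strain
#' waterfall tables — the standard re-analysis of a published genetic
#' reference panel DR experiment.
#'
#' @param x Path to a CSV, or a survival data.frame.
#' @param test_ref Reference distribution of the variance LRTs (see
#'   [fit_panel()]).
#' @param baseline Include the strain-level random baseline in the mixed
#'   Cox fit (default TRUE; see [fit_mixed_cox()]).
#' @return An object of class `"panel_reanalysis"`: list with `fits` (the
#'   four `panel_fit`s), `cvg_table` (four rows: scale, pooling, overall,
#'   sigma_hat, cv_g, LRT statistic and p), and `waterfall` (per-strain
#'   tables on each scale, ordered by the no-pooling estimate).
#' @export
reanalyze <- function(x, test_ref = c("chisq", "mixture"),
                      baseline = TRUE) {
  test_ref <- match.arg(test_ref)
  data <- if (is.character(x)) read_panel_csv(x) else
    validate_panel(x, drop_incomplete = TRUE)
  if (length(unique(data$strain)) < 2L)
    stop("re-analysis needs at least 2 strains with both diet arms; ",
         "among-strain variance is not estimable from one strain")
  fits <- list(
    md_none = fit_panel(data, "md", "none"),
    md_partial = fit_panel(data, "md", "partial", test_ref = test_ref),
    lnhr_none = fit_panel(data, "lnhr", "none"),
    lnhr_partial = fit_panel(data, "lnhr", "partial", test_ref = test_ref,
                             baseline = baseline))
  cvg_table <- do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    data.frame(estimator = nm, scale = f$scale, pooling = f$pooling,
               overall = f$overall, sigma_hat = f$sigma_hat, cv_g = f$cv_g,
               lrt_statistic = if (is.null(f$variance_test)) NA_real_
                               else f$variance_test$statistic,
               lrt_p = if (is.null(f$variance_test)) NA_real_
                       else f$variance_test$p_value)
  }))
  waterfall <- lapply(c(md = "md", lnhr = "lnhr"), function(sc) {
    none <- fits[[paste0(sc, "_none")]]$strains
    part <- fits[[paste0(sc, "_partial")]]$strains
    tab <- data.frame(strain = none$strain, no_pooling = none$estimate,
                      se = none$se, p_value = none$p_value,
                      partial_pooling = part$estimate[
                        match(none$strain, part$strain)])
    tab <- tab[order(-tab$no_pooling), ]
    rownames(tab) <- NULL
    tab
  })
  structure(list(fits = fits, cvg_table = cvg_table, waterfall = waterfall,
                 n_strains = length(unique(data$strain)), n = nrow(data)),
            class = "panel_reanalysis")
}

#' @export
print.panel_reanalysis <- function(x, ...) {
  cat(sprintf("Strain-panel re-analysis: %d strains, %d animals\n\n",
              x$n_strains, x$n))
  tab <- x$cvg_table
  tab[, 4:8] <- signif(tab[, 4:8], 4)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Write a deterministic synthetic survival fixture CSV
#'
#' Generates a synthetic stand-in for a published genetic-reference-panel
#' DR experiment: by default 40 strains with 11 animals per strain per diet
#' (the 10-12 females per strain per diet of the motivating mouse study),
#' overall lnHR -0.5, genuine among-strain variation in response
#' (`sigma_delta = 0.25`, CV_G 0.5) and mild baseline heterogeneity
#' (`sigma_alpha = 0.2`). Byte-identical output for identical arguments.
#'
#' @param path Output CSV path.
#' @param design A [panel_design()].
#' @param effect An [effect_model()].
#' @param seed Seed. Default 421.
#' @return `path`, invisibly.
#' @export
generate_fixture <- function(path,
                             design = panel_design(n_strains = 40,
                                                   n_per_arm = 11),
                             effect = effect_model(mu = -0.5,
                                                   sigma_delta = 0.25,
                                                   sigma_alpha = 0.2),
                             seed = 421) {
  data <- simulate_panel(design, effect, seed = seed)
  data$age <- round(data$age, 1)
  write_panel_csv(data, path)
}
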