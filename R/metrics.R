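#' Coefficient of genetic variation in response
#'
#' `CV_G = sigma / |overall|`: the among-strain SD of the diet effect
#' divided by the absolute overall effect, on whatever scale both were
#' estimated. Unitless, so comparable across the mean-difference and
#' log-hazard-ratio scales.
#'
#' @param sigma Among-strain SD (>= 0).
#' @param overall Overall effect on the same scale.
#' @return `sigma / abs(overall)`. A zero overall effect leaves the ratio
#'   undefined; `Inf` is returned with a warning.
#' @examples
#' cv_g(106.1, 90.8)  # 1.17
#' cv_g(42.7, 90.8)   # 0.47
#' @export
cv_g <- function(sigma, overall) {
  stopifnot(all(sigma >= 0, na.rm = TRUE))
  out <- ifelse(overall == 0, Inf, sigma / abs(overall))
  if (any(!is.na(overall) & overall == 0))
    warning("overall effect is 0: CV_G undefined, returning Inf")
  out
}

#' Correlation of strain effects between two experiments
#'
#' Pearson correlation of per-strain estimates from two fits of paired
#' experiments on the same genotypes, aligned by strain label. Strains
#' flagged in either fit are excluded. Degenerate cases — fewer than 3
#' usable strains, or zero variance of the estimates in either member (full
#' shrinkage) — return `NA`.
#'
#' @param fit1,fit2 `panel_fit` objects from the two members of a pair.
#' @return A correlation in `[-1, 1]`, or `NA` if undefined.
#' @export
pair_correlation <- function(fit1, fit2) {
  s1 <- fit1$strains[!fit1$strains$flagged, c("strain", "estimate")]
  s2 <- fit2$strains[!fit2$strains$flagged, c("strain", "estimate")]
  m <- merge(s1, s2, by = "strain")
  if (nrow(m) < 3L) return(NA_real_)
  if (stats::sd(m$estimate.x) == 0 || stats::sd(m$estimate.y) == 0)
    return(NA_real_)
  stats::cor(m$estimate.x, m$estimate.y)
}

#' Between-experiment replicability of strain effects
#'
#' The mean Pearson correlation of strain-level effect estimates across
#' pairs of experiments run on the same genotypes. Degenerate pairs (see
#' [pair_correlation()]) are dropped, not scored zero, and their count is
#' reported.
#'
#' @param pairs A list whose elements are length-2 lists of `panel_fit`
#'   objects (the two members of each pair), or a numeric vector of
#'   precomputed pair correlations (possibly containing `NA`).
#' @return A list: `mean` (mean correlation over valid pairs), `n_pairs`
#'   (valid pairs used), `n_dropped` (degenerate pairs dropped).
#' @export
replicability <- function(pairs) {
  cors <- if (is.numeric(pairs)) pairs
          else vapply(pairs, function(p) pair_correlation(p[[1]], p[[2]]),
                      numeric(1))
  if (!length(cors)) stop("no pairs supplied")
  valid <- cors[!is.na(cors)]
  if (!length(valid)) stop("no valid (non-degenerate) pairs")
  list(mean = mean(valid), n_pairs = length(valid),
       n_dropped = sum(is.na(cors)))
}

#' Power as the rejection fraction
#'
#' @param p_values Non-empty numeric vector of p-values (NAs dropped with
#'   their count reflected in the denominator being reduced).
#' @param alpha Significance level in (0, 1). Default 0.05.
#' @return Fraction of (non-missing) p-values strictly below `alpha`.
#' @export
power_estimate <- function(p_values, alpha = 0.05) {
  stopifnot(length(p_values) > 0, alpha > 0, alpha < 1)
  p <- p_values[!is.na(p_values)]
  if (!length(p)) stop("no non-missing p-values")
  mean(p < alpha)
}

#' Median/IQR summary of replicated CV_G estimates
#'
#' Replicated-simulation summary of an estimator: the median and
#' interquartile range of the estimates across replicates, and the bias of
#' the median relative to the true value. Quartiles use linear interpolation
#' (R's default type-7 convention).
#'
#' @param estimates Non-empty numeric vector of per-replicate estimates.
#' @param true_value The generating (true) value.
#' @return A list: `median`, `q1`, `q3`, `iqr`, `bias` (median - true).
#' @examples
#' bias_summary(c(0.1, 0.2, 0.3, 0.4), 0)  # median 0.25, IQR 0.15
#' @export
bias_summary <- function(estimates, true_value) {
  stopifnot(length(estimates) > 0)
  q <- stats::quantile(estimates, c(0.25, 0.5, 0.75), names = FALSE,
                       type = 7, na.rm = TRUE)
  list(median = q[2], q1 = q[1], q3 = q[3], iqr = q[3] - q[1],
       bias = q[2] - true_value)
}
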