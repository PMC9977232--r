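# Independent oracles used across tests. These deliberately re-derive
# quantities by brute force / naive formulas, separate from the package's
# fitting code paths.

# Naive Cox log partial likelihood with Efron ties for an arbitrary linear
# predictor eta (one value per record). Loops over distinct death times.
naive_cox_loglik <- function(eta, age, event) {
  ll <- 0
  for (t in sort(unique(age[event == 1]))) {
    R <- which(age >= t)
    D <- which(age == t & event == 1)
    d <- length(D)
    ll <- ll + sum(eta[D])
    for (k in seq_len(d) - 1)
      ll <- ll - log(sum(exp(eta[R])) - (k / d) * sum(exp(eta[D])))
  }
  ll
}

# Dense grid search for the single-covariate Cox MLE, iteratively refined.
grid_search_lnhr <- function(data, lo = -5, hi = 5, rounds = 4, k = 201) {
  for (r in seq_len(rounds)) {
    beta <- seq(lo, hi, length.out = k)
    ll <- vapply(beta, function(b)
      naive_cox_loglik(b * data$diet, data$age, data$event), numeric(1))
    i <- which.max(ll)
    step <- beta[2] - beta[1]
    lo <- beta[i] - 2 * step
    hi <- beta[i] + 2 * step
  }
  beta[i]
}

# Brute-force maximizer of the penalized partial likelihood over
# (beta, u_1, u_2) for a 2-strain toy dataset at fixed sigma^2.
grid_search_ppl2 <- function(data, sigma2, lo = -4, hi = 4, rounds = 5,
                             k = 21) {
  strain <- as.integer(factor(data$strain))
  rng <- list(c(lo, hi), c(lo, hi), c(lo, hi))
  best <- c(0, 0, 0)
  for (r in seq_len(rounds)) {
    gb <- seq(rng[[1]][1], rng[[1]][2], length.out = k)
    g1 <- seq(rng[[2]][1], rng[[2]][2], length.out = k)
    g2 <- seq(rng[[3]][1], rng[[3]][2], length.out = k)
    val <- -Inf
    for (b in gb) for (u1 in g1) for (u2 in g2) {
      u <- c(u1, u2)
      eta <- data$diet * (b + u[strain])
      v <- naive_cox_loglik(eta, data$age, data$event) -
        sum(u^2) / (2 * sigma2)
      if (v > val) { val <- v; best <- c(b, u1, u2) }
    }
    w <- vapply(rng, function(z) diff(z) / (k - 1), numeric(1))
    rng <- lapply(1:3, function(i) best[i] + c(-2, 2) * w[i])
  }
  list(par = best, value = val)
}

# Mean residual lifespan under the Gompertz model, by numeric integration
# of the survivor function (independent of the package quantile code).
gompertz_mean_oracle <- function(log_a, log_b, shift = 0) {
  a <- exp(log_a + shift); b <- exp(log_b)
  stats::integrate(function(t) exp(-(a / b) * expm1(b * t)), 0, Inf,
                   rel.tol = 1e-10)$value
}

# Small balanced panel with known per-strain values, for hand-arithmetic
# checks of the mean-difference estimators.
toy_md_panel <- function() {
  data.frame(
    strain = rep(c("s1", "s2"), each = 4),
    diet = rep(c(0, 0, 1, 1), 2),
    age = c(800, 820, 900, 940,   # strain 1: MD = 920 - 810 = 110
            700, 740, 760, 800),  # strain 2: MD = 780 - 720 = 60
    event = 1L)
}
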