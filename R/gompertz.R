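#' Gompertz baseline-hazard parameters
#'
#' The mortality hazard is \eqn{h(t) = a e^{bt}}: `a` is the baseline hazard
#' at age zero and `b` the exponential rate of increase with age, both per
#' day. Parameters are held on the log scale, the scale on which rodent
#' estimates are usually reported. The defaults are typical values for ad
#' libitum fed laboratory rodents and put the bulk of mortality beyond 700
#' days with a left-skewed age-at-death distribution.
#'
#' @param log_a Log baseline hazard (per day). Default -11.57.
#' @param log_b Log of the age coefficient (per day). Default -4.9. `b = 0`
#'   (i.e. `log_b = -Inf`) is accepted and gives the exponential
#'   (age-independent hazard) limit.
#' @return An object of class `"gompertz_params"`: a list with elements
#'   `log_a` and `log_b`.
#' @examples
#' gp <- gompertz_params()
#' gompertz_quantile(0.5, gp)            # analytic median age at death
#' gompertz_quantile(0.5, gp, shift = -0.5)  # under a protective hazard shift
#' @export
gompertz_params <- function(log_a = -11.57, log_b = -4.9) {
  stopifnot(is.numeric(log_a), length(log_a) == 1L, is.finite(log_a),
            is.numeric(log_b), length(log_b) == 1L, !is.na(log_b),
            log_b < Inf)
  structure(list(log_a = log_a, log_b = log_b), class = "gompertz_params")
}

#' @export
print.gompertz_params <- function(x, ...) {
  cat(sprintf("Gompertz hazard h(t) = a*exp(b*t): log(a) = %g, log(b) = %g\n",
              x$log_a, x$log_b))
  cat(sprintf("  (a = %.4g /day, b = %.4g /day)\n",
              exp(x$log_a), exp(x$log_b)))
  invisible(x)
}

# Internal: pull (A, b) where A = a * exp(shift) is the shifted baseline.
.gp_ab <- function(params, shift) {
  if (!inherits(params, "gompertz_params"))
    stop("`params` must be a gompertz_params object")
  stopifnot(is.numeric(shift), all(is.finite(shift)))
  list(A = exp(params$log_a + shift), b = exp(params$log_b))
}

#' Gompertz proportional-hazards functions
#'
#' Hazard, survivor and quantile functions of the Gompertz distribution with
#' the hazard multiplied by `exp(shift)` — the proportional-hazards model
#' used for diet effects, so `shift` is a log hazard ratio. Writing
#' \eqn{A = a e^{shift}}, the hazard is \eqn{A e^{bt}}, the survivor function
#' \eqn{S(t) = \exp\{-(A/b)(e^{bt}-1)\}} and its inverse
#' \eqn{t(p) = \log\{1 - (b/A)\log(1-p)\}/b}. When `b = 0` these reduce to
#' the exponential distribution with rate `A`.
#'
#' @param t Age in days (vectorised, `t >= 0`).
#' @param p Probability of death by the returned age (`0 <= p < 1`).
#' @param params A [gompertz_params()] object.
#' @param shift Log hazard ratio applied multiplicatively to the hazard
#'   (default 0). For an animal on diet arm X in strain j this is
#'   `X * (mu + delta_j)` (plus any strain baseline deviation).
#' @return `gompertz_hazard`: hazard rate per day; `gompertz_survival`:
#'   survival probability; `gompertz_quantile`: age in days.
#' @seealso [rgompertz()] for sampling death times.
#' @export
gompertz_hazard <- function(t, params, shift = 0) {
  ab <- .gp_ab(params, shift)
  if (any(t < 0)) stop("negative age `t` is outside the domain")
  ab$A * exp(ab$b * t)
}

#' @rdname gompertz_hazard
#' @export
gompertz_survival <- function(t, params, shift = 0) {
  ab <- .gp_ab(params, shift)
  if (any(t < 0)) stop("negative age `t` is outside the domain")
  if (ab$b == 0) return(exp(-ab$A * t))
  exp(-(ab$A / ab$b) * expm1(ab$b * t))
}

#' @rdname gompertz_hazard
#' @export
gompertz_quantile <- function(p, params, shift = 0) {
  ab <- .gp_ab(params, shift)
  if (any(p < 0 | p >= 1)) stop("`p` must satisfy 0 <= p < 1")
  if (ab$b == 0) return(-log1p(-p) / ab$A)
  # argument of the log is 1 - (b/A) log(1-p) >= 1, so always defined
  log1p(-(ab$b / ab$A) * log1p(-p)) / ab$b
}

#' Sample Gompertz death times
#'
#' Inverse-CDF sampling: draws U ~ Uniform(0,1) and returns
#' `gompertz_quantile(U, params, shift)`. Exact and reproducible under
#' `set.seed()`.
#'
#' @inheritParams gompertz_hazard
#' @param n Number of draws (`n >= 0`).
#' @return Numeric vector of `n` ages at death, in days.
#' @examples
#' set.seed(1)
#' median(rgompertz(1000, gompertz_params()))
#' @export
rgompertz <- function(n, params, shift = 0) {
  stopifnot(length(n) == 1L, n >= 0)
  if (n == 0) return(numeric(0))
  gompertz_quantile(stats::runif(n), params, shift)
}
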