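#' Diet-effect model for a strain panel
#'
#' Describes how dietary restriction (DR) shifts the mortality hazard across
#' the strains of a genetic reference panel. Animal i of strain j has hazard
#' \eqn{h(t) e^{\alpha_j + X_i(\mu + \delta_j)}} where `X_i` is the diet
#' indicator (0 = ad libitum, 1 = DR), `mu` the overall log hazard ratio of
#' DR vs AL, \eqn{\delta_j \sim N(0, \sigma_\delta^2)} the strain deviation
#' in diet response, and \eqn{\alpha_j \sim N(0, \sigma_\alpha^2)} an
#' optional strain deviation in baseline (AL) mortality. The main model has
#' `sigma_alpha = 0`: survival under AL is homogeneous across strains.
#'
#' The coefficient of genetic variation in response is
#' `CV_G = sigma_delta / |mu|`; use [sigma_for_cvg()] to parameterise a
#' model by its target CV_G.
#'
#' @param mu Overall log hazard ratio of DR vs AL (negative = protective).
#' @param sigma_delta SD of strain deviations in the diet effect (>= 0).
#' @param sigma_alpha SD of strain deviations in baseline log hazard (>= 0).
#' @return An object of class `"effect_model"`.
#' @export
effect_model <- function(mu = -0.5, sigma_delta = 0, sigma_alpha = 0) {
  stopifnot(is.finite(mu), length(mu) == 1L,
            is.finite(sigma_delta), sigma_delta >= 0,
            is.finite(sigma_alpha), sigma_alpha >= 0)
  structure(list(mu = mu, sigma_delta = sigma_delta,
                 sigma_alpha = sigma_alpha),
            class = "effect_model")
}

#' @export
print.effect_model <- function(x, ...) {
  cat(sprintf(
    "Diet effect model: mu = %g (lnHR), sigma_delta = %g, sigma_alpha = %g\n",
    x$mu, x$sigma_delta, x$sigma_alpha))
  if (x$mu != 0)
    cat(sprintf("  true CV_G = %.3g\n", x$sigma_delta / abs(x$mu)))
  invisible(x)
}

#' Among-strain SD for a target CV_G
#'
#' @param cv_g Target coefficient of genetic variation (>= 0).
#' @param mu Overall log hazard ratio.
#' @return `cv_g * abs(mu)`.
#' @export
sigma_for_cvg <- function(cv_g, mu) {
  stopifnot(all(cv_g >= 0), is.finite(mu))
  cv_g * abs(mu)
}

#' Design of a strain-panel survival experiment
#'
#' @param n_strains Number of strains (>= 1).
#' @param n_per_arm Animals per strain per diet arm (>= 1); the design is
#'   fully balanced.
#' @param gompertz Baseline mortality, a [gompertz_params()] object.
#' @return An object of class `"panel_design"`.
#' @export
panel_design <- function(n_strains = 40, n_per_arm = 5,
                         gompertz = gompertz_params()) {
  stopifnot(n_strains >= 1, n_per_arm >= 1,
            inherits(gompertz, "gompertz_params"))
  structure(list(n_strains = as.integer(n_strains),
                 n_per_arm = as.integer(n_per_arm),
                 gompertz = gompertz),
            class = "panel_design")
}

#' @export
print.panel_design <- function(x, ...) {
  cat(sprintf("Panel design: %d strains x %d animals per strain per diet\n",
              x$n_strains, x$n_per_arm))
  print(x$gompertz)
  invisible(x)
}

#' Draw strain-level effects
#'
#' Samples the per-strain deviations of the effect model: diet-response
#' deviations `delta` and baseline deviations `alpha`, mutually independent.
#'
#' @param effect An [effect_model()].
#' @param n_strains Number of strains.
#' @param seed Optional seed; when given the draw is reproducible and the
#'   caller's RNG state is untouched.
#' @return A data.frame with columns `strain`, `delta`, `alpha`.
#' @export
draw_strain_effects <- function(effect, n_strains, seed = NULL) {
  stopifnot(inherits(effect, "effect_model"), n_strains >= 1)
  with_seed(seed, {
    data.frame(strain = seq_len(n_strains),
               delta = stats::rnorm(n_strains, 0, effect$sigma_delta),
               alpha = stats::rnorm(n_strains, 0, effect$sigma_alpha))
  })
}

#' Simulate one strain-panel diet experiment
#'
#' Generates a fully balanced experiment: for each strain, `n_per_arm` AL
#' animals with hazard shift \eqn{\alpha_j} and `n_per_arm` DR animals with
#' shift \eqn{\alpha_j + \mu + \delta_j}, death times drawn from the Gompertz
#' model by inverse-CDF sampling. Every animal's death is observed
#' (`event = 1`); censoring is a feature of external data, not of the
#' simulated design.
#'
#' @param design A [panel_design()].
#' @param effect An [effect_model()].
#' @param seed Optional seed for reproducibility.
#' @param strain_effects Optional data.frame as returned by
#'   [draw_strain_effects()], e.g. to share strain effects between paired
#'   experiments. Must cover `design$n_strains` strains.
#' @return A data.frame with columns `strain` (integer), `diet` (0 = AL,
#'   1 = DR), `age` (days) and `event` (all 1), carrying the true strain
#'   effects in `attr(, "strain_effects")` and the generating `design` and
#'   `effect` as attributes.
#' @examples
#' d <- simulate_panel(panel_design(n_strains = 10, n_per_arm = 5),
#'                     effect_model(mu = -0.5, sigma_delta = 0.2), seed = 1)
#' head(d)
#' @export
simulate_panel <- function(design, effect, seed = NULL, strain_effects = NULL) {
  stopifnot(inherits(design, "panel_design"), inherits(effect, "effect_model"))
  J <- design$n_strains
  n <- design$n_per_arm
  if (is.null(strain_effects)) {
    strain_effects <- draw_strain_effects(effect, J,
                                          seed = if (is.null(seed)) NULL
                                                 else child_seed(seed, 0L))
    dt_seed <- if (is.null(seed)) NULL else child_seed(seed, 1L)
  } else {
    if (nrow(strain_effects) != J)
      stop("`strain_effects` must have one row per strain (",
           J, " expected, got ", nrow(strain_effects), ")")
    dt_seed <- seed
  }
  strain <- rep(seq_len(J), each = 2L * n)
  diet <- rep(rep(c(0L, 1L), each = n), times = J)
  shift <- strain_effects$alpha[strain] +
    diet * (effect$mu + strain_effects$delta[strain])
  # gompertz_quantile vectorises over (p, shift) pairs elementwise
  age <- with_seed(dt_seed,
                   gompertz_quantile(stats::runif(length(strain)),
                                     design$gompertz, shift))
  out <- data.frame(strain = strain, diet = diet, age = age,
                    event = rep(1L, length(strain)))
  attr(out, "strain_effects") <- strain_effects
  attr(out, "design") <- design
  attr(out, "effect") <- effect
  out
}

#' Simulate a pair of experiments on the same genotypes
#'
#' Both experiments share a single draw of the strain effects (the genotypes
#' are the same) but have independent death times — the design used to
#' measure between-experiment replicability of strain-specific estimates.
#'
#' @inheritParams simulate_panel
#' @return A list of two datasets as from [simulate_panel()], with identical
#'   `strain_effects` attributes.
#' @export
simulate_panel_pair <- function(design, effect, seed = NULL) {
  eff <- draw_strain_effects(effect, design$n_strains,
                             seed = if (is.null(seed)) NULL
                                    else child_seed(seed, 0L))
  list(simulate_panel(design, effect, strain_effects = eff,
                      seed = if (is.null(seed)) NULL else child_seed(seed, 1L)),
       simulate_panel(design, effect, strain_effects = eff,
                      seed = if (is.null(seed)) NULL else child_seed(seed, 2L)))
}

# Validate a survival data.frame; optionally drop strains missing a diet arm.
validate_panel <- function(data, drop_incomplete = FALSE) {
  need <- c("strain", "diet", "age", "event")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("survival data must have columns strain,diet,age,event; missing: ",
         paste(miss, collapse = ", "))
  if (!all(data$diet %in% c(0, 1)))
    stop("`diet` must be coded 0 (AL) / 1 (DR)")
  if (!all(data$event %in% c(0, 1)))
    stop("`event` must be coded 0/1")
  if (!all(is.finite(data$age)) || any(data$age <= 0))
    stop("`age` must be positive and finite")
  both <- tapply(data$diet, data$strain, function(d) length(unique(d)) == 2L)
  if (any(!both)) {
    bad <- names(both)[!both]
    if (drop_incomplete) {
      warning("dropping strain(s) present in only one diet arm: ",
              paste(bad, collapse = ", "))
      data <- data[!(as.character(data$strain) %in% bad), , drop = FALSE]
      if (!nrow(data)) stop("no strains with both diet arms remain")
    } else {
      stop("strain(s) present in only one diet arm: ",
           paste(bad, collapse = ", "))
    }
  }
  data
}

#' Read and write strain-panel survival CSVs
#'
#' The on-disk exchange format is a plain CSV with header exactly
#' `strain,diet,age,event`: one row per animal, `diet` coded 0 (AL) / 1
#' (DR), `age` in days, `event` 1 if the death was observed. This is both
#' the simulator's output format and the re-analysis input format.
#'
#' @param data A survival data.frame (e.g. from [simulate_panel()]).
#' @param path File path.
#' @return `read_panel_csv`: the validated data.frame;
#'   `write_panel_csv`: `path`, invisibly.
#' @export
write_panel_csv <- function(data, path) {
  data <- validate_panel(data)
  utils::write.csv(data[, c("strain", "diet", "age", "event")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_panel_csv
#' @export
read_panel_csv <- function(path) {
  header <- readLines(path, n = 1L)
  if (!identical(gsub("[\" ]", "", header), "strain,diet,age,event"))
    stop("line 1: header must be exactly `strain,diet,age,event`, got: ",
         header)
  raw <- utils::read.csv(path, colClasses = c("character", "character",
                                              "character", "character"))
  for (i in seq_len(nrow(raw))) {
    num <- suppressWarnings(as.numeric(raw[i, c("diet", "age", "event")]))
    if (any(is.na(num)))
      stop("line ", i + 1L, ": non-numeric diet/age/event field")
  }
  out <- data.frame(strain = raw$strain,
                    diet = as.integer(raw$diet),
                    age = as.numeric(raw$age),
                    event = as.integer(raw$event))
  validate_panel(out, drop_incomplete = TRUE)
}
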