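#' Recipe for a synthetic concentration series
#'
#' Describes how to generate a fixture series with the statistical structure
#' the analysis assumes: a forward-model truth curve, an irregular or regular
#' sampling design over the monitoring window, and multiplicative lognormal
#' measurement noise (the natural error model for a relative-error fitting
#' loss). The defaults emulate the monitored lake-water conditions: a
#' fractional-diffusion truth with `A = 1256`, `alpha = 0.62`,
#' `xi = 5`, `tau = 693` (whole-lake water, Bq m^-3), 40 sampling days over
#' the 234-1981 day window, and 10% relative noise.
#'
#' @param params Truth-model parameter object ([fdm_params()],
#'   [tdm_params()] or [bulgakov_params()]).
#' @param sampling_days Explicit sampling days; if `NULL`, a design of `n`
#'   points over `[day_min, day_max]` with the given `spacing` is used.
#' @param n Number of sampling days in the designed grid (>= 5).
#' @param day_min,day_max Monitoring window in days since release.
#' @param spacing `"uniform"` or `"log"` spacing of the designed grid.
#' @param noise_sd_rel Standard deviation of the lognormal noise on the log
#'   scale (dimensionless); 0 gives the exact model curve.
#' @param medium Series medium label.
#' @param seed RNG seed making generation deterministic.
#' @return A list of class `"synthetic_spec"`.
#' @examples
#' synthetic_spec()
#' synthetic_spec(params = tdm_params(300, 0.01, 80, 5e-4), noise_sd_rel = 0.2)
#' @export
synthetic_spec <- function(params = fdm_params(A = 1256, alpha = 0.62,
                                               xi = 5, tau = 693),
                           sampling_days = NULL, n = 40L,
                           day_min = 234, day_max = 1981,
                           spacing = c("uniform", "log"),
                           noise_sd_rel = 0.1, medium = "water",
                           seed = 1L) {
  spacing <- match.arg(spacing)
  if (is.null(sampling_days)) {
    if (n < 5) stop("`n` must be at least 5.", call. = FALSE)
    if (day_min < 0 || day_max <= day_min) {
      stop("Need 0 <= day_min < day_max.", call. = FALSE)
    }
    sampling_days <- switch(spacing,
      uniform = seq(day_min, day_max, length.out = n),
      log = exp(seq(log(max(day_min, 1)), log(day_max), length.out = n))
    )
  } else {
    if (length(sampling_days) < 5 || any(diff(sampling_days) <= 0) ||
        any(sampling_days < 0)) {
      stop("`sampling_days` must be >= 5 strictly increasing non-negative days.",
           call. = FALSE)
    }
  }
  if (noise_sd_rel < 0) stop("`noise_sd_rel` must be >= 0.", call. = FALSE)
  structure(
    list(params = params, sampling_days = sampling_days,
         noise_sd_rel = noise_sd_rel, medium = medium, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic concentration series
#'
#' Evaluates the truth model of a [synthetic_spec()] at its sampling days and
#' applies multiplicative lognormal noise:
#' \eqn{C_i = C_\mathrm{model}(t_i)\, e^{\varepsilon_i}},
#' \eqn{\varepsilon_i \sim N(0, \mathrm{noise\_sd\_rel}^2)} i.i.d. All values
#' are positive by construction and the result is deterministic given the
#' spec's seed.
#'
#' @param spec A [synthetic_spec()].
#' @param settings [ml_settings()] for Mittag-Leffler evaluation.
#' @return A concentration-series tibble (`day`, `value`, `medium`).
#' @examples
#' generate_series(synthetic_spec(noise_sd_rel = 0, n = 10))
#' @export
generate_series <- function(spec, settings = ml_settings()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  truth <- eval_conc(spec$params, spec$sampling_days, settings)
  eps <- if (spec$noise_sd_rel > 0) {
    withr::with_seed(spec$seed,
                     stats::rnorm(length(truth), 0, spec$noise_sd_rel))
  } else {
    rep(0, length(truth))
  }
  tibble::tibble(
    day = spec$sampling_days,
    value = truth * exp(eps),
    medium = spec$medium
  )
}

#' Generate a paired fish series from a water series
#'
#' Models the observed tight water-fish coupling: the fish concentration is a
#' fixed proportionality times the water concentration at the same sampling
#' days, with independent multiplicative lognormal noise. Units switch to
#' Bq kg^-1 wet weight.
#'
#' @param water A water concentration series data frame.
#' @param proportionality Fish/water concentration ratio (> 0).
#' @param noise_sd_rel Lognormal noise standard deviation on the log scale.
#' @param seed RNG seed.
#' @return A concentration-series tibble with `medium = "fish"`.
#' @examples
#' w <- generate_series(synthetic_spec(noise_sd_rel = 0, n = 10))
#' generate_paired_fish(w, proportionality = 0.25, noise_sd_rel = 0.2, seed = 2)
#' @export
generate_paired_fish <- function(water, proportionality, noise_sd_rel = 0.2,
                                 seed = 1L) {
  water <- as_concentration_series(water)
  if (!is.numeric(proportionality) || proportionality <= 0) {
    stop("`proportionality` must be positive.", call. = FALSE)
  }
  eps <- if (noise_sd_rel > 0) {
    withr::with_seed(as.integer(seed),
                     stats::rnorm(nrow(water), 0, noise_sd_rel))
  } else {
    rep(0, nrow(water))
  }
  tibble::tibble(
    day = water$day,
    value = proportionality * water$value * exp(eps),
    medium = "fish"
  )
}
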