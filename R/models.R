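#' Caesium-137 decay constant
#'
#' Converts a half-life in days to a decay constant \eqn{\lambda_d = \ln 2 /
#' T_{1/2}}. The package default corresponds to the standard caesium-137
#' half-life of 30.08 years (365.25 d/y), i.e. 10986.72 days.
#'
#' @param half_life_days Half-life in days (> 0).
#' @return Decay constant in day^-1.
#' @examples
#' decay_constant()                 # ~6.31e-5 per day for 137Cs
#' decay_constant(log(2))           # 1
#' @export
decay_constant <- function(half_life_days = cs137_half_life_days()) {
  stopifnot(is.numeric(half_life_days), length(half_life_days) == 1)
  if (!is.finite(half_life_days) || half_life_days <= 0) {
    stop("`half_life_days` must be positive.", call. = FALSE)
  }
  log(2) / half_life_days
}

#' @rdname decay_constant
#' @export
cs137_half_life_days <- function() 30.08 * 365.25

#' Fractional-diffusion model parameters
#'
#' Parameter set for the fractional-diffusion prediction law
#' \deqn{C(t) = A \, E_\alpha\!\left(-\xi (t/\tau)^\alpha\right) e^{-\lambda_d t}.}
#' The curve depends on \eqn{\xi} and \eqn{\tau} only through the combination
#' \eqn{\theta = \xi \tau^{-\alpha}}, so the canonical internal parametrization
#' is \eqn{(A, \alpha, \theta, \lambda_d)}. Supply either `theta` directly or
#' the pair `(xi, tau)`; the reported `(xi, tau)` pair follows the convention
#' of holding `tau` fixed and deriving `xi = theta * tau^alpha`.
#'
#' @param A Initial average activity concentration (Bq m^-3 for water,
#'   Bq kg^-1 wet weight for fish), > 0.
#' @param alpha Anomalous-diffusion exponent, in (0, 1). Governs the long-time
#'   power-law decay \eqn{t^{-\alpha}}.
#' @param theta Rate-scale combination \eqn{\xi \tau^{-\alpha}} (day^-alpha),
#'   > 0. Mutually exclusive with supplying both `xi` and `tau`.
#' @param xi Mode-scale parameter \eqn{\xi = \mu_1^2 \sigma^2}
#'   (dimensionless), > 0.
#' @param tau Waiting-time scale (days), > 0. Large `tau` means slow
#'   diffusion.
#' @param lambda_d Radioactive decay constant (day^-1), >= 0; defaults to the
#'   caesium-137 value.
#'
#' @return A list of class `"fdm_params"` with fields `A`, `alpha`, `theta`,
#'   `xi`, `tau`, `lambda_d`.
#' @examples
#' fdm_params(A = 1256, alpha = 0.62, xi = 5, tau = 693)
#' fdm_params(A = 1256, alpha = 0.62, theta = 5 / 693^0.62)
#' @export
fdm_params <- function(A, alpha, theta = NULL, xi = NULL, tau = NULL,
                       lambda_d = decay_constant()) {
  stopifnot(is.numeric(A), length(A) == 1, is.numeric(alpha),
            length(alpha) == 1, is.numeric(lambda_d), length(lambda_d) == 1)
  if (!is.finite(A) || A <= 0) stop("`A` must be positive.", call. = FALSE)
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must lie strictly in (0, 1).", call. = FALSE)
  }
  if (lambda_d < 0) stop("`lambda_d` must be non-negative.", call. = FALSE)
  if (is.null(theta)) {
    if (is.null(xi) || is.null(tau)) {
      stop("Supply `theta`, or both `xi` and `tau`.", call. = FALSE)
    }
    if (xi <= 0 || tau <= 0) stop("`xi` and `tau` must be positive.",
                                  call. = FALSE)
    theta <- xi * tau^(-alpha)
  } else {
    if (theta <= 0) stop("`theta` must be positive.", call. = FALSE)
    if (is.null(tau)) tau <- 1
    if (tau <= 0) stop("`tau` must be positive.", call. = FALSE)
    xi <- theta * tau^alpha
  }
  structure(
    list(A = A, alpha = alpha, theta = theta, xi = xi, tau = tau,
         lambda_d = lambda_d),
    class = "fdm_params"
  )
}

#' Two-component decay model parameters
#'
#' Parameters of \eqn{C(t) = Q_1 e^{-k_1 t} + Q_2 e^{-k_2 t}}. Components are
#' stored in canonical order with the fast component first (`k1 >= k2`). The
#' rates are effective rates that already include radioactive decay; no
#' separate decay factor is applied. With `Q2 = 0` this is the
#' single-component model (SDM).
#'
#' @param Q1,Q2 Component amplitudes (concentration units), >= 0.
#' @param k1,k2 Component decay rates (day^-1), >= 0.
#' @return A list of class `"tdm_params"`.
#' @examples
#' tdm_params(Q1 = 300, k1 = 0.01, Q2 = 80, k2 = 5e-4)
#' tdm_params(Q1 = 300, k1 = 0.01)   # SDM
#' @export
tdm_params <- function(Q1, k1, Q2 = 0, k2 = 0) {
  stopifnot(is.numeric(c(Q1, k1, Q2, k2)), all(is.finite(c(Q1, k1, Q2, k2))))
  if (Q1 < 0 || Q2 < 0) stop("Amplitudes must be non-negative.", call. = FALSE)
  if (k1 < 0 || k2 < 0) stop("Rates must be non-negative.", call. = FALSE)
  if (k1 < k2) {  # canonical ordering: fast component first
    tmp <- c(Q1, k1); Q1 <- Q2; k1 <- k2; Q2 <- tmp[1]; k2 <- tmp[2]
  }
  structure(list(Q1 = Q1, k1 = k1, Q2 = Q2, k2 = k2), class = "tdm_params")
}

#' Bulgakov sediment-diffusion model parameters
#'
#' Physical parameters of the Bulgakov lake-water prediction law
#' \deqn{C(t) = \frac{\sigma_d}{h_w} e^{z^2} \mathrm{erfc}(z)\, e^{-\lambda_d t},
#'   \qquad z(t) = \frac{K_d \sqrt{D_E}}{h_w} t^{1/2}.}
#'
#' @param sigma_d Radionuclide deposition density (Bq m^-2), > 0.
#' @param h_w Average water-column depth (m), > 0.
#' @param K_d Dimensionless sediment-water distribution coefficient, > 0.
#' @param D_E Effective diffusion coefficient in sediments (m^2 day^-1), > 0.
#' @param lambda_d Radioactive decay constant (day^-1), >= 0.
#' @return A list of class `"bulgakov_params"`.
#' @examples
#' bulgakov_params(sigma_d = 2e4, h_w = 10, K_d = 200, D_E = 1e-5)
#' @export
bulgakov_params <- function(sigma_d, h_w, K_d, D_E,
                            lambda_d = decay_constant()) {
  vals <- c(sigma_d = sigma_d, h_w = h_w, K_d = K_d, D_E = D_E)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    stop("All physical Bulgakov parameters must be positive.", call. = FALSE)
  }
  if (lambda_d < 0) stop("`lambda_d` must be non-negative.", call. = FALSE)
  structure(
    list(sigma_d = sigma_d, h_w = h_w, K_d = K_d, D_E = D_E,
         lambda_d = lambda_d),
    class = "bulgakov_params"
  )
}

#' Forward models for activity concentration
#'
#' Evaluate a prediction model at times `t` (days since release).
#' `c_fdm()` is the fractional-diffusion law
#' \eqn{A E_\alpha(-\xi (t/\tau)^\alpha) e^{-\lambda_d t}}, evaluated through
#' [ml_neg()] with argument \eqn{y = \theta t^\alpha}; `c_tdm()` is the sum of
#' two exponentials; `c_bulgakov_full()` is the erfc closed form (computed
#' cancellation-safely through the scaled complementary error function) and
#' `c_bulgakov_approx()` its large-time approximation
#' \eqn{A_B t^{-1/2} e^{-\lambda_d t}}.
#'
#' @param t Time(s) in days; non-negative (strictly positive for
#'   `c_bulgakov_approx()`, whose \eqn{t^{-1/2}} is singular at zero).
#' @param params A parameter object from [fdm_params()], [tdm_params()] or
#'   [bulgakov_params()].
#' @param settings [ml_settings()] controlling the Mittag-Leffler evaluation.
#' @return Numeric vector of concentrations, same length as `t`.
#' @examples
#' p <- fdm_params(A = 1256, alpha = 0.62, xi = 5, tau = 693)
#' c_fdm(c(0, 693, 1981), p)
#' c_tdm(100, tdm_params(Q1 = 300, k1 = 0.01, Q2 = 80, k2 = 5e-4))
#' @export
c_fdm <- function(t, params, settings = ml_settings()) {
  stopifnot(inherits(params, "fdm_params"))
  check_times(t)
  ml_neg(params$alpha, params$theta * t^params$alpha, settings) *
    params$A * exp(-params$lambda_d * t)
}

#' @rdname c_fdm
#' @export
c_tdm <- function(t, params) {
  stopifnot(inherits(params, "tdm_params"))
  check_times(t)
  params$Q1 * exp(-params$k1 * t) + params$Q2 * exp(-params$k2 * t)
}

#' @rdname c_fdm
#' @export
c_bulgakov_full <- function(t, params) {
  stopifnot(inherits(params, "bulgakov_params"))
  check_times(t)
  z <- params$K_d * sqrt(params$D_E) / params$h_w * sqrt(t)
  params$sigma_d / params$h_w * ml_half_closed_form(z) *
    exp(-params$lambda_d * t)
}

#' @rdname c_fdm
#' @param A_B Amplitude of the approximate Bulgakov form
#'   (concentration x day^1/2), > 0.
#' @param lambda_d Decay constant (day^-1) for the approximate form.
#' @export
c_bulgakov_approx <- function(t, A_B, lambda_d = decay_constant()) {
  stopifnot(is.numeric(A_B), length(A_B) == 1, A_B > 0)
  check_times(t)
  if (any(t <= 0)) stop("`t` must be strictly positive: t^(-1/2) is singular at 0.",
                        call. = FALSE)
  A_B * t^(-0.5) * exp(-lambda_d * t)
}

check_times <- function(t) {
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0)) {
    stop("Times `t` must be finite, non-negative days.", call. = FALSE)
  }
  invisible(t)
}

#' Initial concentration from sediment inventory
#'
#' Estimates the initial whole-lake average activity concentration by
#' spreading the sediment areal inventory over the water volume:
#' `inventory_areal * bottom_area / volume`.
#'
#' @param inventory_areal Areal inventory in the deposits (Bq m^-2), > 0.
#' @param bottom_area Lake bottom area (m^2), > 0.
#' @param volume Total lake-water volume (m^3), > 0.
#' @return Concentration in Bq m^-3.
#' @examples
#' initial_concentration_estimate(2e4, 1e6, 1e7)   # 2000 Bq m^-3
#' @export
initial_concentration_estimate <- function(inventory_areal, bottom_area,
                                           volume) {
  vals <- c(inventory_areal, bottom_area, volume)
  if (!is.numeric(vals) || any(!is.finite(vals)) || any(vals <= 0)) {
    stop("All of `inventory_areal`, `bottom_area`, `volume` must be positive.",
         call. = FALSE)
  }
  inventory_areal * bottom_area / volume
}

#' Physical diffusion scales
#'
#' Derived quantities connecting the microscopic walk to the prediction law:
#' the generalised diffusion coefficient \eqn{K_\alpha = \sigma^2/\tau^\alpha}
#' (m^2 day^-alpha), the mode-scale parameter \eqn{\xi = \mu_1^2 \sigma^2}
#' and the rate scale \eqn{\theta = \xi \tau^{-\alpha}}.
#'
#' @param sigma2 Jump-length variance parameter (m^2), > 0.
#' @param mu1 Fundamental spatial eigenvalue (m^-1), > 0; set by the water
#'   depth of the lake.
#' @param tau Waiting-time scale (days), > 0.
#' @param alpha Anomalous-diffusion exponent in (0, 1].
#' @return A tibble with one row: `K_alpha`, `xi`, `theta`.
#' @examples
#' diffusion_scales(sigma2 = 2, mu1 = 3, tau = 693, alpha = 0.62)
#' @export
diffusion_scales <- function(sigma2, mu1, tau, alpha) {
  stopifnot(sigma2 > 0, mu1 > 0, tau > 0, alpha > 0, alpha <= 1)
  xi <- mu1^2 * sigma2
  tibble::tibble(
    K_alpha = sigma2 / tau^alpha,
    xi = xi,
    theta = xi * tau^(-alpha)
  )
}
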