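#' Numerical settings for Mittag-Leffler evaluation
#'
#' Bundles the tolerances and dispatch rule used by [ml_neg()] and friends.
#'
#' @param series_tol Relative truncation tolerance of the power series
#'   (dimensionless, > 0). Summation stops once the next term is below
#'   `series_tol` times the magnitude of the partial sum.
#' @param series_kmax Maximum number of series terms (integer >= 2). Needing
#'   more terms than this is treated as non-convergence: the alternating
#'   series for negative arguments grows before it shrinks and becomes
#'   numerically unstable in double precision at large argument.
#' @param quad_rel_tol Relative tolerance requested from the adaptive
#'   quadrature of the integral representation (> 0).
#' @param dispatch_threshold Argument magnitude `y` above which [ml_neg()]
#'   switches from the series to the integral representation (> 0).
#'
#' @return A list of class `"ml_settings"`.
#' @examples
#' ml_settings()
#' ml_settings(dispatch_threshold = 2)
#' @export
ml_settings <- function(series_tol = 1e-14,
                        series_kmax = 200L,
                        quad_rel_tol = 1e-9,
                        dispatch_threshold = 1) {
  stopifnot(
    is.numeric(series_tol), length(series_tol) == 1, series_tol > 0,
    is.numeric(series_kmax), length(series_kmax) == 1, series_kmax >= 2,
    is.numeric(quad_rel_tol), length(quad_rel_tol) == 1, quad_rel_tol > 0,
    is.numeric(dispatch_threshold), length(dispatch_threshold) == 1,
    dispatch_threshold > 0
  )
  structure(
    list(
      series_tol = series_tol,
      series_kmax = as.integer(series_kmax),
      quad_rel_tol = quad_rel_tol,
      dispatch_threshold = dispatch_threshold
    ),
    class = "ml_settings"
  )
}

check_alpha <- function(alpha, open_right = FALSE) {
  if (!is.numeric(alpha) || length(alpha) != 1 || !is.finite(alpha)) {
    stop("`alpha` must be a single finite number.", call. = FALSE)
  }
  hi_ok <- if (open_right) alpha < 1 else alpha <= 1
  if (alpha <= 0 || !hi_ok) {
    stop(sprintf(
      "`alpha` must lie in (0, 1%s); got %g.",
      if (open_right) ")" else "]", alpha
    ), call. = FALSE)
  }
  invisible(alpha)
}

#' Mittag-Leffler function by truncated power series
#'
#' Evaluates \eqn{E_\alpha(z) = \sum_{k \ge 0} z^k / \Gamma(\alpha k + 1)} by
#' direct summation, stopping when the next term falls below `series_tol`
#' relative to the partial sum. For negative `z` the series alternates and its
#' terms first grow before decaying; once `|z|` is large the growth exhausts
#' double precision, which is why callers should prefer [ml_integral_neg()]
#' there (see [ml_neg()] for automatic dispatch).
#'
#' @param alpha Order, in (0, 1].
#' @param z Real argument (scalar or vector).
#' @param settings An [ml_settings()] object.
#'
#' @return Numeric vector, same length as `z`.
#' @seealso [ml_neg()], [ml_integral_neg()]
#' @examples
#' ml_series(0.62, 0)       # 1
#' ml_series(1, -1)         # exp(-1)
#' @export
ml_series <- function(alpha, z, settings = ml_settings()) {
  check_alpha(alpha)
  stopifnot(is.numeric(z), all(is.finite(z)))
  vapply(z, ml_series_one, numeric(1), alpha = alpha, settings = settings)
}

ml_series_one <- function(alpha, z, settings) {
  if (z == 0) return(1)
  total <- 1
  logaz <- log(abs(z))
  sgn <- if (z < 0) -1 else 1
  for (k in seq_len(settings$series_kmax)) {
    # log-space term avoids overflow of z^k and Gamma(alpha k + 1) separately
    term <- sgn^k * exp(k * logaz - lgamma(alpha * k + 1))
    if (!is.finite(term) || abs(term) > 1e15) {
      stop("Mittag-Leffler series diverged/ill-conditioned: term overflow at k = ",
           k, " for z = ", z, ". Use the integral representation.",
           call. = FALSE)
    }
    total <- total + term
    if (abs(term) <= settings$series_tol * max(abs(total), .Machine$double.xmin)) {
      return(total)
    }
  }
  stop("Mittag-Leffler series diverged/ill-conditioned: no convergence within ",
       settings$series_kmax, " terms for z = ", z,
       ". Use the integral representation.", call. = FALSE)
}

#' Mittag-Leffler function on the negative axis by integral representation
#'
#' Evaluates \eqn{E_\alpha(-y)} for \eqn{0 < \alpha < 1} and \eqn{y \ge 0}
#' through the Gorenflo semi-infinite integral
#' \deqn{E_\alpha(-t^\alpha) = \int_0^\infty \frac{1}{\pi\alpha}
#'   e^{-r^{1/\alpha}} \frac{t^\alpha \sin(\pi\alpha)}
#'   {r^2 + 2 r t^\alpha \cos(\pi\alpha) + t^{2\alpha}} \, dr}
#' evaluated at \eqn{t = y^{1/\alpha}}. Internally the integration variable is
#' rescaled by \eqn{r = y s}, which places the integrand's mass near
#' \eqn{s \approx 1} for every \eqn{y} and lets adaptive quadrature resolve it
#' uniformly. The analytic limit at \eqn{y = 0} is 1 and is returned exactly.
#'
#' @param alpha Order, strictly in (0, 1): the representation carries a
#'   \eqn{\sin(\pi\alpha)} factor and degenerates at the endpoints.
#' @param y Non-negative real argument (scalar or vector); the function value
#'   is \eqn{E_\alpha(-y)}.
#' @param settings An [ml_settings()] object; `quad_rel_tol` is passed to
#'   [stats::integrate()].
#'
#' @return Numeric vector, same length as `y`.
#' @examples
#' ml_integral_neg(0.5, 1)           # exp(1) * erfc(1)
#' ml_integral_neg(0.62, c(0, 5))
#' @export
ml_integral_neg <- function(alpha, y, settings = ml_settings()) {
  check_alpha(alpha, open_right = TRUE)
  stopifnot(is.numeric(y), all(is.finite(y)))
  if (any(y < 0)) stop("`y` must be non-negative.", call. = FALSE)
  vapply(y, ml_integral_one, numeric(1), alpha = alpha, settings = settings)
}

ml_integral_one <- function(alpha, y, settings) {
  if (y == 0) return(1)
  spa <- sinpi(alpha)
  cpa <- cospi(alpha)
  # integrand in the original variable, with t^alpha = y:
  #   (1/(pi a)) exp(-r^(1/a)) * y sin(pi a) / (r^2 + 2 r y cos(pi a) + y^2)
  f <- function(r) {
    exp(-r^(1 / alpha)) * (y * spa / (pi * alpha)) /
      (r^2 + 2 * r * y * cpa + y^2)
  }
  # the exponential factor is exactly zero in double precision beyond
  # r = 690^alpha; the denominator has a resonance near r = -y cos(pi a)
  # (alpha > 1/2) and fine structure near r = y when y is small — both get
  # their own panel boundaries
  rmax <- 690^alpha
  cuts <- c(1, 45^alpha, if (y < 1) y, if (cpa < 0) -y * cpa)
  cuts <- sort(unique(cuts[is.finite(cuts) & cuts > 0 & cuts < rmax]))
  lo <- c(0, cuts)
  hi <- c(cuts, rmax)
  val <- 0
  abserr <- 0
  for (i in seq_along(lo)) {
    res <- tryCatch(
      stats::integrate(f, lo[i], hi[i], rel.tol = settings$quad_rel_tol,
                       abs.tol = 0, subdivisions = 400L),
      error = function(e) stop("Quadrature for E_alpha(-y) failed at y = ", y,
                               ": ", conditionMessage(e), call. = FALSE)
    )
    val <- val + res$value
    abserr <- abserr + res$abs.error
  }
  achieved <- abserr / max(abs(val), .Machine$double.xmin)
  if (achieved > 100 * settings$quad_rel_tol) {
    stop(sprintf(
      "Quadrature for E_alpha(-y) reached relative tolerance %.2e, requested %.2e (y = %g).",
      achieved, settings$quad_rel_tol, y
    ), call. = FALSE)
  }
  val
}

#' Mittag-Leffler function \eqn{E_\alpha(-y)} with automatic method dispatch
#'
#' The workhorse evaluator used throughout the package. For `alpha = 1` (or
#' within 0.005 of it, where the integral representation degenerates through
#' its \eqn{\sin(\pi\alpha)} factor) it returns `exp(-y)` exactly; otherwise
#' it uses the power series for `y <= dispatch_threshold` and the Gorenflo
#' integral beyond, matching the usual practice of abandoning the series where
#' it turns numerically unstable.
#'
#' @inheritParams ml_integral_neg
#' @param alpha Order, in (0, 1].
#'
#' @return Numeric vector of \eqn{E_\alpha(-y)}, same length as `y`.
#' @examples
#' ml_neg(1, 2)            # exp(-2)
#' ml_neg(0.62, c(0.5, 5))
#' @export
ml_neg <- function(alpha, y, settings = ml_settings()) {
  check_alpha(alpha)
  stopifnot(is.numeric(y), all(is.finite(y)))
  if (any(y < 0)) stop("`y` must be non-negative.", call. = FALSE)
  if (alpha > 0.995) return(exp(-y))
  out <- numeric(length(y))
  lo <- y <= settings$dispatch_threshold
  if (any(lo)) out[lo] <- ml_series(alpha, -y[lo], settings)
  if (any(!lo)) out[!lo] <- ml_integral_neg(alpha, y[!lo], settings)
  out
}

#' Closed form of \eqn{E_{1/2}(-z)}
#'
#' For order one half the Mittag-Leffler function on the negative axis has the
#' closed form \eqn{E_{1/2}(-z) = e^{z^2}\,\mathrm{erfc}(z)}. Computed through
#' the scaled complementary error function (`pracma::erfcx`), which avoids the
#' catastrophic cancellation of multiplying a huge exponential by a tiny erfc.
#'
#' @param z Non-negative real (scalar or vector).
#' @return Numeric vector of \eqn{e^{z^2}\mathrm{erfc}(z)}.
#' @examples
#' ml_half_closed_form(0)   # 1
#' ml_half_closed_form(1)   # 0.4275836
#' @export
ml_half_closed_form <- function(z) {
  stopifnot(is.numeric(z), all(is.finite(z)))
  if (any(z < 0)) stop("`z` must be non-negative.", call. = FALSE)
  out <- numeric(length(z))
  small <- z < 25
  out[small] <- pracma::erfcx(z[small])
  if (any(!small)) {
    # asymptotic expansion erfcx(z) ~ (z sqrt(pi))^-1 sum (-1)^k (2k-1)!!/(2z^2)^k;
    # truncation error < 1e-13 relative for z >= 25
    zz <- z[!small]
    w <- 1 / (2 * zz^2)
    out[!small] <- (1 - w + 3 * w^2 - 15 * w^3 + 105 * w^4) / (zz * sqrt(pi))
  }
  out
}

#' Power-law tail of \eqn{E_\alpha(-y)}
#'
#' For large argument \eqn{E_\alpha(-y) \sim 1/(\Gamma(1-\alpha)\, y)}, the
#' leading term of the asymptotic expansion; with \eqn{y = \theta t^\alpha}
#' this is the \eqn{t^{-\alpha}} power-law decay that distinguishes fractional
#' relaxation from exponential decay.
#'
#' @param alpha Order, strictly in (0, 1); at `alpha = 1` the tail is
#'   exponential and this formula does not apply.
#' @param y Positive argument, intended to be large (\eqn{y \gg 1}).
#' @return Numeric vector `1 / (gamma(1 - alpha) * y)`.
#' @examples
#' ml_tail(0.5, 1e4)    # 1 / (sqrt(pi) * 1e4)
#' @export
ml_tail <- function(alpha, y) {
  check_alpha(alpha, open_right = TRUE)
  stopifnot(is.numeric(y), all(is.finite(y)), all(y > 0))
  1 / (gamma(1 - alpha) * y)
}
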