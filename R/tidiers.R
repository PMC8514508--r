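#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted concentration model
#'
#' @param x A `"lakecs_fit"` object.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`, and
#'   `fixed` (TRUE for quantities held constant or derived under a reporting
#'   convention rather than estimated freely).
#' @export
tidy.lakecs_fit <- function(x, ...) {
  p <- x$params
  switch(x$model,
    fdm = tibble::tibble(
      term = c("A", "alpha", "theta", "xi", "tau", "lambda_d"),
      estimate = c(p$A, p$alpha, p$theta, p$xi, p$tau, p$lambda_d),
      fixed = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
    ),
    tdm = tibble::tibble(
      term = c("Q1", "k1", "Q2", "k2"),
      estimate = c(p$Q1, p$k1, p$Q2, p$k2),
      fixed = FALSE
    ),
    sdm = tibble::tibble(
      term = c("Q1", "k1"),
      estimate = c(p$Q1, p$k1),
      fixed = FALSE
    ),
    bulgakov = tibble::tibble(
      term = c("A_B", "lambda_d"),
      estimate = c(p$A_B, p$lambda_d),
      fixed = c(FALSE, TRUE)
    )
  )
}

#' Glance at a fitted concentration model
#'
#' @param x A `"lakecs_fit"` object.
#' @param ... Unused.
#' @return A one-row tibble: `model`, `epsilon2`, `n_points`, `converged`,
#'   `boundary`, `n_iterations`, `grad_norm`.
#' @export
glance.lakecs_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model, epsilon2 = x$epsilon2, n_points = x$n_points,
    converged = x$converged, boundary = x$boundary,
    n_iterations = x$n_iterations, grad_norm = x$grad_norm
  )
}

#' @rdname glance.lakecs_fit
#' @export
glance.lakecs_backtest <- function(x, ...) {
  tibble::tibble(
    model = x$model, split_day = x$split_day,
    epsilon2_train = x$epsilon2_train, epsilon2_test = x$epsilon2_test,
    n_train = x$n_train, n_test = x$n_test,
    converged = x$fit$converged
  )
}

#' @rdname tidy.lakecs_fit
#' @export
tidy.lakecs_backtest <- function(x, ...) {
  tidy(x$fit)
}

#' Tidy a CTRW simulation result
#'
#' @param x A `"ctrw_result"` object.
#' @param ... Unused.
#' @return For `tidy()`, the per-probe MSD tibble (`t`, `msd`,
#'   `n_particles`); for `glance()`, a one-row summary with the fitted
#'   exponent.
#' @export
tidy.ctrw_result <- function(x, ...) {
  x$msd
}

#' @rdname tidy.ctrw_result
#' @export
glance.ctrw_result <- function(x, ...) {
  tibble::tibble(
    alpha = x$config$alpha,
    fitted_exponent = x$fitted_exponent,
    stderr = x$stderr,
    n_particles = x$config$n_particles,
    range_warning = x$range_warning
  )
}

#' Compare models on one series
#'
#' Fits several models to the same series and reports one squared relative
#' error per model, side by side.
#'
#' @inheritParams fit_model
#' @param models Character vector of model names to fit.
#' @param ... Passed on to [fit_model()].
#' @return A tibble with one [glance.lakecs_fit()] row per model.
#' @examples
#' series <- generate_series(synthetic_spec(noise_sd_rel = 0.1, seed = 3))
#' compare_models(series, c("fdm", "tdm"))
#' @export
compare_models <- function(data, models = c("fdm", "tdm"), ...) {
  purrr::map_dfr(models, function(m) glance(fit_model(data, m, ...)))
}
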