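#' Validate a concentration series data frame
#'
#' The package's tabular exchange format is a data frame with a `day` column
#' (days since release, strictly increasing, >= 0) and a `value` column
#' (activity concentration, strictly positive — the relative-error loss is
#' undefined at zero). An optional `medium` column ("water" or "fish") is
#' carried along.
#'
#' @param data A data frame with columns `day` and `value`.
#' @param medium Optional medium label applied when `data` has no `medium`
#'   column.
#' @return A tibble sorted by `day` with columns `day`, `value`, `medium`.
#' @examples
#' as_concentration_series(data.frame(day = c(1, 2, 3), value = c(3, 2, 1)))
#' @export
as_concentration_series <- function(data, medium = NULL) {
  if (!is.data.frame(data)) stop("`data` must be a data frame.", call. = FALSE)
  missing_cols <- setdiff(c("day", "value"), names(data))
  if (length(missing_cols) > 0) {
    stop("`data` is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::as_tibble(data)
  if (!is.numeric(out$day) || !is.numeric(out$value)) {
    stop("`day` and `value` must be numeric.", call. = FALSE)
  }
  bad <- which(!is.finite(out$day) | out$day < 0)
  if (length(bad) > 0) {
    stop("Non-finite or negative `day` at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(out$value) | out$value <= 0)
  if (length(bad) > 0) {
    stop("Non-positive `value` at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "),
         ". Relative-error fitting divides by the measured value; ",
         "zero or negative concentrations are rejected, not dropped.",
         call. = FALSE)
  }
  if (!("medium" %in% names(out))) {
    out$medium <- if (is.null(medium)) NA_character_ else medium
  }
  out <- dplyr::arrange(out, .data$day)
  dup <- which(duplicated(out$day))
  if (length(dup) > 0) {
    stop("Duplicate `day` at row(s): ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Squared relative error
#'
#' The fitting objective
#' \eqn{\epsilon^2 = \sum_i \left((C_{m_i} - C(t_i))/C_{m_i}\right)^2},
#' dimensionless and invariant under rescaling of the concentration unit.
#'
#' @param measured Measured concentrations, all > 0.
#' @param predicted Model values aligned to the same times.
#' @return The scalar squared relative error.
#' @examples
#' epsilon2(100, 90)                # 0.01
#' epsilon2(c(2, 4), c(1, 5))       # 0.3125
#' @export
epsilon2 <- function(measured, predicted) {
  stopifnot(is.numeric(measured), is.numeric(predicted))
  if (length(measured) != length(predicted)) {
    stop("`measured` and `predicted` must have equal length.", call. = FALSE)
  }
  if (any(!is.finite(measured)) || any(measured <= 0)) {
    stop("All measured values must be positive: the relative error divides by them.",
         call. = FALSE)
  }
  sum(((measured - predicted) / measured)^2)
}

# ---- internal model evaluation dispatch ------------------------------------

eval_conc <- function(params, t, settings = ml_settings()) {
  switch(class(params)[1],
    fdm_params = c_fdm(t, params, settings),
    tdm_params = c_tdm(t, params),
    bulgakov_params = c_bulgakov_full(t, params),
    bulgakov_approx_params = c_bulgakov_approx(t, params$A_B, params$lambda_d),
    stop("Unknown parameter class: ", class(params)[1], call. = FALSE)
  )
}

# alpha bounds used by the smooth logit reparametrization
.alpha_lo <- 0.01
.alpha_hi <- 0.99

alpha_to_u <- function(a) stats::qlogis((a - .alpha_lo) / (.alpha_hi - .alpha_lo))
u_to_alpha <- function(u) .alpha_lo + (.alpha_hi - .alpha_lo) * stats::plogis(u)

pack_params <- function(model, params) {
  switch(model,
    fdm = c(logA = log(params$A), ua = alpha_to_u(params$alpha),
            logtheta = log(params$theta)),
    tdm = c(logQ1 = log(params$Q1), logk1 = log(params$k1),
            logQ2 = log(params$Q2), logk2 = log(params$k2)),
    sdm = c(logQ1 = log(params$Q1), logk1 = log(params$k1)),
    bulgakov = c(logA_B = log(params$A_B))
  )
}

unpack_params <- function(model, u, lambda_d, tau_report) {
  switch(model,
    fdm = fdm_params(A = exp(u[[1]]), alpha = u_to_alpha(u[[2]]),
                     theta = exp(u[[3]]), tau = tau_report,
                     lambda_d = lambda_d),
    tdm = tdm_params(Q1 = exp(u[[1]]), k1 = exp(u[[2]]),
                     Q2 = exp(u[[3]]), k2 = exp(u[[4]])),
    sdm = tdm_params(Q1 = exp(u[[1]]), k1 = exp(u[[2]])),
    bulgakov = structure(list(A_B = exp(u[[1]]), lambda_d = lambda_d),
                         class = "bulgakov_approx_params")
  )
}

n_free_params <- function(model) {
  switch(model, fdm = 3L, tdm = 4L, sdm = 2L, bulgakov = 1L)
}

default_inits <- function(model, data, lambda_d) {
  t <- data$day
  v <- data$value
  n <- length(t)
  if (model == "fdm") {
    # two starts bracketing the subdiffusive range: the relative-error surface
    # has a long curved valley in (alpha, theta) and a single start can settle
    # in a local minimum on the wrong side of it
    t_mid <- t[ceiling(n / 2)]
    return(lapply(c(0.4, 0.8), function(a0) {
      # theta such that the Mittag-Leffler argument is ~1 at the midpoint,
      # i.e. the curve has roughly halved there
      list(A = v[1], alpha = a0, theta = 1 / t_mid^a0)
    }))
  }
  list(default_init_single(model, data, lambda_d))
}

default_init_single <- function(model, data, lambda_d) {
  t <- data$day
  v <- data$value
  n <- length(t)
  switch(model,
    tdm = {
      # log-linear seeds from the early and late thirds of the series
      early <- seq_len(max(2, floor(n / 3)))
      late <- seq.int(n - max(2, floor(n / 3)) + 1, n)
      fl <- stats::lm(log(v[late]) ~ t[late])
      k2 <- max(-stats::coef(fl)[[2]], 1e-6)
      Q2 <- exp(stats::coef(fl)[[1]])
      resid_early <- pmax(v[early] - Q2 * exp(-k2 * t[early]), 0.05 * v[early])
      fe <- stats::lm(log(resid_early) ~ t[early])
      k1 <- max(-stats::coef(fe)[[2]], 10 * k2)
      Q1 <- exp(stats::coef(fe)[[1]])
      list(Q1 = Q1, k1 = k1, Q2 = Q2, k2 = k2)
    },
    sdm = {
      fl <- stats::lm(log(v) ~ t)
      list(Q1 = exp(stats::coef(fl)[[1]]),
           k1 = max(-stats::coef(fl)[[2]], 1e-8))
    },
    bulgakov = {
      list(A_B = stats::median(v * sqrt(t) * exp(lambda_d * t)))
    }
  )
}

init_to_params <- function(model, init, lambda_d, tau_report) {
  switch(model,
    fdm = fdm_params(A = init$A, alpha = init$alpha, theta = init$theta,
                     tau = tau_report, lambda_d = lambda_d),
    tdm = tdm_params(Q1 = init$Q1, k1 = init$k1, Q2 = init$Q2, k2 = init$k2),
    sdm = tdm_params(Q1 = init$Q1, k1 = init$k1),
    bulgakov = structure(list(A_B = init$A_B, lambda_d = lambda_d),
                         class = "bulgakov_approx_params")
  )
}

#' Fit a prediction model by relative-error Levenberg-Marquardt
#'
#' Minimises the squared relative error [epsilon2()] over the model
#' parameters using the Levenberg-Marquardt algorithm
#' (`minpack.lm::nls.lm`) on the residual vector
#' \eqn{r_i = (C_{m_i} - C(t_i))/C_{m_i}}. The fractional-diffusion model is
#' fitted in the canonical \eqn{(A, \alpha, \theta)} space: the curve depends
#' on \eqn{\xi} and \eqn{\tau} only through \eqn{\theta = \xi\tau^{-\alpha}},
#' so fitting \eqn{\xi} and \eqn{\tau} separately would be degenerate.
#' Positivity is enforced by log transforms and \eqn{\alpha \in (0.01, 0.99)}
#' by a smooth logit transform, keeping the internal problem unconstrained.
#' The decay constant is held fixed (a known nuclide property, not a fitting
#' parameter). Deterministic given `(data, init, control)`.
#'
#' @param data A concentration series data frame (see
#'   [as_concentration_series()]).
#' @param model One of `"fdm"`, `"tdm"`, `"sdm"`, `"bulgakov"` (the
#'   single-parameter approximate Bulgakov form \eqn{A_B t^{-1/2}
#'   e^{-\lambda_d t}}).
#' @param init Optional named list of starting values (`A`, `alpha`, `theta`
#'   for FDM; `Q1`, `k1`, `Q2`, `k2` for TDM; `Q1`, `k1` for SDM; `A_B` for
#'   Bulgakov). When `NULL`, the package's seeding rules apply: for FDM, two
#'   Levenberg-Marquardt starts bracketing the subdiffusive range
#'   (`alpha0` of 0.4 and 0.8, `A0` the first measured value, `theta0` such
#'   that the Mittag-Leffler argument reaches 1 at the series midpoint) with
#'   the lower-objective run kept; log-linear segment fits seed the
#'   exponential components.
#' @param lambda_d Fixed decay constant (day^-1).
#' @param tau_report Reporting convention for the non-identifiable
#'   \eqn{(\xi,\tau)} pair: `tau` is held at this value and
#'   \eqn{\xi = \theta\tau^\alpha} derived from it.
#' @param settings [ml_settings()] for Mittag-Leffler evaluation.
#' @param max_iter Maximum Levenberg-Marquardt iterations.
#'
#' @return An object of class `"lakecs_fit"`: a list with `model`, `params`
#'   (fitted parameter object), `epsilon2`, `n_points`, `converged`,
#'   `boundary`, `n_iterations`, `grad_norm`, `data`, and `settings`. Use
#'   [tidy()][generics::tidy], [glance()][generics::glance],
#'   [predict.lakecs_fit()] and [ggplot2::autoplot()] on it.
#' @examples
#' spec <- synthetic_spec(noise_sd_rel = 0, n = 20)
#' fit <- fit_model(generate_series(spec), "fdm")
#' glance(fit)
#' @export
fit_model <- function(data, model = c("fdm", "tdm", "sdm", "bulgakov"),
                      init = NULL, lambda_d = decay_constant(),
                      tau_report = 693, settings = ml_settings(),
                      max_iter = 100L) {
  model <- match.arg(model)
  data <- as_concentration_series(data)
  npar <- n_free_params(model)
  if (nrow(data) < max(5L, npar + 1L)) {
    stop("Need at least ", max(5L, npar + 1L), " points to fit a ", npar,
         "-parameter model; got ", nrow(data), ".", call. = FALSE)
  }
  if (model == "bulgakov" && any(data$day <= 0)) {
    stop("Bulgakov approximate form requires strictly positive days.",
         call. = FALSE)
  }
  inits <- if (is.null(init)) default_inits(model, data, lambda_d) else list(init)

  resid_fn <- function(u) {
    p <- unpack_params(model, u, lambda_d, tau_report)
    pred <- eval_conc(p, data$day, settings)
    (data$value - pred) / data$value
  }
  runs <- lapply(inits, function(ini) {
    u0 <- pack_params(model, init_to_params(model, ini, lambda_d, tau_report))
    minpack.lm::nls.lm(
      par = u0, fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = max_iter, ftol = 1e-14,
                                           ptol = 1e-12)
    )
  })
  fit <- runs[[which.min(vapply(runs, function(r) r$deviance, numeric(1)))]]
  u_hat <- stats::coef(fit)
  params <- unpack_params(model, u_hat, lambda_d, tau_report)
  pred <- eval_conc(params, data$day, settings)
  eps2 <- epsilon2(data$value, pred)

  # forward-difference gradient of the objective in the transformed space
  g <- vapply(seq_along(u_hat), function(j) {
    h <- 1e-6 * max(1, abs(u_hat[j]))
    up <- u_hat; up[j] <- up[j] + h
    (sum(resid_fn(up)^2) - eps2) / h
  }, numeric(1))

  boundary <- FALSE
  if (model == "fdm") {
    a <- params$alpha
    boundary <- a < .alpha_lo + 0.005 || a > .alpha_hi - 0.005
  }
  converged <- fit$info %in% 1:4 && !boundary

  structure(
    list(
      model = model, params = params, epsilon2 = eps2,
      n_points = nrow(data), converged = converged, boundary = boundary,
      n_iterations = fit$niter, grad_norm = sqrt(sum(g^2)),
      lm_info = fit$info, lm_message = fit$message,
      rsstrace = fit$rsstrace,
      data = data, lambda_d = lambda_d, settings = settings
    ),
    class = "lakecs_fit"
  )
}

#' @export
print.lakecs_fit <- function(x, ...) {
  cat("<lakecs_fit> ", toupper(x$model), " fit, ", x$n_points, " points\n",
      sep = "")
  cat("  epsilon^2 = ", format(x$epsilon2, digits = 6),
      if (x$converged) "  (converged" else "  (NOT converged",
      if (x$boundary) ", at parameter boundary)\n" else ")\n", sep = "")
  print(generics::tidy(x))
  invisible(x)
}

#' Predict from a fitted model
#'
#' @param object A `"lakecs_fit"` object.
#' @param t Days at which to evaluate the fitted curve; defaults to the
#'   fitted series' own days.
#' @param ... Unused.
#' @return A tibble with columns `day` and `value`.
#' @export
predict.lakecs_fit <- function(object, t = NULL, ...) {
  if (is.null(t)) t <- object$data$day
  predict_curve(object$params, t, settings = object$settings)
}

#' Evaluate a model curve on a time grid
#'
#' @param params A parameter object ([fdm_params()], [tdm_params()],
#'   [bulgakov_params()]).
#' @param t_grid Non-negative days.
#' @param settings [ml_settings()].
#' @return A tibble with columns `day`, `value`.
#' @examples
#' p <- fdm_params(A = 1256, alpha = 0.62, xi = 5, tau = 693)
#' predict_curve(p, c(0, 1000, 10000))
#' @export
predict_curve <- function(params, t_grid, settings = ml_settings()) {
  check_times(t_grid)
  tibble::tibble(day = t_grid, value = eval_conc(params, t_grid, settings))
}

#' Blind-test backtest of a prediction model
#'
#' Fits the model to the early part of the series (days `<= split_day`,
#' inclusive) and evaluates the squared relative error of the frozen fitted
#' curve on the held-out later points (days `> split_day`). This is the
#' protocol used to compare predictive skill between models: train on an
#' early window, score on the later one.
#'
#' @inheritParams fit_model
#' @param split_day Last day included in the training window; must lie
#'   strictly inside the series' time range so both partitions are non-empty.
#' @param ... Passed on to [fit_model()].
#' @return An object of class `"lakecs_backtest"`: list with `split_day`,
#'   `fit` (the training [fit_model()] result), `epsilon2_train`,
#'   `epsilon2_test`, `n_train`, `n_test`, and `test` (held-out tibble with
#'   predictions).
#' @examples
#' series <- generate_series(synthetic_spec(noise_sd_rel = 0.05, seed = 1))
#' bt <- backtest(series, split_day = 1527, model = "fdm")
#' glance(bt)
#' @export
backtest <- function(data, split_day, model = c("fdm", "tdm", "sdm", "bulgakov"),
                     ...) {
  model <- match.arg(model)
  data <- as_concentration_series(data)
  train <- dplyr::filter(data, .data$day <= split_day)
  test <- dplyr::filter(data, .data$day > split_day)
  if (nrow(train) == 0 || nrow(test) == 0) {
    stop("`split_day` = ", split_day, " must split the series into non-empty ",
         "train and test partitions (range ", min(data$day), "-",
         max(data$day), ").", call. = FALSE)
  }
  fit <- fit_model(train, model, ...)
  pred <- predict(fit, test$day)
  test$predicted <- pred$value
  structure(
    list(
      split_day = split_day, model = model, fit = fit,
      epsilon2_train = fit$epsilon2,
      epsilon2_test = epsilon2(test$value, test$predicted),
      n_train = nrow(train), n_test = nrow(test), test = test
    ),
    class = "lakecs_backtest"
  )
}

#' @export
print.lakecs_backtest <- function(x, ...) {
  cat("<lakecs_backtest> ", toupper(x$model), ", split at day ", x$split_day,
      "\n  train: n = ", x$n_train, ", epsilon^2 = ",
      format(x$epsilon2_train, digits = 6),
      "\n  test:  n = ", x$n_test, ", epsilon^2 = ",
      format(x$epsilon2_test, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Water-fish correlation
#'
#' Pearson correlation between paired water and fish activity concentrations.
#' Points are paired by nearest-neighbour matching in time within
#' `pairing_window` days, each observation used at most once (greedy matching
#' by ascending time difference).
#'
#' @param water,fish Concentration series data frames (columns `day`,
#'   `value`).
#' @param pairing_window Maximum |time difference| in days for a valid pair.
#' @return A one-row tibble with `r` (Pearson correlation), `n_pairs` and
#'   `pairing_window`; the matched pairs are attached as attribute
#'   `"pairs"`.
#' @examples
#' w <- data.frame(day = 1:10 * 100, value = exp(-(1:10) / 5) * 100)
#' f <- data.frame(day = 1:10 * 100, value = exp(-(1:10) / 5) * 25)
#' correlate_media(w, f)$r    # 1
#' @export
correlate_media <- function(water, fish, pairing_window = 30) {
  water <- as_concentration_series(water)
  fish <- as_concentration_series(fish)
  cand <- tidyr::expand_grid(i = seq_len(nrow(water)), j = seq_len(nrow(fish)))
  cand$dt <- abs(water$day[cand$i] - fish$day[cand$j])
  cand <- dplyr::arrange(dplyr::filter(cand, .data$dt <= pairing_window),
                         .data$dt)
  used_w <- logical(nrow(water))
  used_f <- logical(nrow(fish))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand$i[k]; j <- cand$j[k]
    if (!used_w[i] && !used_f[j]) {
      used_w[i] <- TRUE; used_f[j] <- TRUE; keep[k] <- TRUE
    }
  }
  pairs <- cand[keep, ]
  if (nrow(pairs) < 3) {
    stop("Fewer than 3 water-fish pairs within ", pairing_window,
         " days; cannot compute a correlation.", call. = FALSE)
  }
  pairs_tbl <- tibble::tibble(
    day_water = water$day[pairs$i], water = water$value[pairs$i],
    day_fish = fish$day[pairs$j], fish = fish$value[pairs$j]
  )
  out <- tibble::tibble(
    r = stats::cor(pairs_tbl$water, pairs_tbl$fish, method = "pearson"),
    n_pairs = nrow(pairs_tbl),
    pairing_window = pairing_window
  )
  attr(out, "pairs") <- pairs_tbl
  out
}
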