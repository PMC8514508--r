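#' Plot a fitted concentration model
#'
#' Measured points with the fitted curve overlaid, concentration on a log
#' scale.
#'
#' @param object A `"lakecs_fit"` object.
#' @param t_grid Days at which to draw the fitted curve; defaults to 200
#'   points spanning the data.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lakecs_fit <- function(object, t_grid = NULL, ...) {
  d <- object$data
  if (is.null(t_grid)) {
    t_grid <- seq(min(d$day), max(d$day), length.out = 200)
  }
  curve <- predict(object, t_grid)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$day, y = .data$value)) +
    ggplot2::geom_point(colour = "firebrick") +
    ggplot2::geom_line(data = curve) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "Days since release",
      y = "Activity concentration",
      title = sprintf("%s fit, ε² = %.3g", toupper(object$model),
                      object$epsilon2)
    )
}

#' Plot a backtest
#'
#' Training points, held-out points and the frozen fitted curve, with the
#' split day marked.
#'
#' @param object A `"lakecs_backtest"` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lakecs_backtest <- function(object, ...) {
  d <- object$fit$data
  d$partition <- "train"
  te <- object$test[, c("day", "value", "medium")]
  te$partition <- "test"
  all <- dplyr::bind_rows(d, te)
  t_grid <- seq(min(all$day), max(all$day), length.out = 200)
  curve <- predict(object$fit, t_grid)
  ggplot2::ggplot(all, ggplot2::aes(x = .data$day, y = .data$value)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$partition)) +
    ggplot2::geom_line(data = curve) +
    ggplot2::geom_vline(xintercept = object$split_day, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "Days since release", y = "Activity concentration",
      title = sprintf("%s blind test: train ε² = %.3g, test ε² = %.3g",
                      toupper(object$model), object$epsilon2_train,
                      object$epsilon2_test)
    )
}

#' Plot a CTRW mean squared displacement
#'
#' MSD against time in log-log space with the fitted power law and, for
#' reference, the configured exponent \eqn{\alpha}.
#'
#' @param object A `"ctrw_result"` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ctrw_result <- function(object, ...) {
  msd <- object$msd
  ggplot2::ggplot(msd, ggplot2::aes(x = .data$t, y = .data$msd)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "t (days)", y = "MSD (m²)",
      title = sprintf("CTRW MSD: fitted exponent %.3f (α = %.2f)",
                      object$fitted_exponent, object$config$alpha)
    )
}
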