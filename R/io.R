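#' Read and write concentration series CSV files
#'
#' The interchange format is a UTF-8, comma-separated, dot-decimal CSV with
#' header `day,value[,medium]`: `day` is days since release (>= 0, strictly
#' increasing after sorting, duplicates rejected), `value` a positive
#' activity concentration. `write_series_csv()` writes values at full
#' round-trip precision, so write-then-read is lossless.
#'
#' @param path File path.
#' @return `read_series_csv()` returns a validated concentration-series
#'   tibble; `write_series_csv()` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_series_csv(generate_series(synthetic_spec(n = 8)), f)
#' read_series_csv(f)
#' @export
read_series_csv <- function(path) {
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  # base read.csv parses doubles through strtod, which is correctly rounded,
  # so write-then-read round-trips bit-for-bit
  raw <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  missing_cols <- setdiff(c("day", "value"), names(raw))
  if (length(missing_cols) > 0) {
    stop("CSV ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in c("day", "value")) {
    if (!is.numeric(raw[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(raw[[col]]))))
      stop("Non-numeric `", col, "` in ", path, " at data row(s): ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
  }
  as_concentration_series(raw)
}

#' @rdname read_series_csv
#' @param data A concentration series data frame.
#' @export
write_series_csv <- function(data, path) {
  data <- as_concentration_series(data)
  readr::write_csv(data, path)
  invisible(path)
}

#' Write a JSON fit report
#'
#' Serialises a fitted model to JSON: the model kind, the canonical and
#' derived parameters (for the fractional-diffusion model, `xi` and `tau`
#' under the fixed-`tau` reporting convention), the squared relative error, a
#' convergence block, the package version and a hash of the numerical
#' settings. Non-convergence is carried prominently, never silently dropped.
#'
#' @param fit A `"lakecs_fit"` object.
#' @param path Output path.
#' @return The report list, invisibly.
#' @examples
#' fit <- fit_model(generate_series(synthetic_spec(noise_sd_rel = 0)), "fdm")
#' f <- tempfile(fileext = ".json")
#' write_fit_report(fit, f)
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "lakecs_fit"))
  td <- tidy(fit)
  report <- list(
    model = fit$model,
    params = stats::setNames(as.list(td$estimate), td$term),
    epsilon2 = fit$epsilon2,
    n_points = fit$n_points,
    convergence = list(
      converged = fit$converged,
      boundary = fit$boundary,
      n_iterations = fit$n_iterations,
      grad_norm = fit$grad_norm,
      lm_info = fit$lm_info,
      lm_message = fit$lm_message
    ),
    lambda_d = fit$lambda_d,
    half_life_days = log(2) / fit$lambda_d,
    software_version = as.character(utils::packageVersion("lakecs")),
    config_hash = rlang::hash(list(fit$settings, fit$lambda_d))
  )
  ok <- tryCatch({
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = I(17),
                         pretty = TRUE)
    TRUE
  }, error = function(e) {
    stop("Cannot write fit report to ", path, ": ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(report)
}

#' Read back a JSON fit report
#'
#' @param path Path written by [write_fit_report()].
#' @return The report as a list.
#' @export
read_fit_report <- function(path) {
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}
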