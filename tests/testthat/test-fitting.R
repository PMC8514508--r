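test_that("squared relative error matches hand-computed values", {
  expect_equal(epsilon2(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(epsilon2(100, 90), 0.01)
  expect_equal(epsilon2(c(2, 4), c(1, 5)), 0.3125)
  # invariant under unit rescaling
  m <- c(3, 7, 11); p <- c(2.5, 8, 10)
  expect_equal(epsilon2(1000 * m, 1000 * p), epsilon2(m, p))
  expect_error(epsilon2(c(1, 2), c(1, 2, 3)), "equal length")
  expect_error(epsilon2(c(1, 0), c(1, 1)), "positive")
})

test_that("series validation enforces the fitting contract", {
  expect_error(as_concentration_series(data.frame(day = 1:3)), "value")
  expect_error(
    as_concentration_series(data.frame(day = c(1, 2), value = c(1, -2))),
    "row\\(s\\): 2"
  )
  expect_error(
    as_concentration_series(data.frame(day = c(1, 2, 2), value = c(1, 2, 3))),
    "Duplicate"
  )
  s <- as_concentration_series(data.frame(day = c(3, 1, 2), value = c(30, 10, 20)))
  expect_equal(s$day, c(1, 2, 3))  # sorted
})

test_that("noiseless synthetic data are recovered essentially exactly", {
  truth <- reference_fdm()
  s <- generate_series(synthetic_spec(params = truth, noise_sd_rel = 0))
  fit <- fit_model(s, "fdm")
  expect_true(fit$converged)
  expect_lt(abs(fit$params$alpha - truth$alpha), 1e-3)
  expect_lt(abs(fit$params$theta - truth$theta) / truth$theta, 1e-3)
  expect_lt(fit$epsilon2, 1e-10)

  tt <- tdm_params(Q1 = 300, k1 = 0.01, Q2 = 80, k2 = 5e-4)
  st <- generate_series(synthetic_spec(params = tt, noise_sd_rel = 0))
  ft <- fit_model(st, "tdm")
  expect_lt(ft$epsilon2, 1e-12)
  expect_equal(ft$params$Q1, 300, tolerance = 1e-6)
  expect_equal(ft$params$k2, 5e-4, tolerance = 1e-6)
})

test_that("a flat series drives the FDM fit to a flagged boundary, not a crash", {
  flat <- data.frame(day = seq(100, 1000, length.out = 10),
                     value = rep(100, 10))
  fit <- fit_model(flat, "fdm")
  expect_s3_class(fit, "lakecs_fit")
  expect_true(fit$boundary || !fit$converged)
})

test_that("objective is non-increasing over accepted Levenberg-Marquardt steps", {
  s <- generate_series(synthetic_spec(noise_sd_rel = 0.1, seed = 11))
  fit <- fit_model(s, "fdm", init = list(A = s$value[1], alpha = 0.5,
                                         theta = 1 / s$day[20]^0.5))
  expect_true(all(diff(fit$rsstrace) <= 1e-12))
})

test_that("fitted epsilon2 agrees with an independent recomputation", {
  s <- generate_series(synthetic_spec(noise_sd_rel = 0.1, seed = 4))
  for (m in c("fdm", "tdm", "sdm", "bulgakov")) {
    fit <- fit_model(s, m)
    pred <- predict(fit)$value
    direct <- sum(((s$value - pred) / s$value)^2)
    expect_identical(fit$epsilon2, direct)
  }
})

test_that("backtest scores held-out points with frozen parameters", {
  s <- generate_series(synthetic_spec(noise_sd_rel = 0.1, seed = 5))
  bt <- backtest(s, split_day = 1527, model = "fdm")
  # partition is exhaustive and disjoint, train side inclusive
  expect_equal(bt$n_train + bt$n_test, nrow(s))
  expect_true(all(bt$fit$data$day <= 1527))
  expect_true(all(bt$test$day > 1527))
  # held-out error equals direct summation of the definition
  direct <- sum(((bt$test$value - bt$test$predicted) / bt$test$value)^2)
  expect_identical(bt$epsilon2_test, direct)
  expect_error(backtest(s, split_day = 5000, model = "fdm"), "non-empty")
  expect_error(backtest(s, split_day = 100, model = "fdm"), "non-empty")
})

test_that("prediction grids honour model limits", {
  p <- reference_fdm()
  expect_equal(predict_curve(p, 0)$value, p$A)
  tt <- tdm_params(Q1 = 300, k1 = 0.01, Q2 = 80, k2 = 5e-4)
  expect_equal(predict_curve(tt, 0)$value, 380)
  expect_error(predict_curve(p, c(-1, 10)), "non-negative")
  # long TDM horizon is dominated by the slow component
  far <- predict_curve(tt, 20000)$value
  expect_equal(far, 80 * exp(-5e-4 * 20000), tolerance = 1e-6)
  # decay-free FDM long-horizon log-log slope approaches -alpha
  p0 <- fdm_params(A = 1256, alpha = 0.62, theta = 5 / 693^0.62, lambda_d = 0)
  grid <- 10^seq(3, 5, length.out = 15)
  cv <- predict_curve(p0, grid)
  sl <- unname(coef(lm(log(value) ~ log(day), data = cv))[2])
  expect_lt(abs(sl + 0.62), 0.03)
})

test_that("model comparison reports one epsilon2 per model on the same series", {
  s <- generate_series(synthetic_spec(noise_sd_rel = 0.1, seed = 3))
  cmp <- compare_models(s, c("fdm", "tdm", "sdm"))
  expect_equal(nrow(cmp), 3)
  expect_equal(cmp$model, c("fdm", "tdm", "sdm"))
  expect_true(all(cmp$epsilon2 >= 0))
  # SDM is nested in TDM, so it can never fit better
  expect_gte(cmp$epsilon2[cmp$model == "sdm"],
             cmp$epsilon2[cmp$model == "tdm"] - 1e-10)
})

test_that("water-fish correlation handles exact, inverted and noisy coupling", {
  w <- data.frame(day = seq(100, 1000, by = 100),
                  value = 100 * exp(-(1:10) / 4))
  f2 <- data.frame(day = w$day, value = 2 * w$value)
  expect_equal(correlate_media(w, f2)$r, 1, tolerance = 1e-12)
  finv <- data.frame(day = w$day, value = max(w$value) + 1 - w$value)
  expect_equal(correlate_media(w, finv)$r, -1, tolerance = 1e-12)
  # noisy proportional pairs against the direct Pearson formula
  wn <- generate_series(synthetic_spec(noise_sd_rel = 0.1, seed = 8, n = 10))
  fn <- generate_paired_fish(wn, proportionality = 0.3, noise_sd_rel = 0.2,
                             seed = 9)
  res <- correlate_media(wn, fn)
  expect_equal(res$r, pearson_direct(wn$value, fn$value), tolerance = 1e-12)
  # pairing window: offset days beyond the window leave too few pairs
  foff <- data.frame(day = w$day + 50, value = w$value)
  expect_error(correlate_media(w, foff, pairing_window = 30), "Fewer than 3")
})

test_that("tidy and glance expose the canonical fit summaries", {
  s <- generate_series(synthetic_spec(noise_sd_rel = 0.05, seed = 2))
  fit <- fit_model(s, "fdm")
  td <- tidy(fit)
  expect_true(all(c("A", "alpha", "theta", "xi", "tau") %in% td$term))
  # reporting convention: xi = theta * tau^alpha at the fixed tau
  xi <- td$estimate[td$term == "xi"]
  th <- td$estimate[td$term == "theta"]
  a <- td$estimate[td$term == "alpha"]
  tau <- td$estimate[td$term == "tau"]
  expect_equal(xi, th * tau^a)
  gl <- glance(fit)
  expect_equal(gl$epsilon2, fit$epsilon2)
  expect_true(is.logical(gl$converged))
})
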