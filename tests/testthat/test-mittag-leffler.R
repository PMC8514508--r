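test_that("E_alpha(0) = 1 in every branch", {
  for (a in c(0.3, 0.5, 0.62, 0.76, 0.9)) {
    expect_identical(ml_series(a, 0), 1)
    expect_identical(ml_integral_neg(a, 0), 1)
    expect_identical(ml_neg(a, 0), 1)
  }
  expect_identical(ml_neg(1, 0), 1)
  expect_identical(ml_half_closed_form(0), 1)
})

test_that("both branches reproduce high-precision reference values", {
  for (i in seq_len(nrow(ml_oracle))) {
    a <- ml_oracle$alpha[i]; y <- ml_oracle$y[i]; v <- ml_oracle$value[i]
    expect_equal(ml_integral_neg(a, y), v, tolerance = 1e-10)
    if (y <= 2) {  # series within its numerically stable domain
      expect_equal(ml_series(a, -y), v, tolerance = 1e-10)
    }
    expect_equal(ml_neg(a, y), v, tolerance = 1e-10)
  }
})

test_that("order one is exactly the exponential", {
  y <- c(0, 0.5, 2, 10, 50)
  expect_identical(ml_neg(1, y), exp(-y))
  # series at alpha = 1 is the Taylor series of exp
  expect_equal(ml_series(1, -2), exp(-2), tolerance = 1e-14)
})

test_that("order one half matches the scaled-erfc closed form", {
  y <- seq(0, 25, by = 0.25)
  expect_equal(ml_integral_neg(0.5, y), ml_half_closed_form(y),
               tolerance = 1e-8)
  # large argument: erfc(z) ~ exp(-z^2)/(sqrt(pi) z), so erfcx(10) ~ 1/(sqrt(pi)*10)
  expect_equal(ml_half_closed_form(10), 1 / (sqrt(pi) * 10), tolerance = 0.01)
})

test_that("series and integral branches agree where the series is stable", {
  grid <- expand.grid(alpha = c(0.3, 0.5, 0.62, 0.76, 0.9),
                      y = c(0.1, 0.5, 1, 2))
  rel <- mapply(function(a, y) {
    abs(ml_series(a, -y) - ml_integral_neg(a, y)) / ml_integral_neg(a, y)
  }, grid$alpha, grid$y)
  expect_lt(max(rel), 1e-6)
})

test_that("series signals its documented instability at large argument", {
  # alpha = 0.3, z = -5: terms peak near k ~ 712 at ~1e91; no double-precision
  # summation survives the cancellation
  expect_error(ml_series(0.3, -5), "diverged|ill-conditioned")
  expect_error(ml_series(0.5, -40, ml_settings(series_kmax = 50)),
               "diverged|ill-conditioned")
})

test_that("E_alpha(-y) is strictly decreasing and confined to (0, 1]", {
  y <- c(0, 10^seq(-2, 4, by = 0.5))
  for (a in c(0.3, 0.62, 0.9)) {
    v <- ml_neg(a, y)
    expect_true(all(diff(v) < 0))
    expect_true(all(v > 0 & v <= 1))
  }
})

test_that("dispatcher is continuous across the series/integral switch", {
  s <- ml_settings()
  bound <- 10 * max(s$series_tol, s$quad_rel_tol)
  for (a in c(0.3, 0.62, 0.9)) {
    lo <- ml_neg(a, s$dispatch_threshold * (1 - 1e-10), s)
    hi <- ml_neg(a, s$dispatch_threshold * (1 + 1e-10), s)
    expect_lt(abs(lo - hi) / lo, bound)
  }
})

test_that("power-law tail has the 1/Gamma(1-alpha) coefficient and 1/y scaling", {
  expect_equal(ml_tail(0.5, 1e4), 1 / (sqrt(pi) * 1e4), tolerance = 1e-12)
  for (a in c(0.5, 0.62, 0.76)) {
    expect_equal(ml_integral_neg(a, 1e4) / ml_tail(a, 1e4), 1, tolerance = 0.01)
  }
  expect_equal(ml_tail(0.76, 2e3) / ml_tail(0.76, 1e3), 0.5, tolerance = 1e-12)
})

test_that("log-log decay slope in y approaches -1 far in the tail", {
  y <- 10^seq(3, 5, length.out = 21)
  for (a in c(0.5, 0.76)) {
    sl <- unname(coef(lm(log(ml_integral_neg(a, y)) ~ log(y)))[2])
    expect_lt(abs(sl + 1), 0.02)
  }
})

test_that("domain contracts are enforced", {
  expect_error(ml_neg(1.2, 1), "alpha")
  expect_error(ml_neg(0, 1), "alpha")
  expect_error(ml_neg(0.6, -1), "non-negative")
  expect_error(ml_integral_neg(1, 1), "alpha")
  expect_error(ml_tail(1, 10), "alpha")
  expect_error(ml_half_closed_form(-1), "non-negative")
  expect_error(ml_settings(series_tol = -1))
  expect_error(ml_settings(series_kmax = 1))
})
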