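test_that("FDM curve equals its defining factors", {
  p <- reference_fdm()
  expect_equal(c_fdm(0, p), 1256)
  # at t = tau the Mittag-Leffler argument is exactly xi = 5
  e5 <- ml_oracle$value[ml_oracle$alpha == 0.62 & ml_oracle$y == 5]
  expect_equal(c_fdm(693, p), 1256 * e5 * exp(-693 * p$lambda_d),
               tolerance = 1e-9)
  t <- seq(0, 5000, by = 250)
  expect_true(all(diff(c_fdm(t, p)) < 0))
})

test_that("FDM output is gauge-invariant in (xi, tau) at fixed theta", {
  p <- reference_fdm()
  t <- c(1, 234, 693, 1981, 10000)
  base <- c_fdm(t, p)
  for (cc in c(0.1, 2, 10)) {
    q <- fdm_params(A = p$A, alpha = p$alpha, xi = cc * p$xi,
                    tau = cc^(1 / p$alpha) * p$tau, lambda_d = p$lambda_d)
    expect_equal(q$theta, p$theta, tolerance = 1e-13)
    expect_equal(c_fdm(t, q), base, tolerance = 1e-12)
  }
})

test_that("FDM near alpha = 1 collapses to exponential decay", {
  k <- 0.002
  p <- fdm_params(A = 500, alpha = 0.999, xi = k * 800, tau = 800,
                  lambda_d = 0)
  t <- c(50, 200, 800)
  expect_equal(c_fdm(t, p), 500 * exp(-k * t), tolerance = 0.01)
})

test_that("TDM evaluates the two-exponential sum and its special cases", {
  p <- tdm_params(Q1 = 300, k1 = 0.01, Q2 = 80, k2 = 5e-4)
  expect_equal(c_tdm(0, p), 380)
  expect_equal(c_tdm(100, p), 300 * exp(-1) + 80 * exp(-0.05),
               tolerance = 1e-15)
  # identical to the sum of two order-1 Mittag-Leffler relaxations
  t <- c(0, 100, 2000, 10000)
  expect_identical(c_tdm(t, p),
                   300 * ml_neg(1, 0.01 * t) + 80 * ml_neg(1, 5e-4 * t))
  sdm <- tdm_params(Q1 = 300, k1 = 0.01)
  expect_equal(c_tdm(t, sdm), 300 * exp(-0.01 * t))
  # canonical ordering puts the fast component first
  swapped <- tdm_params(Q1 = 80, k1 = 5e-4, Q2 = 300, k2 = 0.01)
  expect_equal(swapped$k1, 0.01)
  expect_equal(swapped$Q1, 300)
})

test_that("Bulgakov full form equals the order-1/2 Mittag-Leffler form", {
  p <- bulgakov_params(sigma_d = 2e4, h_w = 10, K_d = 60, D_E = 2.5e-5)
  t <- 10^seq(0, 4, length.out = 41)
  z <- p$K_d * sqrt(p$D_E) / p$h_w * sqrt(t)
  ml_form <- p$sigma_d / p$h_w * ml_neg(0.5, z) * exp(-p$lambda_d * t)
  expect_equal(c_bulgakov_full(t, p), ml_form, tolerance = 1e-10)
  expect_equal(c_bulgakov_full(0, p), p$sigma_d / p$h_w)
})

test_that("approximate Bulgakov form matches the full one once z > 20", {
  p <- bulgakov_params(sigma_d = 2e4, h_w = 1, K_d = 600, D_E = 1e-4,
                       lambda_d = 0)
  # A_B from erfc(z) ~ exp(-z^2)/(sqrt(pi) z)
  A_B <- p$sigma_d / (sqrt(pi) * p$K_d * sqrt(p$D_E))
  t <- 10^seq(1.1, 4, length.out = 20)
  z <- p$K_d * sqrt(p$D_E) / p$h_w * sqrt(t)
  expect_true(all(z > 20))
  expect_equal(c_bulgakov_approx(t, A_B, 0), c_bulgakov_full(t, p),
               tolerance = 0.01)
  # t^{-1/2} scaling: quadrupling time halves the level
  expect_equal(c_bulgakov_approx(4, 100, 0), 50)
  expect_equal(c_bulgakov_approx(16, 100, 0), 25)
  expect_error(c_bulgakov_approx(0, 100, 0), "positive")
})

test_that("decay constant arithmetic round-trips", {
  expect_equal(decay_constant(30.08 * 365.25), 6.3089e-5, tolerance = 1e-4)
  expect_equal(decay_constant(log(2)), 1)
  half <- 1234.5
  expect_equal(decay_constant(half) * half, log(2))
  expect_error(decay_constant(0), "positive")
})

test_that("inventory-based initial concentration is areal inventory spread over volume", {
  expect_equal(initial_concentration_estimate(2e4, 1e6, 1e7), 2000)
  base <- initial_concentration_estimate(100, 10, 1000)
  expect_equal(initial_concentration_estimate(300, 10, 1000), 3 * base)
  expect_equal(initial_concentration_estimate(100, 30, 1000), 3 * base)
  expect_error(initial_concentration_estimate(0, 1, 1), "positive")
})

test_that("diffusion scales combine as K_alpha = sigma^2/tau^alpha and xi = mu^2 sigma^2", {
  expect_equal(diffusion_scales(1, 2, 1, 0.62)$K_alpha, 1)
  expect_equal(diffusion_scales(2, 3, 693, 0.62)$xi, 18)
  # theta invariant under (xi, tau) -> (c xi, c^(1/alpha) tau)
  a <- 0.62
  d1 <- diffusion_scales(2, 3, 693, a)
  d2 <- diffusion_scales(2 * 10^(1), 3, 693 * 10^(1 / a), a)
  expect_equal(d2$theta, d1$theta, tolerance = 1e-12)
})

test_that("long-time FDM decay follows the t^-alpha power law", {
  for (a in c(0.5, 0.76)) {
    p <- fdm_params(A = 1, alpha = a, xi = 1, tau = 1, lambda_d = 0)
    t <- 10^seq(3, 5, length.out = 15)
    sl <- unname(coef(lm(log(c_fdm(t, p)) ~ log(t)))[2])
    expect_lt(abs(sl + a), 0.03)
  }
})

test_that("parameter constructors reject invalid physics", {
  expect_error(fdm_params(A = -1, alpha = 0.6, theta = 1), "positive")
  expect_error(fdm_params(A = 1, alpha = 1.0, theta = 1), "strictly")
  expect_error(fdm_params(A = 1, alpha = 0.6), "theta")
  expect_error(tdm_params(Q1 = -1, k1 = 0.1), "non-negative")
  expect_error(bulgakov_params(sigma_d = 0, h_w = 1, K_d = 1, D_E = 1),
               "positive")
  expect_error(c_fdm(-5, reference_fdm()), "non-negative")
})
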