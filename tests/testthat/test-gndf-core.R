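test_that("kernel peaks at the localization and decays symmetrically", {
  for (beta in c(1, 2, 7.5, 200)) {
    expect_identical(gndf_kernel(3.2, mu = 3.2, sigma = 0.4, beta = beta), 1)
    expect_equal(gndf_kernel(1, 0, 1, beta), exp(-1))
    d <- seq(0.1, 4, by = 0.37)
    expect_equal(gndf_kernel(2 + d, 2, 0.7, beta),
                 gndf_kernel(2 - d, 2, 0.7, beta))
    k <- gndf_kernel(d, 0, 0.7, beta)
    # non-increasing overall; strictly decreasing where the floating
    # point values have not saturated at 1 or underflowed to 0
    expect_true(all(diff(k) <= 0))
    live <- utils::head(k, -1) < 1 & utils::tail(k, -1) > 0
    expect_true(all(diff(k)[live] < 0))
  }
  expect_equal(gndf_kernel(2, 0, 1, 2), exp(-4))
  expect_error(gndf_kernel(Inf), "finite")
  # far tails underflow to exactly 0, never NaN
  expect_identical(gndf_kernel(1e6, 0, 1e-3, 50), 0)
})

test_that("density normalizes to one and matches known special cases", {
  # beta = 2, sigma = 1 is a Gaussian with variance 1/2
  expect_equal(dgndf(0, 0, 1, 2), 1 / sqrt(pi))
  x <- seq(-3, 3, by = 0.1)
  expect_equal(dgndf(x, 0, 1, 2), dnorm(x, sd = sqrt(0.5)))
  # beta = 1 is Laplace: peak 1 / (2 sigma)
  expect_equal(dgndf(0, 0, 2, 1), 0.25)
  for (beta in c(1, 2, 3, 8, 32, 200)) {
    for (sigma in c(0.5, 1, 5)) {
      total <- integrate_oracle(dgndf, -50 * sigma, 50 * sigma,
                                mu = 0, sigma = sigma, beta = beta)
      expect_equal(total, 1, tolerance = 1e-8)
    }
  }
})

test_that("cdf matches numerical integration of the density", {
  for (beta in c(1, 2, 3, 8, 32, 200)) {
    # grid density scales with beta: the profile edge sharpens as
    # sigma / beta, and the trapezoid rule must resolve it
    n <- min(5e5, max(4001, round(2000 * beta)))
    x <- seq(-6 * 1.3, 6 * 1.3, length.out = n)
    num <- cumtrapz(x, dgndf(x, 0, 1.3, beta)) + pgndf(x[1], 0, 1.3, beta)
    expect_lt(max(abs(num - pgndf(x, 0, 1.3, beta))), 1e-6)
  }
})

test_that("cdf has the median and reflection symmetries", {
  for (beta in c(1, 2.5, 40)) {
    expect_identical(pgndf(1.5, mu = 1.5, sigma = 2, beta = beta), 0.5)
    d <- c(0.01, 0.3, 1, 2.7)
    expect_equal(pgndf(-d, 0, 1, beta) + pgndf(d, 0, 1, beta),
                 rep(1, length(d)))
  }
  # Laplace closed form
  expect_equal(pgndf(1, 0, 1, 1), 1 - exp(-1) / 2)
})

test_that("quantile function inverts the cdf to high precision", {
  p <- c(1e-4, 0.01, 0.3, 0.5, 0.7, 0.99, 0.9999)
  for (beta in c(1, 2, 3, 8, 32, 200)) {
    expect_equal(pgndf(qgndf(p, 0.3, 1.7, beta), 0.3, 1.7, beta), p,
                 tolerance = 1e-10)
    # keep x where the cdf is representable away from 0 and 1 (the
    # tails saturate in double precision for steep shapes)
    x <- if (beta >= 32) c(-1.01, -0.4, 0, 0.9, 1.01)
         else if (beta >= 3) c(-1.2, -0.4, 0, 0.9, 1.2)
         else c(-2.1, -0.4, 0, 0.9, 3)
    expect_equal(qgndf(pgndf(x, 0, 1, beta), 0, 1, beta), x,
                 tolerance = 1e-10)
  }
  expect_equal(qgndf(0.5, mu = 4), 4)
  expect_equal(qgndf(1 - exp(-1) / 2, 0, 1, 1), 1, tolerance = 1e-6)
  expect_error(qgndf(0), "\\(0, 1\\)")
  expect_error(qgndf(1), "\\(0, 1\\)")
})

test_that("fwhm equals the numerically solved half-maximum crossing", {
  for (beta in c(1, 2, 3, 8, 32, 200)) {
    for (sigma in c(0.5, 1, 5)) {
      crossing <- uniroot(function(x) gndf_kernel(x, 0, sigma, beta) - 0.5,
                          c(1e-12, 10 * sigma), tol = 1e-14)$root
      expect_equal(gndf_fwhm(sigma, beta), 2 * crossing,
                   tolerance = 1e-9)
    }
  }
  expect_equal(gndf_fwhm(1, 2), 2 * sqrt(log(2)))
  expect_equal(gndf_fwhm(1, 1000), 2 * log(2)^0.001)
  expect_equal(gndf_fwhm(2 * 1.3, 7), 2 * gndf_fwhm(1.3, 7))
})

test_that("event model recovers the baseline and peak currents", {
  p <- gndf_params(100, -30, mu = 0.01, sigma = 1e-4, beta = 2)
  expect_equal(event_model(0.01, p), 70)
  expect_equal(event_model(0.01 + 20e-4, p), 100, tolerance = 1e-6)
  # beta = 2 profile is exactly Gaussian-shaped
  x <- seq(-5e-4, 5e-4, length.out = 101) + 0.01
  expect_equal(event_model(x, p),
               100 - 30 * exp(-((x - 0.01) / 1e-4)^2))
})

test_that("large beta approaches a rectangular pulse of half-width sigma", {
  k_in <- gndf_kernel(seq(-0.97, 0.97, by = 0.01), 0, 1, 1000)
  k_out <- gndf_kernel(c(seq(-3, -1.03, by = 0.01),
                         seq(1.03, 3, by = 0.01)), 0, 1, 1000)
  expect_true(all(k_in > 0.99))
  expect_true(all(k_out < 0.01))
})

test_that("parameter container enforces its invariants", {
  expect_error(gndf_params(100, -30, 0, -1, 2), "sigma")
  expect_error(gndf_params(100, -30, 0, 1, 0.5), "beta")
  expect_error(gndf_params(100, -30, 0, 1, 600), "beta_max")
  expect_silent(gndf_params(100, -30, 0, 1, 600, beta_max = 1000))
  expect_warning(gndf_params(100, -130, 0, 1, 2), "non-physical")
  expect_warning(gndf_params(-100, 150, 0, 1, 2), "non-physical")
  expect_silent(gndf_params(-100, 30, 0, 1, 2))
})
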