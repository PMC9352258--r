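test_that("back-mapped dwell time conserves the event area", {
  # closed-form checks
  expect_equal(dwell_time(1, 2), sqrt(pi))
  expect_equal(dwell_time(1, 1000), 2, tolerance = 2e-3)
  expect_equal(dwell_time(3, 2), 3 * sqrt(pi))
  # area equivalence: dt * |di_b| equals the integrated blockade area,
  # for many random parameter draws
  set.seed(42)
  for (i in 1:200) {
    sigma <- runif(1, 0.1, 10)
    beta <- runif(1, 1, 60)
    di_b <- runif(1, -50, -1)
    area <- integrate_oracle(function(x) -di_b * gndf_kernel(x, 0, sigma, beta),
                             -60 * sigma, 60 * sigma)
    expect_equal(dwell_time(sigma, beta) * abs(di_b), area,
                 tolerance = 1e-6)
  }
})

test_that("dwell time grows with sigma; sampling frequency shrinks", {
  sig <- seq(0.5, 5, by = 0.5)
  for (beta in c(1.5, 3, 12)) {
    expect_true(all(diff(dwell_time(sig, beta)) > 0))
    fs_c <- vapply(sig, function(s)
      event_sampling_frequency(s, beta, mode = "cdf"), numeric(1))
    fs_a <- vapply(sig, function(s)
      event_sampling_frequency(s, beta, mode = "amplitude"), numeric(1))
    expect_true(all(diff(fs_c) < 0))
    expect_true(all(diff(fs_a) < 0))
  }
})

test_that("fwhm approximates the back-mapped dwell time for steep shapes", {
  # regression curve of the relative discrepancy: ~0.9% at beta = 3
  # (fwhm below the dwell), a sign change before beta = 4, a maximum of
  # ~1.45% near beta = 7, then decay like 0.42 / beta
  betas <- seq(3, 200, by = 0.5)
  rel <- abs(gndf_fwhm(1, betas) - dwell_time(1, betas)) / dwell_time(1, betas)
  expect_equal(rel[betas == 3], 0.00896, tolerance = 1e-2)
  expect_equal(rel[betas == 4], 0.00660, tolerance = 1e-2)
  expect_lt(max(rel), 0.015)
  expect_lt(rel[betas == 200], 0.0022)
  expect_lt(gndf_fwhm(1, 3), dwell_time(1, 3))
  expect_gt(gndf_fwhm(1, 4), dwell_time(1, 4))
  # the approximation degrades toward the Gaussian limit (~6% at beta 2)
  expect_gt(abs(gndf_fwhm(1, 2) - dwell_time(1, 2)) / dwell_time(1, 2), 0.05)
  # and decays monotonically beyond its midrange maximum
  expect_true(all(diff(rel[betas >= 12]) < 0))
})

test_that("excluded and residual currents are exact complements", {
  ec <- excluded_current(100, -30)
  expect_equal(ec$i_ex, 0.3)
  expect_equal(ec$i_res, 0.7)
  expect_identical(excluded_current(100, 0)$i_ex, 0)
  set.seed(1)
  for (i in 1:20) {
    ec <- excluded_current(runif(1, 10, 300), runif(1, -100, 0))
    expect_identical(ec$i_ex + ec$i_res, 1)
  }
  expect_error(excluded_current(0, -30), "nonzero")
})

test_that("RC correction inverts the forward charging model", {
  # identity when charging is disabled
  expect_identical(rc_correct(0.8, 1e-3, 0), 0.8)
  # fully charged: observation is already asymptotic
  expect_equal(rc_correct(0.8, 10 * 2e-6, 2e-6), 0.8, tolerance = 1e-4)
  # derived closed-form value: observed 0.8 one time constant in
  expect_equal(rc_correct(0.8, 2e-6, 2e-6),
               (0.8 - exp(-1)) / (1 - exp(-1)), tolerance = 1e-10)
  expect_equal(rc_correct(0.8, 2e-6, 2e-6), 0.6836004, tolerance = 1e-5)
  # round trip against the forward model, many draws
  set.seed(7)
  for (i in 1:50) {
    i_res <- runif(1)
    tau <- runif(1, 1e-7, 1e-5)
    t <- runif(1, 1e-7, 1e-4)
    expect_equal(rc_correct(rc_charge(i_res, t, tau), t, tau), i_res,
                 tolerance = 1e-10)
  }
  expect_lte(rc_correct(0.5, 1e-6, 1e-6), 0.5)
  expect_error(rc_correct(0.5, 0, 1e-6), "t <= 0")
  expect_error(rc_correct(1.2, 1e-6, 1e-6), "\\[0, 1\\]")
})

test_that("localization validity is inclusive at the window edges", {
  expect_true(validate_localization(0.5, 0, 1))
  expect_true(validate_localization(0, 0, 1))
  expect_true(validate_localization(1, 0, 1))
  expect_false(validate_localization(-1e-9, 0, 1))
  expect_false(validate_localization(1 + 1e-9, 0, 1))
  expect_error(validate_localization(0.5, 1, 0), "empty")
})

test_that("overlap validation separates resolved from dilated shapes", {
  # near-rectangular, dwell equal to the full width: trivially contained
  ov <- validate_overlap(1, 200, dwell = 2)
  expect_true(ov$valid)
  expect_lt(ov$p_star, 0.01)
  # Gaussian shape with a dwell far narrower than the fitted spread:
  # containment fails at every acceptable probability
  ov <- validate_overlap(1, 2, dwell = 0.01)
  expect_false(ov$valid)
  expect_true(is.na(ov$p_star))
  # p* agrees with a brute-force grid scan of the containment condition
  grid_pstar <- function(sigma, beta, dwell) {
    p <- seq(1e-6, 0.4999, by = 1e-6)
    ok <- -qgndf(p, 0, sigma, beta) <= dwell / 2
    if (!any(ok)) NA_real_ else p[which(ok)[1]]
  }
  for (beta in c(2, 3, 6, 20)) {
    dt <- dwell_time(1.4, beta)
    ov <- validate_overlap(1.4, beta, dt, p_max = 0.5)
    expect_equal(ov$p_star, grid_pstar(1.4, beta, dt), tolerance = 2e-2)
  }
  # natural fits: dilated Gaussian-limit shapes fail at the default
  # threshold, plateau shapes pass
  expect_false(validate_overlap(1, 2, dwell_time(1, 2))$valid)
  expect_true(validate_overlap(1, 8, dwell_time(1, 8))$valid)
})

test_that("per-event sampling frequency matches a numeric CDF inversion", {
  # derived: Gaussian case, p = 0.001
  expect_equal(event_sampling_frequency(1, 2, 0.001), 282.0945,
               tolerance = 1e-4)
  # oracle: invert the CDF numerically instead of via qgndf
  for (beta in c(1.3, 2, 5, 30)) {
    qs <- vapply(c(0.499, 0.501), function(p)
      uniroot(function(x) pgndf(x, 0, 1, beta) - p, c(-5, 5),
              tol = 1e-13)$root, numeric(1))
    expect_equal(event_sampling_frequency(1, beta, 0.001, mode = "cdf"),
                 1 / diff(qs), tolerance = 1e-6)
  }
  # scale equivariance
  for (s in c(0.2, 3, 40)) {
    expect_equal(event_sampling_frequency(s, 4, 0.001),
                 event_sampling_frequency(1, 4, 0.001) / s)
    expect_equal(event_sampling_frequency(s, 4, 0.001, mode = "amplitude"),
                 event_sampling_frequency(1, 4, 0.001, mode = "amplitude") / s)
  }
  # undefined at the rectangular bound
  expect_true(is.na(event_sampling_frequency(1, gndf_beta_max(), 0.001)))
  expect_error(event_sampling_frequency(1, 2, 0.7), "\\(0, 0.5\\)")
})

test_that("the amplitude reading measures the profile edge rise time", {
  # time between kernel = p and kernel = 1 - p, solved numerically
  p <- 0.001
  for (beta in c(2, 5, 20)) {
    t_lo <- uniroot(function(x) gndf_kernel(x, 0, 1, beta) - (1 - p),
                    c(0, 3), tol = 1e-13)$root
    t_hi <- uniroot(function(x) gndf_kernel(x, 0, 1, beta) - p,
                    c(0, 6), tol = 1e-13)$root
    expect_equal(event_sampling_frequency(1, beta, p, mode = "amplitude"),
                 1 / (t_hi - t_lo), tolerance = 1e-6)
  }
})

test_that("event_features assembles a consistent one-row summary", {
  params <- gndf_params(100, -30, mu = 0.005, sigma = 2e-4, beta = 6)
  f <- event_features(params, t_start = 0.004, t_end = 0.006)
  expect_equal(nrow(f), 1L)
  expect_equal(f$dwell_time, dwell_time(2e-4, 6))
  expect_identical(f$i_ex + f$i_res, 1)
  expect_true(f$loc_valid)
  expect_true(f$overlap_valid)
  expect_equal(f$fs_event, f$fs_event_cdf)
  # amplitude reading selectable
  f2 <- event_features(params, fs_mode = "amplitude")
  expect_equal(f2$fs_event, f2$fs_event_amp)
  expect_true(is.na(f2$loc_valid))
  # RC correction raises i_ex relative to the uncorrected value
  f3 <- event_features(params, rc_tau = 5e-5)
  expect_gt(f3$i_ex, f$i_ex)
})
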