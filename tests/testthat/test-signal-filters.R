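test_that("gaussian filter has unit DC gain and a -3 dB point at the cutoff", {
  fs <- 1e6
  tr <- nanopore_trace(rep(42, 5000), fs)
  expect_equal(gaussian_lowpass(tr, 5e4)$current, rep(42, 5000),
               tolerance = 1e-12)
  # sine at exactly the cutoff emerges at 1/sqrt(2) amplitude
  fc <- 2e4
  t <- (0:49999) / fs
  x <- sin(2 * pi * fc * t)
  y <- gaussian_lowpass(x, fc, fs = fs)
  mid <- 10000:40000
  amp <- max(abs(y[mid]))
  expect_equal(amp, 1 / sqrt(2), tolerance = 0.01)
  expect_error(gaussian_lowpass(tr, fs / 2), "Nyquist")
})

test_that("gaussian filter attenuates white noise by the analytic bandwidth", {
  fs <- 1e6
  fc <- fs / 20
  set.seed(11)
  x <- rnorm(2e5)
  y <- gaussian_lowpass(x, fc, fs = fs)
  # oracle: output variance = sum of squared kernel weights, computed
  # independently from the impulse response (impulse mid-vector, away
  # from the reflected edges)
  imp <- rep(0, 8192); imp[4096] <- 1
  k <- gaussian_lowpass(imp, fc, fs = fs)
  expect_equal(stats::sd(y), sqrt(sum(k^2)), tolerance = 0.05)
  # and the analytic continuous-time noise bandwidth integral
  sd_t <- sqrt(log(2)) / (2 * pi * fc)
  expect_equal(sum(k^2), 1 / (fs * 2 * sqrt(pi) * sd_t), tolerance = 0.01)
})

test_that("bessel filter matches an independent ODE integration", {
  skip_if_not_installed("deSolve")
  fs <- 1e7
  fc <- 5e4
  n <- 4000
  u <- rep(0, n); u[501:1500] <- 1
  y <- bessel4_lowpass(u, fc, fs = fs)
  # oracle: integrate the 4th-order state-space system directly
  den <- c(1, 10, 45, 105, 105)
  p0 <- polyroot(rev(den))
  h2 <- function(w) {
    s <- 1i * w
    Mod(105 / ((s - p0[1]) * (s - p0[2]) * (s - p0[3]) * (s - p0[4])))^2
  }
  w3 <- uniroot(function(w) h2(w) - 0.5, c(0.5, 5), tol = 1e-12)$root
  sc <- 2 * pi * fc / w3
  A <- rbind(c(0, 1, 0, 0), c(0, 0, 1, 0), c(0, 0, 0, 1),
             -c(105, 105, 45, 10) * c(sc^4, sc^3, sc^2, sc))
  ufun <- stats::approxfun(seq(0, by = 1 / fs, length.out = n), u,
                           method = "constant", rule = 2)
  sol <- deSolve::ode(rep(0, 4), seq(0, (n - 1) / fs, by = 1 / fs),
                      function(t, x, p) list(A %*% x + c(0, 0, 0, 1) * ufun(t)),
                      NULL, rtol = 1e-10, atol = 1e-12)
  oracle <- as.numeric(sol[, 2]) * 105 * sc^4
  expect_lt(max(abs(y - oracle)), 1e-5)
})

test_that("bessel step response settles to one and preserves causality", {
  fs <- 1e7
  u <- c(rep(0, 100), rep(1, 30000))
  y <- bessel4_lowpass(u, 5e4, fs = fs)
  expect_equal(y[length(y)], 1, tolerance = 1e-4)
  # causal: nothing happens before the step beyond numerical dust
  expect_lt(max(abs(y[1:100])), 1e-10)
  expect_error(bessel4_lowpass(u, fs / 10, fs = fs), "undersampled")
})

test_that("short pulses dilate under the bessel filter with conserved area", {
  # 10 us unit pulse at 100 MHz through a 50 kHz 4-pole Bessel
  fs <- 1e8
  n <- 20000
  u <- rep(0, n); u[1001:2000] <- 1
  y <- bessel4_lowpass(u, 5e4, fs = fs)
  expect_equal(sum(y) / fs, sum(u) / fs, tolerance = 0.01)  # area
  expect_lt(max(y), 1)                                      # reduced peak
  half <- range(which(y >= max(y) / 2))
  expect_gt(diff(half) / fs, 10e-6)                         # wider half-max
})

test_that("a 20 us half-height and a 10 us full-height pulse agree at 10 kHz", {
  fs <- 1e8
  n <- 60000
  u10 <- rep(0, n); u10[10001:11000] <- 1
  u20 <- rep(0, n); u20[10001:12000] <- 0.5
  y10 <- bessel4_lowpass(u10, 1e4, fs = fs)
  y20 <- bessel4_lowpass(u20, 1e4, fs = fs)
  # time-align (the two responses have different group delays through
  # their different input durations), then compare pointwise on the
  # amplitude scale of the ideal pulse (height 1), the scale on which
  # the two blockades would be judged indistinguishable
  mismatch_at <- function(shift) {
    idx <- seq(1, n - abs(shift))
    max(abs(y10[idx] - y20[idx + shift]))
  }
  mismatch <- min(vapply(0:800, mismatch_at, numeric(1)))
  expect_lt(mismatch, 0.05)
  # the residual difference relative to the filtered peak itself
  expect_lt(mismatch / max(y10), 0.06)
})

test_that("both filters are linear, time-invariant and area-conserving", {
  fs <- 1e6
  set.seed(3)
  x <- rnorm(5000); z <- rnorm(5000)
  for (kind in c("gaussian", "bessel4")) {
    f <- function(v) if (kind == "gaussian") gaussian_lowpass(v, 2e4, fs = fs)
                     else bessel4_lowpass(v, 2e4, fs = fs)
    expect_equal(f(2 * x + 3 * z), 2 * f(x) + 3 * f(z), tolerance = 1e-10)
    # shifted pulse in, shifted response out
    pulse <- rep(0, 5000); pulse[1000:1100] <- 1
    shifted <- rep(0, 5000); shifted[1500:1600] <- 1
    expect_equal(f(shifted)[1600:4000], f(pulse)[1100:3500],
                 tolerance = 1e-10)
    # pulse area conserved
    expect_equal(sum(f(pulse)) / fs, 101 / fs, tolerance = 0.01)
  }
})

test_that("pulse dilation runs in the expected direction when cutoff * duration < 1", {
  fs <- 1e7
  n <- 50000
  width_s <- 20e-6
  u <- rep(0, n); u[10001:(10000 + width_s * fs)] <- 1
  for (kind in c("gaussian", "bessel4")) {
    fc <- 2e4  # fc * width = 0.4 < 1
    y <- if (kind == "gaussian") gaussian_lowpass(u, fc, fs = fs)
         else bessel4_lowpass(u, fc, fs = fs)
    expect_lt(max(y), 1)
    half <- range(which(y >= max(y) / 2))
    expect_gt(diff(half) / fs, width_s)
  }
})

test_that("filter specifications validate and dispatch", {
  expect_error(filter_spec("gaussian", -1), "cutoff")
  expect_error(filter_spec("butterworth", 1e4))
  tr <- nanopore_trace(c(rep(0, 2000), rep(1, 2000)), 1e6)
  spec <- filter_spec("bessel4", 2e4)
  expect_equal(apply_filter(tr, spec)$current,
               bessel4_lowpass(tr, 2e4)$current)
})
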