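#' Low-pass filter specification
#'
#' @param kind `"gaussian"` (zero-phase digital preprocessing filter) or
#'   `"bessel4"` (causal continuous-time 4-pole Bessel, emulating the
#'   patch-clamp acquisition chain).
#' @param cutoff -3 dB frequency, Hz; > 0.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(kind = c("gaussian", "bessel4"), cutoff) {
  kind <- match.arg(kind)
  if (!is.finite(cutoff) || cutoff <= 0)
    stop("cutoff must be > 0", call. = FALSE)
  structure(list(kind = kind, cutoff = cutoff), class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf("%s low-pass, -3 dB at %.6g Hz\n", x$kind, x$cutoff))
  invisible(x)
}

#' Apply a filter specification to a trace
#'
#' @param trace A [nanopore_trace()].
#' @param spec A [filter_spec()].
#' @return A filtered [nanopore_trace()].
#' @export
apply_filter <- function(trace, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  switch(spec$kind,
         gaussian = gaussian_lowpass(trace, spec$cutoff),
         bessel4 = bessel4_lowpass(trace, spec$cutoff))
}

# Gaussian kernel SD in seconds for a -3 dB cutoff: the continuous
# frequency response exp(-2 pi^2 sd_t^2 f^2) equals 1/sqrt(2) at
# f = cutoff when sd_t = sqrt(log(2)) / (2 pi cutoff).
gaussian_sd_t <- function(cutoff) sqrt(log(2)) / (2 * pi * cutoff)

#' Zero-phase Gaussian low-pass filter
#'
#' Convolution with a discrete Gaussian kernel whose SD is chosen so the
#' amplitude response is -3 dB at `cutoff`
#' (`sd_t = sqrt(ln 2) / (2 pi cutoff)` in the time domain). The kernel
#' is normalized to unit sum (DC gain exactly 1), truncated at six SDs,
#' and applied with reflected edges; the result is zero-phase, as suits
#' a preprocessing/display filter.
#'
#' @param trace A [nanopore_trace()] (or a numeric vector if `fs` is
#'   given).
#' @param cutoff -3 dB frequency, Hz; must be below `fs / 2`.
#' @param fs Sampling frequency, Hz; taken from the trace if omitted.
#' @return Filtered trace (same class as the input).
#' @export
gaussian_lowpass <- function(trace, cutoff, fs = NULL) {
  is_trace <- inherits(trace, "nanopore_trace")
  x <- if (is_trace) trace$current else trace
  if (is.null(fs)) {
    if (!is_trace) stop("fs required for a bare numeric vector", call. = FALSE)
    fs <- trace$fs
  }
  if (cutoff >= fs / 2)
    stop("cutoff must be below the Nyquist frequency fs/2", call. = FALSE)
  sd_n <- gaussian_sd_t(cutoff) * fs
  half <- max(1L, ceiling(6 * sd_n))
  k <- stats::dnorm(seq(-half, half), sd = sd_n)
  k <- k / sum(k)
  n <- length(x)
  # reflect edges so the filtered trace has no DC droop at the ends
  if (half > n)
    stop("Gaussian kernel wider than the trace; raise the cutoff or ",
         "supply a longer trace", call. = FALSE)
  pad_l <- rev(x[seq_len(half)])
  pad_r <- rev(x[(n - half + 1):n])
  xp <- c(pad_l, x, pad_r)
  y <- stats::filter(xp, k, method = "convolution", sides = 2)
  y <- as.numeric(y)[(length(pad_l) + 1):(length(pad_l) + n)]
  if (is_trace) nanopore_trace(y, fs, trace$t0) else y
}

# Poles and gain of the -3 dB-normalized 4th-order Bessel low-pass at
# angular cutoff wc (rad/s). The delay-normalized prototype denominator
# is s^4 + 10 s^3 + 45 s^2 + 105 s + 105; its -3 dB point is found
# numerically and the poles rescaled so |H| = 1/sqrt(2) at wc.
bessel4_poles <- function(wc) {
  den <- c(1, 10, 45, 105, 105)
  p0 <- polyroot(rev(den))
  h2 <- function(w) {
    s <- 1i * w
    Mod(105 / ((s - p0[1]) * (s - p0[2]) * (s - p0[3]) * (s - p0[4])))^2
  }
  w3 <- stats::uniroot(function(w) h2(w) - 0.5, c(0.5, 5), tol = 1e-12)$root
  scale <- wc / w3
  list(p = p0 * scale, k = 105 * scale^4)
}

#' Causal 4-pole Bessel low-pass (continuous-time simulation)
#'
#' Simulates the continuous-time 4th-order Bessel transfer function,
#' frequency-normalized so the amplitude response is -3 dB at `cutoff`
#' (the patch-clamp amplifier convention). The input is treated as
#' piecewise constant between samples, for which the zero-order-hold
#' modal discretization (partial fractions over the four poles, each
#' conjugate pair realized as a real second-order recursion) is exact —
#' no bilinear approximation is involved. The filter is causal, so the
#' hardware phase delay is preserved; a unit step settles to 1.
#'
#' The state is started settled at the first sample's value, so a trace
#' that begins on its baseline has no start-up transient.
#'
#' @param trace A [nanopore_trace()] (or numeric vector with `fs`).
#' @param cutoff -3 dB frequency, Hz. The trace must be sampled at
#'   least 20 times faster than the cutoff.
#' @param fs Sampling frequency, Hz; taken from the trace if omitted.
#' @return Filtered trace (same class as the input).
#' @export
bessel4_lowpass <- function(trace, cutoff, fs = NULL) {
  is_trace <- inherits(trace, "nanopore_trace")
  x <- if (is_trace) trace$current else trace
  if (is.null(fs)) {
    if (!is_trace) stop("fs required for a bare numeric vector", call. = FALSE)
    fs <- trace$fs
  }
  if (fs < 20 * cutoff)
    stop("input undersampled: need fs >= 20 * cutoff for the ",
         "continuous-time simulation", call. = FALSE)
  bp <- bessel4_poles(2 * pi * cutoff)
  p <- bp$p
  r <- vapply(1:4, function(i) bp$k / prod(p[i] - p[-i]), complex(1))
  dt <- 1 / fs
  # warm-up samples at x[1] so the filter starts in steady state
  nw <- max(16L, ceiling(10 / (2 * pi * cutoff) * fs))
  u <- c(rep(x[1], nw), x)
  n <- length(u)
  out <- numeric(n)
  done <- rep(FALSE, 4)
  for (i in 1:4) {
    if (done[i]) next
    j <- which(!done & seq_len(4) != i &
                 Mod(p - Conj(p[i])) < 1e-9 * Mod(p[i]))[1]
    if (is.na(j)) stop("expected complex-conjugate pole pairs")
    done[c(i, j)] <- TRUE
    a <- exp(p[i] * dt)
    w <- (a - 1) / p[i]
    g <- r[i]
    # pair contribution s_k = 2 Re(a) s_{k-1} - |a|^2 s_{k-2}
    #                        + 2 Re(g w) u_{k-1} - 2 Re(g w conj(a)) u_{k-2}
    v <- 2 * Re(g * w) * c(0, u[-n]) -
      2 * Re(g * w * Conj(a)) * c(0, 0, u[-c(n - 1, n)])
    s <- stats::filter(v, c(2 * Re(a), -Mod(a)^2), method = "recursive")
    out <- out + as.numeric(s)
  }
  y <- out[(nw + 1):n]
  if (is_trace) nanopore_trace(y, fs, trace$t0) else y
}
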