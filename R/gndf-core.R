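#' Upper bound of the shape-parameter domain
#'
#' The generalized normal shape exponent beta is restricted to
#' `[1, beta_max]`. Below 1 the kernel is cusped at the localization and
#' non-physical for band-limited pulses; above the default of 500 the
#' profile is numerically indistinguishable from a rectangle and
#' quantities that probe the edge steepness (such as the per-event
#' sampling frequency) lose meaning.
#'
#' @return The default upper bound for beta (500).
#' @export
gndf_beta_max <- function() 500

# shape validation for the closed forms; the [1, beta_max] fitting
# domain is enforced by gndf_params()/fit_event(), not here, so limit
# behaviour (beta -> infinity) can be evaluated directly
.check_shape <- function(mu, sigma, beta) {
  if (!all(is.finite(mu)))
    stop("mu must be finite", call. = FALSE)
  if (!all(is.finite(sigma)) || any(sigma <= 0))
    stop("sigma must be finite and > 0", call. = FALSE)
  if (!all(is.finite(beta)) || any(beta < 1))
    stop("beta must be finite and >= 1", call. = FALSE)
  invisible(TRUE)
}

#' Generalized normal kernel
#'
#' The unnormalized profile `exp(-(|x - mu| / sigma)^beta)` shared by the
#' density and the five-parameter blockade model. It equals 1 exactly at
#' `x = mu`, is symmetric about `mu`, and decreases monotonically in
#' `|x - mu|`. At `beta = 2` it is Gaussian; as `beta` grows it
#' approaches a rectangle of half-width `sigma` with ever steeper edges.
#'
#' `(|x - mu|/sigma)^beta` is evaluated as `exp(beta * log(.))`, so for
#' arguments far outside the event the power overflows to `Inf` and the
#' kernel underflows to exactly 0 rather than producing NaN.
#'
#' @param x Time, s. Must be finite.
#' @param mu Localization (time of the extremum), s.
#' @param sigma Scale, s; `sigma > 0`.
#' @param beta Shape exponent, dimensionless; in `[1, beta_max]`.
#' @return Values in `(0, 1]` (0 on underflow in the far tails).
#' @examples
#' gndf_kernel(0)            # 1 at the localization
#' gndf_kernel(1, beta = 2)  # exp(-1)
#' @export
gndf_kernel <- function(x, mu = 0, sigma = 1, beta = 2) {
  if (!all(is.finite(x))) stop("x must be finite", call. = FALSE)
  .check_shape(mu, sigma, beta)
  z <- abs(x - mu) / sigma
  # z^beta in log space; z == 0 handled explicitly (log(0) = -Inf is fine
  # for beta >= 1 but 0 * -Inf would be NaN if beta were vectorized oddly)
  zb <- ifelse(z == 0, 0, exp(beta * log(z)))
  exp(-zb)
}

#' Generalized normal density
#'
#' `dgndf(x) = beta / (2 * sigma * gamma(1/beta)) * exp(-(|x-mu|/sigma)^beta)`.
#' Integrates to one over the real line. With `beta = 2` this is a
#' Gaussian with variance `sigma^2 / 2`; with `beta = 1` a Laplace
#' density with rate `1/sigma`.
#'
#' @inheritParams gndf_kernel
#' @return Density, 1/s.
#' @export
dgndf <- function(x, mu = 0, sigma = 1, beta = 2) {
  .check_shape(mu, sigma, beta)
  beta / (2 * sigma * gamma(1 / beta)) * gndf_kernel(x, mu, sigma, beta)
}

#' Generalized normal cumulative distribution function
#'
#' `pgndf(q) = 1/2 + sign(q - mu)/2 * P(1/beta, (|q-mu|/sigma)^beta)`,
#' where `P` is the regularized lower incomplete gamma function
#' (`stats::pgamma`). Nondecreasing, with `pgndf(mu) = 1/2` and the
#' symmetry `pgndf(mu - d) + pgndf(mu + d) = 1`.
#'
#' @param q Time, s.
#' @inheritParams gndf_kernel
#' @return Probability in `[0, 1]`.
#' @export
pgndf <- function(q, mu = 0, sigma = 1, beta = 2) {
  if (!all(is.finite(q))) stop("q must be finite", call. = FALSE)
  .check_shape(mu, sigma, beta)
  z <- abs(q - mu) / sigma
  lzb <- ifelse(z == 0, -Inf, beta * log(z))
  p <- stats::pgamma(exp(lzb), shape = 1 / beta)
  # when z^beta underflows (steep shapes near the localization) use the
  # small-argument expansion P(1/beta, z^beta) = z / gamma(1 + 1/beta)
  tiny <- lzb < -600
  if (any(tiny))
    p[tiny] <- (z / gamma(1 + 1 / beta))[tiny]
  0.5 + sign(q - mu) / 2 * p
}

#' Generalized normal quantile function
#'
#' Exact inverse of [pgndf()]:
#' `qgndf(p) = mu + sign(p - 1/2) * sigma * qgamma(|2p - 1|, 1/beta)^(1/beta)`.
#'
#' @param p Probability, strictly in `(0, 1)`.
#' @inheritParams gndf_kernel
#' @return Time, s.
#' @export
qgndf <- function(p, mu = 0, sigma = 1, beta = 2) {
  if (!all(is.finite(p)) || any(p <= 0) || any(p >= 1))
    stop("p must lie strictly in (0, 1)", call. = FALSE)
  .check_shape(mu, sigma, beta)
  q <- abs(2 * p - 1)
  g <- stats::qgamma(q, shape = 1 / beta)
  z <- ifelse(g == 0, 0, exp(log(g) / beta))
  # qgamma underflows for small central probabilities at steep shapes;
  # invert the expansion P(1/beta, z^beta) = z / gamma(1 + 1/beta)
  tiny <- g == 0 & q > 0
  if (any(tiny))
    z[tiny] <- (q * gamma(1 + 1 / beta))[tiny]
  mu + sign(p - 0.5) * sigma * z
}

#' Full width at half-maximum of the event profile
#'
#' `fwhm = 2 * sigma * log(2)^(1/beta)`: the width of the region where
#' the kernel is at least 1/2. Tends to `2 * sigma` (the rectangle
#' width) as `beta` grows.
#'
#' @inheritParams gndf_kernel
#' @return Duration, s.
#' @export
gndf_fwhm <- function(sigma = 1, beta = 2) {
  .check_shape(0, sigma, beta)
  2 * sigma * log(2)^(1 / beta)
}

#' Five-parameter blockade parameter set
#'
#' Container for the parameters of the blockade model: the open-pore
#' current `i_open` (pA), the signed current difference `di_b` caused by
#' the blockade (pA, negative for a blockade of a positive open-pore
#' current), the localization `mu` (s), the scale `sigma` (s) and the
#' shape exponent `beta`.
#'
#' For a physical blockade `i_open + di_b` keeps the sign of `i_open`
#' and `|di_b| <= |i_open|`; values outside this produce a warning (an
#' enhancement or an over-deep fit), not an error.
#'
#' @param i_open Open-pore current, pA. Finite.
#' @param di_b Signed current difference relative to `i_open`, pA.
#' @param mu Localization, s.
#' @param sigma Scale, s; `> 0`.
#' @param beta Shape, in `[1, beta_max]`.
#' @param beta_max Upper bound for `beta`.
#' @return An object of class `gndf_params` (a named list).
#' @export
gndf_params <- function(i_open, di_b, mu, sigma, beta,
                        beta_max = gndf_beta_max()) {
  if (!is.finite(i_open) || !is.finite(di_b))
    stop("i_open and di_b must be finite", call. = FALSE)
  .check_shape(mu, sigma, beta)
  if (beta > beta_max)
    stop("beta exceeds beta_max (", beta_max, ")", call. = FALSE)
  blocked <- i_open + di_b
  if (i_open != 0 && (sign(blocked) != sign(i_open) || abs(di_b) > abs(i_open)))
    warning("non-physical blockade: |di_b| > |i_open| or sign reversal",
            call. = FALSE)
  structure(list(i_open = i_open, di_b = di_b, mu = mu,
                 sigma = sigma, beta = beta),
            class = "gndf_params")
}

#' @export
print.gndf_params <- function(x, ...) {
  cat(sprintf(
    "gNDF event parameters:\n  i_open = %.6g pA, di_b = %.6g pA\n  mu = %.6g s, sigma = %.6g s, beta = %.6g\n",
    x$i_open, x$di_b, x$mu, x$sigma, x$beta))
  invisible(x)
}

#' Five-parameter event model
#'
#' The blockade current profile
#' `I(x) = i_open + di_b * exp(-(|x - mu|/sigma)^beta)`. Returns
#' `i_open + di_b` at `x = mu`, recovers `i_open` far from the event, is
#' Gaussian-shaped at `beta = 2`, and approaches a rectangular pulse of
#' half-width `sigma` as `beta` grows.
#'
#' @param x Time, s.
#' @param params A [gndf_params()] object, or `NULL` if the individual
#'   parameters are supplied.
#' @param i_open,di_b,mu,sigma,beta Individual parameters, used when
#'   `params` is `NULL`.
#' @return Current, pA.
#' @export
event_model <- function(x, params = NULL, i_open = NULL, di_b = NULL,
                        mu = NULL, sigma = NULL, beta = NULL) {
  if (!is.null(params)) {
    stopifnot(inherits(params, "gndf_params"))
    i_open <- params$i_open; di_b <- params$di_b
    mu <- params$mu; sigma <- params$sigma; beta <- params$beta
  }
  i_open + di_b * gndf_kernel(x, mu, sigma, beta)
}
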