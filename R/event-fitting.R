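#' Fit options for the five-parameter event model
#'
#' @param max_iter Maximum optimizer iterations.
#' @param beta_max Upper bound of the shape exponent.
#' @param pad_factor Padding added on each side of a detection window,
#'   in multiples of the detected width, so the open-pore level is
#'   constrained by true baseline.
#' @param p Probability threshold for the per-event sampling frequency.
#' @param p_max Overlap-validation threshold, see [validate_overlap()].
#' @param fs_mode Sampling-frequency reading reported as `fs_event`.
#' @param rc_tau RC time constant used for residual-current correction,
#'   s; 0 disables it.
#' @return A list of class `fit_control`.
#' @export
fit_control <- function(max_iter = 200L, beta_max = gndf_beta_max(),
                        pad_factor = 5, p = 0.001, p_max = 0.05,
                        fs_mode = c("cdf", "amplitude"), rc_tau = 0) {
  fs_mode <- match.arg(fs_mode)
  structure(list(max_iter = as.integer(max_iter), beta_max = beta_max,
                 pad_factor = pad_factor, p = p, p_max = p_max,
                 fs_mode = fs_mode, rc_tau = rc_tau),
            class = "fit_control")
}

#' Initial parameter guess for an event window
#'
#' Heuristic starting point for the optimizer: the open-pore current
#' from the median of the padding samples outside the window, the
#' current difference from the in-window extremum, the localization
#' from the time of the extremum, the scale from half the width of the
#' region deeper than half the extremum depth, and `beta = 2`.
#'
#' @param trace A [nanopore_trace()] segment covering the window plus
#'   padding.
#' @param start,end Window as a 1-based half-open sample interval into
#'   `trace`.
#' @param direction `"down"` for blockades, `"up"` for enhancements.
#' @param require_signature Error with "no event signature" when the
#'   extremum depth is below four noise SDs of the padding (default);
#'   set `FALSE` to always return a guess (used when deliberately
#'   fitting baseline windows).
#' @return A [gndf_params()] object.
#' @export
initial_guess <- function(trace, start, end, direction = c("down", "up"),
                          require_signature = TRUE) {
  stopifnot(inherits(trace, "nanopore_trace"))
  direction <- match.arg(direction)
  x <- trace$current
  n <- length(x)
  start <- max(1L, as.integer(start)); end <- min(n + 1L, as.integer(end))
  if (end <= start) stop("empty window", call. = FALSE)
  inside <- seq.int(start, end - 1L)
  outside <- setdiff(seq_len(n), inside)
  if (!length(outside)) outside <- inside   # window covers whole segment
  i_open <- stats::median(x[outside])
  noise <- stats::mad(x[outside], center = i_open)
  sgn <- if (direction == "down") -1 else 1
  excursion <- sgn * (x[inside] - i_open)
  k <- which.max(excursion)
  depth <- excursion[k]
  if (require_signature && depth <= 4 * noise)
    stop("no event signature in window", call. = FALSE)
  mu <- index_to_time(trace, inside[k])
  deep <- inside[excursion >= depth / 2]
  width_s <- max(length(deep), 1L) / trace$fs
  sigma <- max(width_s / 2, 0.5 / trace$fs)
  suppressWarnings(
    gndf_params(i_open = i_open, di_b = sgn * depth, mu = mu,
                sigma = sigma, beta = 2))
}

#' Fit the five-parameter event model to a windowed segment
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt via
#' \pkg{minpack.lm}) of the blockade model over
#' `(i_open, di_b, mu, sigma, beta)`, started from [initial_guess()].
#' `sigma` and `beta` are fitted in log space for conditioning; `mu` is
#' bounded to the padded window and `beta` to `[1, beta_max]`. The fit
#' is deterministic for identical input. Non-convergence is reported in
#' the result (`converged = FALSE`), not raised.
#'
#' @param trace A [nanopore_trace()]; the fit uses the window plus
#'   `pad_factor` widths of context on each side.
#' @param start,end Detection window, 1-based half-open sample interval.
#' @param control A [fit_control()].
#' @param direction Blockade direction, as in [initial_guess()].
#' @return An object of class `gndf_fit`: a list with `params`
#'   ([gndf_params()]), `rmse` (pA), `converged`, `n_iter`, `at_bound`
#'   (character vector of parameters pinned at a bound), `non_event`
#'   (`TRUE` when the fitted amplitude is below four noise SDs),
#'   `window` (`c(start, end)`), `t_start`, `t_end` (window in trace
#'   time, s).
#' @export
fit_event <- function(trace, start, end, control = fit_control(),
                      direction = c("down", "up")) {
  stopifnot(inherits(trace, "nanopore_trace"),
            inherits(control, "fit_control"))
  direction <- match.arg(direction)
  x <- trace$current
  n <- length(x)
  start <- as.integer(start); end <- as.integer(end)
  if (end - start < 1L || start < 1L || end > n + 1L)
    stop("window outside trace", call. = FALSE)
  width <- end - start
  pad <- max(8L, ceiling(control$pad_factor * width))
  s0 <- max(1L, start - pad)
  s1 <- min(n, end - 1L + pad)
  if (s1 - s0 + 1L < 8L) stop("segment too short to fit", call. = FALSE)
  seg <- nanopore_trace(x[s0:s1], trace$fs,
                        t0 = index_to_time(trace, s0))
  w0 <- start - s0 + 1L
  w1 <- end - s0 + 1L
  guess <- initial_guess(seg, w0, w1, direction = direction,
                         require_signature = FALSE)
  tt <- trace_times(seg)
  yy <- seg$current
  out_idx <- setdiff(seq_along(yy), seq.int(w0, w1 - 1L))
  noise <- if (length(out_idx) >= 4L)
    stats::mad(yy[out_idx], center = guess$i_open)
  else stats::mad(yy, center = guess$i_open)
  span <- (s1 - s0) / trace$fs
  lower <- c(i_open = -Inf, di_b = -Inf,
             mu = index_to_time(trace, s0),
             log_sigma = log(0.25 / trace$fs), log_beta = 0)
  upper <- c(i_open = Inf, di_b = Inf,
             mu = index_to_time(trace, s1),
             log_sigma = log(span), log_beta = log(control$beta_max))
  par0 <- c(guess$i_open, guess$di_b, guess$mu,
            log(min(max(guess$sigma, exp(lower["log_sigma"])),
                    exp(upper["log_sigma"]))), log(2))
  resid_fn <- function(par) {
    event_model(tt, i_open = par[1], di_b = par[2], mu = par[3],
                sigma = exp(par[4]), beta = exp(par[5])) - yy
  }
  fit <- minpack.lm::nls.lm(
    par = par0, lower = unname(lower), upper = unname(upper),
    fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = control$max_iter))
  par <- fit$par
  params <- suppressWarnings(
    gndf_params(par[1], par[2], par[3], exp(par[4]), exp(par[5]),
                beta_max = control$beta_max))
  rmse <- sqrt(mean(fit$fvec^2))
  tol_b <- 1e-6
  names(par) <- names(lower)
  at_bound <- names(par)[(is.finite(lower) & par - lower < tol_b) |
                           (is.finite(upper) & upper - par < tol_b)]
  converged <- fit$info %in% 1:4 && fit$niter < control$max_iter
  structure(list(
    params = params,
    rmse = rmse,
    converged = converged,
    n_iter = fit$niter,
    at_bound = at_bound,
    non_event = abs(params$di_b) < 4 * noise,
    window = c(start = start, end = end),
    t_start = index_to_time(trace, start),
    t_end = index_to_time(trace, end - 1L) + 1 / trace$fs
  ), class = "gndf_fit")
}

#' @export
print.gndf_fit <- function(x, ...) {
  cat(sprintf("gNDF event fit (%s, %d iterations, rmse %.4g pA)\n",
              if (x$converged) "converged" else "NOT converged",
              x$n_iter, x$rmse))
  print(x$params)
  if (length(x$at_bound))
    cat("  at bound:", paste(x$at_bound, collapse = ", "), "\n")
  if (x$non_event) cat("  flagged non-event (amplitude below noise floor)\n")
  invisible(x)
}
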