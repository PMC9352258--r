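#' Back-mapped dwell time of the ideal pulse
#'
#' Reconstructs the duration of the ideal rectangular pulse whose height
#' equals the fitted current difference and whose area equals the area
#' under the fitted event profile:
#' `dt = 2 * sigma * gamma(1 + 1/beta)` (equivalently
#' `(2 * sigma / beta) * gamma(1/beta)`). For `beta = 2` this is
#' `sigma * sqrt(pi)`; as `beta` grows it tends to `2 * sigma`, i.e. a
#' rectangular fit recovers its own width. Because the filter chain
#' conserves pulse area, this estimate is robust to band-limiting that
#' depresses the apparent amplitude.
#'
#' @param sigma Scale of the fitted profile, s.
#' @param beta Shape exponent.
#' @return Dwell time, s. Vectorized over the inputs.
#' @export
dwell_time <- function(sigma, beta) {
  .check_shape(0, sigma, beta)
  2 * sigma * gamma(1 + 1 / beta)
}

#' Excluded and residual current fractions
#'
#' The excluded current is the blocked fraction of the open-pore
#' current, `i_ex = |di_b| / |i_open|`; the residual current is its
#' complement, `i_res = 1 - i_ex`.
#'
#' @param i_open Open-pore current, pA; must be nonzero.
#' @param di_b Signed blockade current difference, pA.
#' @return A list with components `i_ex` and `i_res`.
#' @export
excluded_current <- function(i_open, di_b) {
  if (any(i_open == 0)) stop("i_open must be nonzero", call. = FALSE)
  i_ex <- abs(di_b) / abs(i_open)
  list(i_ex = i_ex, i_res = 1 - i_ex)
}

#' Correct a residual current for RC charging
#'
#' The pore and membrane form an RC circuit; a blockade shorter than a
#' few time constants never fully charges it, so the residual current is
#' observed too high. Under the charging model
#' `i_res(t) = i_res + (1 - i_res) * exp(-t / tau)` this inverts the
#' observation at time `t` after blockade onset back to the asymptotic
#' residual current:
#' `i_res = (i_res(t) - exp(-t/tau)) / (1 - exp(-t/tau))`.
#' With `tau = 0` (the default model: charging negligible) this is the
#' identity. The corrected value can fall outside `[0, 1]` when the
#' observation is noisy; it is flagged by a warning, not clamped.
#'
#' @param i_res_obs Observed residual current fraction at time `t`,
#'   in `[0, 1]`.
#' @param t Time since blockade onset, s; `> 0` when `tau > 0`.
#' @param tau RC time constant of the system, s; `>= 0`.
#' @return Corrected residual current fraction (never above the
#'   observed value).
#' @export
rc_correct <- function(i_res_obs, t, tau) {
  if (!is.finite(tau) || tau < 0) stop("tau must be >= 0", call. = FALSE)
  if (any(i_res_obs < 0) || any(i_res_obs > 1))
    stop("observed residual current must lie in [0, 1]", call. = FALSE)
  if (tau == 0) return(i_res_obs)
  if (any(t <= 0))
    stop("correction undefined for t <= 0 with tau > 0", call. = FALSE)
  e <- exp(-t / tau)
  out <- (i_res_obs - e) / (1 - e)
  if (any(out < 0 | out > 1))
    warning("RC-corrected residual current outside [0, 1]", call. = FALSE)
  out
}

#' Forward RC charging model
#'
#' The observed residual current fraction at time `t` after blockade
#' onset, given the asymptotic residual current: the inverse of
#' [rc_correct()]. Used by the trace simulator and as the round-trip
#' check of the correction.
#'
#' @param i_res Asymptotic residual current fraction.
#' @param t Time since blockade onset, s.
#' @param tau RC time constant, s.
#' @return Observed residual current fraction.
#' @export
rc_charge <- function(i_res, t, tau) {
  if (tau == 0) return(i_res)
  i_res + (1 - i_res) * exp(-t / tau)
}

#' Does the detection window encompass the fitted localization?
#'
#' The back-mapped dwell time is quantitative only if the observed event
#' encompasses the localization of the fitted profile: `mu` must lie
#' inside the detection window (inclusive at both edges).
#'
#' @param mu Fitted localization, s.
#' @param t_start,t_end Window limits in trace time, s.
#' @return Logical flag.
#' @export
validate_localization <- function(mu, t_start, t_end) {
  if (any(t_end < t_start)) stop("empty window", call. = FALSE)
  mu >= t_start & mu <= t_end
}

#' Did the event reach its true amplitude? (back-mapped overlap)
#'
#' Checks that the reconstructed ideal pulse of width `dwell` centered
#' at the localization contains the central quantile interval of the
#' fitted profile: it searches for the smallest probability
#' `p in (0, 1/2)` such that `mu - qgndf(p) <= dwell / 2`, by bisection
#' to tolerance `tol`. The event is flagged as having reached its
#' amplitude when that threshold `p*` does not exceed `p_max`.
#'
#' Fits in the Gaussian limit (`beta` near 2) are the signature of a
#' pulse dilated below its plateau; their `p*` is large and they fail
#' this check, whereas fits with a discernible flat top (`beta` above
#' roughly 4 at the default `p_max`) pass. The threshold is a genuinely
#' numerical quantity with no closed form in general; bisection on the
#' monotone containment condition is used.
#'
#' @param sigma,beta Fitted shape.
#' @param dwell Back-mapped dwell time, s; defaults to
#'   [dwell_time()] of the shape.
#' @param p_max Largest acceptable probability threshold.
#' @param tol Bisection tolerance on `p`.
#' @return A list with `valid` (logical) and `p_star` (the threshold
#'   probability, or `NA` if the containment fails everywhere below
#'   `p_max`).
#' @export
validate_overlap <- function(sigma, beta, dwell = dwell_time(sigma, beta),
                             p_max = 0.05, tol = 1e-6) {
  .check_shape(0, sigma, beta)
  if (dwell <= 0) stop("dwell must be > 0", call. = FALSE)
  contained <- function(p) -qgndf(p, 0, sigma, beta) <= dwell / 2
  lo <- tol / 10
  hi <- 0.5 - tol / 10
  if (!contained(hi)) return(list(valid = FALSE, p_star = NA_real_))
  if (contained(lo)) {
    p_star <- lo
  } else {
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (contained(mid)) hi <- mid else lo <- mid
    }
    p_star <- hi
  }
  if (p_star <= p_max) list(valid = TRUE, p_star = p_star)
  else list(valid = FALSE, p_star = NA_real_)
}

#' Minimal required sampling frequency of an event
#'
#' The per-event effective frequency: the reciprocal of the time the
#' fitted profile spends near its plateau edge, a function of the event
#' shape (not of the dwell time). Two readings are provided:
#'
#' * `"cdf"` (default): `1 / (qgndf(1/2 + p) - qgndf(1/2 - p))`, the
#'   reciprocal of the time the curve spends within CDF-distance `p` of
#'   the localization.
#' * `"amplitude"`: `1 / (sigma * ((-log(p))^(1/beta) -
#'   (-log(1 - p))^(1/beta)))`, the reciprocal of the rise time between
#'   the amplitude fractions `p` and `1 - p` of the profile edge. This
#'   reading is commensurate with a low-pass filter cutoff and is the
#'   one used for filter recommendations.
#'
#' As the shape approaches a rectangle the edge rise time vanishes and
#' the quantity loses meaning; `NA` is returned when
#' `beta >= beta_max`.
#'
#' @param sigma,beta Fitted shape.
#' @param p Probability threshold, in `(0, 1/2)`; default 0.001.
#' @param mode `"cdf"` or `"amplitude"`.
#' @param beta_max Shape bound above which the frequency is undefined.
#' @return Frequency, Hz, or `NA_real_` when undefined.
#' @export
event_sampling_frequency <- function(sigma, beta, p = 0.001,
                                     mode = c("cdf", "amplitude"),
                                     beta_max = gndf_beta_max()) {
  mode <- match.arg(mode)
  if (!is.finite(p) || p <= 0 || p >= 0.5)
    stop("p must lie in (0, 0.5)", call. = FALSE)
  .check_shape(0, sigma, beta)
  undef <- beta >= beta_max
  width <- if (mode == "cdf") {
    qgndf(0.5 + p, 0, sigma, beta) - qgndf(0.5 - p, 0, sigma, beta)
  } else {
    sigma * ((-log(p))^(1 / beta) - (-log1p(-p))^(1 / beta))
  }
  out <- 1 / width
  out[undef] <- NA_real_
  out
}

#' Derived features of a fitted event
#'
#' Computes the full per-event feature set from a five-parameter fit:
#' back-mapped dwell time, excluded/residual current (optionally
#' RC-corrected), minimal required sampling frequency in both readings,
#' and the localization and amplitude-overlap validity flags.
#'
#' @param params A [gndf_params()] fit.
#' @param t_start,t_end Detection-window limits in trace time, s (or
#'   `NA` to skip the localization check).
#' @param p Probability threshold for the sampling frequency.
#' @param p_max Overlap-validation threshold, see [validate_overlap()].
#' @param rc_tau RC time constant for residual-current correction, s;
#'   0 disables the correction.
#' @param fs_mode Reading used for the reported `fs_event` column.
#' @param beta_max Shape bound.
#' @return A one-row `data.frame` with columns `dwell_time`, `i_ex`,
#'   `i_res`, `fs_event`, `fs_event_cdf`, `fs_event_amp`, `loc_valid`,
#'   `overlap_valid`, `p_threshold`.
#' @export
event_features <- function(params, t_start = NA_real_, t_end = NA_real_,
                           p = 0.001, p_max = 0.05, rc_tau = 0,
                           fs_mode = c("cdf", "amplitude"),
                           beta_max = gndf_beta_max()) {
  stopifnot(inherits(params, "gndf_params"))
  fs_mode <- match.arg(fs_mode)
  dt <- dwell_time(params$sigma, params$beta)
  cur <- excluded_current(params$i_open, params$di_b)
  i_res <- cur$i_res
  if (rc_tau > 0)
    i_res <- rc_correct(i_res, dt, rc_tau)
  ov <- validate_overlap(params$sigma, params$beta, dt, p_max = p_max)
  fs_cdf <- event_sampling_frequency(params$sigma, params$beta, p,
                                     mode = "cdf", beta_max = beta_max)
  fs_amp <- event_sampling_frequency(params$sigma, params$beta, p,
                                     mode = "amplitude", beta_max = beta_max)
  loc <- if (is.na(t_start) || is.na(t_end)) NA
         else validate_localization(params$mu, t_start, t_end)
  data.frame(
    dwell_time = dt,
    i_ex = 1 - i_res,
    i_res = i_res,
    fs_event = if (fs_mode == "cdf") fs_cdf else fs_amp,
    fs_event_cdf = fs_cdf,
    fs_event_amp = fs_amp,
    loc_valid = loc,
    overlap_valid = ov$valid,
    p_threshold = ov$p_star
  )
}
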