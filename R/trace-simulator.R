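#' Synthetic trace configuration
#'
#' Full specification of a synthetic single-channel recording: an
#' open-pore baseline, rectangular blockade pulses with known onset,
#' width and depth, optional first-order RC charging at the pulse edges,
#' an optional acquisition low-pass filter, white Gaussian noise, and
#' optional decimation to a target sampling rate (modelling the ADC).
#' The defaults mirror the experimental acquisition regime this package
#' targets: events simulated on a fast virtual clock, band-limited by a
#' 4-pole Bessel, then sampled at 500 kHz.
#'
#' @param fs Virtual sampling frequency of the simulation, Hz.
#' @param duration Trace duration, s.
#' @param i_open Open-pore current, pA.
#' @param noise_sd White Gaussian noise SD, pA (added at `fs`, i.e.
#'   before decimation).
#' @param rc_tau RC time constant applied to the ideal pulse train, s;
#'   0 disables charging effects.
#' @param acq_filter A [filter_spec()] for the acquisition chain, or
#'   `NULL`.
#' @param pulses `data.frame` with columns `onset` (s), `width` (s),
#'   `depth` (pA, positive for a blockade). Pulses must lie inside the
#'   trace and must not overlap.
#' @param seed Integer seed; all randomness in [synthesize()] derives
#'   from it.
#' @param decimate_to Target sampling frequency after filtering, Hz, or
#'   `NULL` to keep `fs`. Must divide `fs` evenly.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(fs = 1e7, duration = 0.01, i_open = 100,
                       noise_sd = 0, rc_tau = 0, acq_filter = NULL,
                       pulses = data.frame(onset = numeric(),
                                           width = numeric(),
                                           depth = numeric()),
                       seed = 1L, decimate_to = NULL) {
  stopifnot(is.data.frame(pulses),
            all(c("onset", "width", "depth") %in% names(pulses)))
  if (fs <= 0 || duration <= 0) stop("fs and duration must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (nrow(pulses)) {
    if (any(pulses$width <= 0)) stop("pulse widths must be > 0")
    if (any(pulses$onset < 0 | pulses$onset + pulses$width > duration))
      stop("pulses must lie within [0, duration]")
  }
  if (!is.null(acq_filter)) stopifnot(inherits(acq_filter, "filter_spec"))
  if (!is.null(decimate_to)) {
    if (abs(fs / decimate_to - round(fs / decimate_to)) > 1e-9)
      stop("decimate_to must divide fs evenly")
    if (is.null(acq_filter))
      warning("decimation without a preceding filter may alias noise",
              call. = FALSE)
  }
  structure(list(fs = fs, duration = duration, i_open = i_open,
                 noise_sd = noise_sd, rc_tau = rc_tau,
                 acq_filter = acq_filter,
                 pulses = pulses[order(pulses$onset), , drop = FALSE],
                 seed = as.integer(seed), decimate_to = decimate_to),
            class = "sim_config")
}

#' Ideal rectangular pulse train
#'
#' The noiseless, unfiltered ground-truth trace: `i_open` everywhere
#' except `i_open - depth` over each half-open pulse interval
#' `[onset, onset + width)`. Overlapping pulses are an error.
#'
#' @param config A [sim_config()].
#' @return A [nanopore_trace()] at the virtual sampling frequency.
#' @export
ideal_pulse_train <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- round(config$fs * config$duration)
  x <- rep(config$i_open, n)
  p <- config$pulses
  if (nrow(p) > 1L &&
      any(p$onset[-1] < (p$onset + p$width)[-nrow(p)]))
    stop("pulses overlap", call. = FALSE)
  for (i in seq_len(nrow(p))) {
    i0 <- floor(p$onset[i] * config$fs) + 1L
    i1 <- floor((p$onset[i] + p$width[i]) * config$fs)   # [onset, onset+width)
    if (i1 >= i0) x[i0:min(i1, n)] <- x[i0:min(i1, n)] - p$depth[i]
  }
  nanopore_trace(x, config$fs)
}

#' Synthesize a trace with known ground truth
#'
#' Pipeline: ideal pulse train, optional first-order RC relaxation at
#' each edge (time constant `rc_tau`), optional acquisition filter,
#' white Gaussian noise at the virtual rate, optional decimation by
#' plain subsampling (the ADC). Deterministic for a fixed seed.
#'
#' @param config A [sim_config()].
#' @return A list with `trace` (the synthetic [nanopore_trace()]) and
#'   `truth`, a `data.frame` of per-pulse ground truth: `onset`,
#'   `width`, `depth`, `dwell_time` (= width), `i_ex`.
#' @export
synthesize <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  tr <- ideal_pulse_train(config)
  x <- tr$current
  if (config$rc_tau > 0) {
    # exact zero-order-hold first-order low-pass 1 / (1 + s tau)
    a <- exp(-1 / (config$fs * config$rc_tau))
    x <- as.numeric(stats::filter(x * (1 - a), a, method = "recursive",
                                  init = x[1]))
  }
  if (!is.null(config$acq_filter))
    x <- switch(config$acq_filter$kind,
                gaussian = gaussian_lowpass(x, config$acq_filter$cutoff,
                                            fs = config$fs),
                bessel4 = bessel4_lowpass(x, config$acq_filter$cutoff,
                                          fs = config$fs))
  if (config$noise_sd > 0) {
    old <- globalenv()$.Random.seed
    set.seed(config$seed)
    x <- x + stats::rnorm(length(x), 0, config$noise_sd)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  fs_out <- config$fs
  if (!is.null(config$decimate_to)) {
    step <- round(config$fs / config$decimate_to)
    x <- x[seq(1L, length(x), by = step)]
    fs_out <- config$decimate_to
  }
  truth <- data.frame(
    onset = config$pulses$onset,
    width = config$pulses$width,
    depth = config$pulses$depth,
    dwell_time = config$pulses$width,
    i_ex = config$pulses$depth / abs(config$i_open)
  )
  list(trace = nanopore_trace(x, fs_out), truth = truth)
}
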