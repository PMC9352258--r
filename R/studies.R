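#' Seeded pulse-recovery study
#'
#' The package's standard simulation experiment for parameter recovery
#' under band-limiting. Each event is an ideal rectangular pulse of
#' random width on a 100 pA baseline with white noise at
#' `depth / snr`, characterized twice with a zero-phase Gaussian
#' filter:
#'
#' * *resolved*: cutoff `1.5 / width`, high enough that the pulse
#'   reaches its plateau (filter rise time about a quarter of the
#'   width);
#' * *over-filtered*: cutoff at `overfilter_factor` times the
#'   amplitude-mode per-event sampling frequency measured from the
#'   resolved fit, deep in the pulse-dilation regime.
#'
#' Widths and noise seeds derive deterministically from `seed`.
#'
#' @param n_events Number of simulated events.
#' @param seed Integer master seed.
#' @param snr Depth over noise SD at the simulation rate.
#' @param width_range Pulse width range, s (drawn uniformly).
#' @param depth Pulse depth, pA.
#' @param fs Virtual sampling frequency, Hz.
#' @param overfilter_factor Over-filtered cutoff as a fraction of the
#'   measured per-event sampling frequency.
#' @return A `data.frame` with one row per event: `width`, the true
#'   depth, and for each arm the fitted amplitude, shape, back-mapped
#'   dwell time, amplitude-mode sampling frequency and overlap flag
#'   (`res_*` and `ovf_*` prefixes).
#' @export
pulse_recovery_study <- function(n_events = 200, seed = 1, snr = 10,
                                 width_range = c(5e-6, 1e-4), depth = 30,
                                 fs = 1e7, overfilter_factor = 0.25) {
  set.seed(seed)
  widths <- stats::runif(n_events, width_range[1], width_range[2])
  sub_seeds <- sample.int(2^30, n_events)
  rows <- lapply(seq_len(n_events), function(i) {
    width <- widths[i]
    fc_hi <- 1.5 / width
    dur <- max(20 * width, 60 / fc_hi)
    cfg <- sim_config(fs = fs, duration = dur, i_open = 100,
                      noise_sd = depth / snr,
                      pulses = data.frame(onset = dur / 2, width = width,
                                          depth = depth),
                      seed = sub_seeds[i])
    sim <- synthesize(cfg)
    fit_at <- function(fc) {
      tr <- gaussian_lowpass(sim$trace, fc)
      center <- round(dur / 2 * fs)
      half <- round(max(2 * width, 6 / fc) * fs)
      fit <- fit_event(tr, max(1L, center - half),
                       min(length(tr), center + round(width * fs) + half))
      ov <- validate_overlap(fit$params$sigma, fit$params$beta)
      data.frame(di_b = fit$params$di_b, sigma = fit$params$sigma,
                 beta = fit$params$beta,
                 dwell = dwell_time(fit$params$sigma, fit$params$beta),
                 fs_amp = event_sampling_frequency(
                   fit$params$sigma, fit$params$beta, mode = "amplitude"),
                 overlap_valid = ov$valid, converged = fit$converged)
    }
    hi <- fit_at(fc_hi)
    lo <- fit_at(max(overfilter_factor * hi$fs_amp, 1.5 / dur))
    names(hi) <- paste0("res_", names(hi))
    names(lo) <- paste0("ovf_", names(lo))
    cbind(data.frame(width = width, depth = depth), hi, lo)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Seeded filter-sweep study
#'
#' The package's standard end-to-end emulation of a characterization
#' filter sweep. A train of identical blockades with a finite intrinsic
#' edge (first-order RC charging, microsecond-range time constant, as a
#' pore-membrane system exhibits) passes through a 4-pole Bessel
#' acquisition filter, is sampled at 500 kHz with white noise, and is
#' then characterized with [recommend_filter()] across the candidate
#' cutoffs. The ground-truth per-event sampling frequency is measured
#' from a noiseless copy of one pulse through the same acquisition
#' chain, fitted without a characterization filter.
#'
#' @param seed Integer master seed.
#' @param n_pulses Number of blockades.
#' @param width Pulse width, s.
#' @param rc_tau Intrinsic RC time constant, s.
#' @param depth Pulse depth, pA.
#' @param snr Depth over noise SD at the simulation rate.
#' @param cutoffs Candidate characterization cutoffs, Hz.
#' @param acq_cutoff Acquisition Bessel cutoff, Hz.
#' @param fs_out Recording sampling frequency, Hz.
#' @return A list: `recommendation` (the [recommend_filter()] result),
#'   `fs_true` (ground-truth amplitude-mode sampling frequency, Hz),
#'   `truth_fit` (the noiseless reference fit), `truth` (per-pulse
#'   ground-truth table).
#' @export
filter_sweep_study <- function(seed = 42, n_pulses = 40, width = 1.5e-4,
                               rc_tau = 6.5e-6, depth = 30, snr = 10,
                               cutoffs = c(1e3, 2.5e3, 5e3, 1e4, 2.5e4,
                                           5e4, 1e5),
                               acq_cutoff = 1e5, fs_out = 5e5) {
  spacing <- max(4e-3, 25 * width)
  onsets <- spacing * seq_len(n_pulses) - spacing / 2
  cfg <- sim_config(fs = 1e7, duration = spacing * (n_pulses + 0.5),
                    i_open = 100, noise_sd = depth / snr, rc_tau = rc_tau,
                    acq_filter = filter_spec("bessel4", acq_cutoff),
                    pulses = data.frame(onset = onsets, width = width,
                                        depth = depth),
                    seed = seed, decimate_to = fs_out)
  sim <- synthesize(cfg)
  # noiseless acquisition-limited reference pulse
  cfg0 <- sim_config(fs = 1e7, duration = 6 * spacing, i_open = 100,
                     noise_sd = 0, rc_tau = rc_tau,
                     acq_filter = filter_spec("bessel4", acq_cutoff),
                     pulses = data.frame(onset = 3 * spacing, width = width,
                                         depth = depth),
                     seed = 1, decimate_to = fs_out)
  ref <- synthesize(cfg0)$trace
  w0 <- range(which(ref$current < 100 - depth / 30))
  truth_fit <- fit_event(ref, w0[1], w0[2] + 1L)
  fs_true <- event_sampling_frequency(truth_fit$params$sigma,
                                      truth_fit$params$beta,
                                      mode = "amplitude")
  rec <- recommend_filter(sim$trace, cutoffs, loc_cutoff = 5000,
                          control = fit_control(fs_mode = "amplitude"),
                          baseline_window = 2001)
  list(recommendation = rec, fs_true = fs_true, truth_fit = truth_fit,
       truth = data.frame(onset = onsets, width = width, depth = depth))
}
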