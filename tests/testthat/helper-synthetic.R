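# Shared fixtures: everything is generated in code at test time.

# numeric integral of f over [lo, hi] (adaptive quadrature oracle)
integrate_oracle <- function(f, lo, hi, ...) {
  stats::integrate(f, lo, hi, rel.tol = 1e-10, abs.tol = 1e-12,
                   subdivisions = 2000L, ...)$value
}

# cumulative trapezoid on a grid
cumtrapz <- function(x, y) {
  c(0, cumsum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2))
}

# standard synthetic recording: rectangular pulses on a 100 pA baseline,
# simulated on a fast virtual clock, band-limited by a 4-pole Bessel at
# 100 kHz and sampled at 500 kHz -- the acquisition regime the package
# targets. SNR = depth / noise_sd = 10 by default.
make_recording <- function(n_pulses = 10, width = 10e-6, depth = 30,
                           noise_sd = 3, seed = 7, spacing = 2e-3,
                           fs_sim = 1e7, fs_out = 5e5,
                           bessel_cutoff = 1e5) {
  onsets <- spacing * seq_len(n_pulses) - spacing / 2
  cfg <- sim_config(
    fs = fs_sim, duration = spacing * (n_pulses + 0.5), i_open = 100,
    noise_sd = noise_sd,
    acq_filter = filter_spec("bessel4", bessel_cutoff),
    pulses = data.frame(onset = onsets, width = width, depth = depth),
    seed = seed, decimate_to = fs_out)
  synthesize(cfg)
}

# one isolated event on its own short segment, fitted after a Gaussian
# characterization filter; returns the fit and the derived features
fit_single_pulse <- function(width, depth = 30, cutoff, noise_sd = 0,
                             seed = 1, fs = 1e7, i_open = 100,
                             control = fit_control()) {
  dur <- max(20 * width, 60 / cutoff)
  cfg <- sim_config(fs = fs, duration = dur, i_open = i_open,
                    noise_sd = noise_sd,
                    pulses = data.frame(onset = dur / 2, width = width,
                                        depth = depth),
                    seed = seed)
  sim <- synthesize(cfg)
  tr <- gaussian_lowpass(sim$trace, cutoff)
  center <- round(dur / 2 * fs)
  half <- round(max(2 * width, 6 / cutoff) * fs)
  start <- max(1, center - half)
  end <- min(length(tr), center + round(width * fs) + half)
  fit <- fit_event(tr, start, end, control = control)
  list(fit = fit,
       features = event_features(fit$params, fit$t_start, fit$t_end,
                                 p = control$p, p_max = control$p_max,
                                 fs_mode = control$fs_mode))
}
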