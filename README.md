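# gndfit

Characterization of fast, short-lived ionic current blockades in
single-channel nanopore recordings — the signals produced by unassisted
peptide and protein translocation, where residence times of micro- to
milliseconds meet picoampere amplitudes and every acquisition chain is
band-limited. The package is for nanopore electrophysiologists who need
dwell times and excluded currents that do not depend on the low-pass
filter they happened to choose.

## The model

Each blockade is fitted with a five-parameter generalized normal event
function

```
I(t) = I_O + ΔI_B · exp( −(|t − μ| / σ)^β )
```

— open-pore current `I_O` (pA), signed blockade difference `ΔI_B` (pA),
localization `μ` (s), scale `σ` (s) and shape `β` — leaving only noise.
`β = 2` is the Gaussian profile of a fully filter-dilated pulse;
`β → ∞` the ideal rectangle. From the fit the package derives:

* **Dwell time** by equal-area back-mapping,
  `Δt = 2σ·Γ(1 + 1/β)`: the width of the ideal rectangular pulse of
  height `ΔI_B` with the same area. Since linear unit-gain filters
  conserve pulse area, `Δt` stays accurate even when the amplitude is
  visibly depressed.
* **Excluded / residual current** `I_ex = |ΔI_B|/|I_O|`,
  `I_res = 1 − I_ex`, optionally corrected for RC charging of the
  pore-membrane circuit.
* **Validity flags**: the detection window must encompass `μ`, and the
  reconstructed pulse must overlap the fitted profile's central
  quantile interval (a numerically found probability threshold `p*`) —
  the test of whether the event actually reached its full amplitude.
* **Per-event minimal sampling frequency** `F_s,event` from the shape
  of the fitted edge, in a CDF-interval and an amplitude-rise reading.
* **A recommended low-pass filter range** from a sweep of
  characterization cutoffs: over-filtering elongates dwell times and
  depresses amplitudes; under-filtering lets baseline noise eat into
  the amplitudes; the stable regime in between is reported with a
  per-cutoff audit table.

Supporting machinery: robust threshold event localization on a
strongly filtered copy of the trace, a zero-phase digital Gaussian
filter, an exact continuous-time 4-pole Bessel simulation of the
amplifier filter, a synthetic-trace generator with known ground truth,
a three-table SQLite event store, CSV/NPY trace I/O and a small CLI
(`inst/scripts/gndfit`) with `simulate`, `detect`, `fit`, `features`,
`recommend-filter` and `export` subcommands.

## Worked example

Six 20 µs, 30 pA blockades on a 100 pA baseline, simulated at 10 MHz
through a 100 kHz 4-pole Bessel, sampled at 500 kHz at SNR 10, then
localized at 5 kHz and characterized at 100 kHz:

```r
library(gndfit)
cfg <- sim_config(fs = 1e7, duration = 0.013, i_open = 100, noise_sd = 3,
                  acq_filter = filter_spec("bessel4", 1e5),
                  pulses = data.frame(onset = 2e-3 * (1:6) - 1e-3,
                                      width = 20e-6, depth = 30),
                  seed = 11, decimate_to = 5e5)
sim <- synthesize(cfg)
ev <- characterize_events(sim$trace, loc_cutoff = 5000, char_cutoff = 1e5,
                          baseline_window = 2001, trace_id = "demo")
ev[, c("t_start", "di_b", "beta", "dwell_time", "i_ex",
       "fs_event_amp", "overlap_valid")]
```

```
   t_start   di_b  beta dwell_time   i_ex fs_event_amp overlap_valid
1 0.000964 -31.13 6.289  1.945e-05 0.3116        93197          TRUE
2 0.002966 -30.44 6.196  2.004e-05 0.3042        89365          TRUE
3 0.004968 -31.32 4.258  2.014e-05 0.3126        65595         FALSE
4 0.006970 -29.26 6.311  1.942e-05 0.2924        93598          TRUE
5 0.008964 -29.91 6.558  2.089e-05 0.2989        89778          TRUE
6 0.010970 -29.77 7.057  1.997e-05 0.2974        99781          TRUE
```

The back-mapped dwell times recover the true 20 µs to a few percent and
the excluded currents the true 0.30, even though the 100 kHz
acquisition chain rounds a 20 µs pulse appreciably (`β ≈ 6`, not
rectangular). Event 3's flatter fit fails the amplitude-overlap check
and would be excluded from quantitative amplitude summaries;
`fs_event_amp` says these events needed roughly 90 kHz of bandwidth.
`store_events(ev, "events.sqlite")` persists detections, fits and
features in separate tables.

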