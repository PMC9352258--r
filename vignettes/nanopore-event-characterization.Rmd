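---
title: "Characterizing fast nanopore translocation events with the generalized normal model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing fast nanopore translocation events with the generalized normal model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gndfit)
```

## The problem

A nanopore sensor reports the passage of single molecules as transient
reductions ("blockades") of the ionic current through the pore. For
unassisted peptide and protein translocation the residence time is
micro- to milliseconds while the current change is tens of picoamperes,
so every practical recording is band-limited — by the analog Bessel
filter of the amplifier, the RC charging of the pore/membrane, the ADC,
and any digital preprocessing filter. When the event duration
approaches the effective rise time of that chain, the pulse *dilates*:
the observed amplitude drops and the observed duration grows, while the
area under the pulse is conserved. Threshold-style dwell-time
estimators then report biased, filter-dependent numbers.

`gndfit` characterizes each blockade with a five-parameter generalized
normal model, reconstructs the dwell time from the conserved area,
tests whether the blockade actually reached its full amplitude, and
reports the minimal sampling/filter frequency each event would have
required — which in turn yields a data-driven low-pass filter
recommendation.

## The event model

A blockade is modelled as

$$ I(t) = I_O + \Delta I_B \, \exp\!\left[-\left(\frac{|t-\mu|}{\sigma}\right)^{\beta}\,\right] $$

with the open-pore current $I_O$ (pA), the signed current difference
$\Delta I_B$ (pA, negative for a blockade), the localization $\mu$ (s),
the scale $\sigma$ (s) and the shape exponent $\beta$. Everything that
is not captured by these five parameters is treated as noise. At
$\beta = 2$ the profile is Gaussian — the signature of an event fully
dilated by a Gaussian-like filter chain; as $\beta \to \infty$ it tends
to a rectangular pulse of half-width $\sigma$ — the ideal, unfiltered
event. The associated distribution functions are closed forms
(`dgndf()`, `pgndf()`, `qgndf()`), with the CDF expressed through the
regularized lower incomplete gamma function
$P(1/\beta, (|t-\mu|/\sigma)^\beta)$ and the quantile function through
its inverse. The full width at half-maximum is
$2\sigma(\ln 2)^{1/\beta}$.

### Dwell time by area back-mapping

The ideal rectangular pulse of height $\Delta I_B$ that carries the
same area as the fitted profile has width

$$ \Delta t = \frac{2\sigma}{\beta}\,\Gamma\!\left(\tfrac1\beta\right)
            = 2\sigma\,\Gamma\!\left(1+\tfrac1\beta\right). $$

Because linear, DC-gain-one filters conserve pulse area, $\Delta t$ is
robust to band-limiting even when the amplitude is visibly depressed:
an amplitude loss inflates the fitted $\sigma$ by exactly the factor
that keeps $\Delta t \cdot |\Delta I_B^{\text{true}}|$ equal to the
area. The excluded current is $I_{ex} = |\Delta I_B| / |I_O|$, with
residual current $I_{res} = 1 - I_{ex}$.

The FWHM is a serviceable stand-in for $\Delta t$ only for steep
shapes: the relative discrepancy is 0.9% at $\beta = 3$, changes sign
before $\beta = 4$, peaks near 1.45% around $\beta \approx 7$ and then
decays like $0.42/\beta$; at the Gaussian limit it is 6%. The package
always reports the back-mapped $\Delta t$.

### RC charging

The pore and membrane form an RC circuit; a blockade shorter than a few
time constants (`rc_correct()`, $\tau$ typically microseconds) is
observed with too high a residual current,
$I_{res}(t) = I_{res} + (1 - I_{res})e^{-t/\tau}$. The correction
inverts this model and is off by default ($\tau = 0$): it is a
reconstruction of the charging behaviour, isolated behind one function,
and should only be enabled with a measured $\tau$.

## Validating an event

Two checks decide whether the back-mapped dwell time is quantitative:

1. **Localization containment** — the detection window must encompass
   the fitted $\mu$ (inclusive at both edges).
2. **Amplitude overlap** — the reconstructed ideal pulse of width
   $\Delta t$ centered at $\mu$ must contain the central quantile
   interval of the fitted profile. `validate_overlap()` finds the
   smallest probability $p^\ast \in (0, \tfrac12)$ with
   $\mu - Q(p^\ast) \le \Delta t/2$ by bisection (tolerance $10^{-6}$;
   the threshold has no closed form in general) and flags the event as
   having reached its amplitude when $p^\ast \le p_{\max}$.

The default $p_{\max} = 0.05$ was chosen from the geometry of natural
fits, where $\Delta t$ tracks $\sigma$: $p^\ast$ falls monotonically
from 0.184 at $\beta = 1$ through 0.105 at $\beta = 2$ to 0.057 at
$\beta = 4$ and 0.039 at $\beta = 6$. A Gaussian-limit fit
($\beta \approx 2$) is precisely the signature of a pulse dilated below
its plateau and must fail this check, while fits with a discernible
flat top ($\beta \gtrsim 4$–5) pass. A permissive threshold near 0.5
would accept every natural fit and make the flag vacuous.

## The per-event minimal sampling frequency

The minimal frequency an event would have needed is a property of its
*shape*, not its dwell time. Two readings are implemented
(`event_sampling_frequency()`):

* **`"cdf"`** (default): the reciprocal of the time the profile spends
  within CDF-distance $p$ of the localization,
  $1/[Q(\tfrac12+p) - Q(\tfrac12-p)]$. For $\sigma = 1$ s,
  $\beta = 2$, $p = 0.001$ this is 282.1 Hz.
* **`"amplitude"`**: the reciprocal of the edge rise time between the
  amplitude fractions $p$ and $1-p$,
  $1/\{\sigma[(-\ln p)^{1/\beta} - (-\ln(1-p))^{1/\beta}]\}$.

The two readings answer different questions and differ by orders of
magnitude for flat-topped events (the cdf reading probes the time
spent *at* the plateau center, the amplitude reading the time needed
to *reach* the plateau). Only the amplitude reading is commensurate
with a low-pass cutoff frequency, so filter recommendations compare
against it; the cdf reading is the default reported feature. Both lose
meaning as the shape approaches the rectangle — the edge rise time
vanishes — so `NA` is returned at the shape bound
($\beta \ge$ `gndf_beta_max()`, default 500).

## Detection, fitting, and their defaults

Events are first localized on a strongly filtered copy of the trace
(5 kHz Gaussian by default): a rolling-median baseline (window 10,001
samples) with a MAD noise estimate, a window opening at
baseline $\pm\, 5$ SD and closing on re-entry within 1 SD, and merging
of windows separated by fewer than 10 samples. Localization only
localizes: characterization refits the model on the raw (or separately
filtered) trace, never reusing the detection amplitudes.

The fit is bounded Levenberg–Marquardt least squares over
$(I_O, \Delta I_B, \mu, \sigma, \beta)$, with $\sigma$ and $\beta$ in
log space for conditioning, $\mu$ bounded to the padded window and
$\beta \in [1, 500]$. Below $\beta = 1$ the kernel cusps, which no
band-limited pulse can produce; above 500 the profile is numerically
rectangular. Parameters pinned at a bound are flagged. Each window is
padded by 5 detected widths per side so that $I_O$ is constrained by
true baseline — which also means event trains packed closer than about
six window widths should be characterized with a smaller
`pad_factor`. Multi-peaked windows are fitted to the single deepest
excursion; decomposing overlapping events is out of scope. Samples are
weighted uniformly. Fits are deterministic for identical input.

## Filters

* `gaussian_lowpass()` is the zero-phase preprocessing/display filter:
  a discrete Gaussian kernel with $\sigma_t = \sqrt{\ln 2}/(2\pi f_c)$
  (−3 dB at $f_c$, assumed to be how a digital Gaussian filter's
  cutoff is specified), unit kernel sum (exact DC gain 1), truncation
  at six SDs, reflected edges.
* `bessel4_lowpass()` emulates the analog acquisition filter: the
  4th-order Bessel transfer function normalized to −3 dB at the cutoff
  (the patch-clamp amplifier datasheet convention; the delay-normalized
  prototype's −3 dB point, ≈2.1139 rad/s, is located numerically and
  rescaled). It is applied *causally* as hardware would, via the exact
  zero-order-hold modal discretization: partial fractions over the four
  poles, each conjugate pair realized as a real second-order recursion.
  For piecewise-constant inputs — ideal pulse trains — this is exact,
  not a bilinear approximation, which is why simulations are run on a
  fast virtual clock (10–100 MHz) and decimated afterwards. The
  implementation is cross-checked in the tests against an independent
  ODE integration of the same state-space system.

## The synthetic-data generator

`sim_config()`/`synthesize()` emulate the acquisition chain this
package targets: an open-pore baseline (100 pA), rectangular blockade
pulses of known onset/width/depth, optional first-order RC relaxation
at the edges, an optional Bessel or Gaussian acquisition filter, white
Gaussian noise added at the virtual rate, and plain-subsampling
decimation to the recording rate (500 kHz by default in the studies,
with a 100 kHz Bessel — the standard amplifier regime). The generator
returns the per-pulse ground truth, which is what every round-trip
test and both studies compare against.

What it deliberately does **not** emulate: 1/f and dielectric noise
(the model treats noise as an unstructured residual), pore gating and
clogging epochs, analyte capture kinetics, and voltage-dependent event
rates. Passing tests therefore demonstrate correctness of the
*method* under its own assumptions — ideal-pulse origins and
Gaussian-like cumulative filtering — not robustness to every artifact
of a wet-lab recording.

## The two standard studies

`pulse_recovery_study()` (200 events by default) draws pulse widths
uniformly from 5–100 µs at SNR 10 and characterizes each event twice:
*resolved*, with a Gaussian cutoff of $1.5/\text{width}$ (filter rise
time about a quarter of the width), and *over-filtered*, at a quarter
of the amplitude-mode $F_{s,\text{event}}$ measured from the resolved
fit. Resolved fits recover amplitudes to well under 5% and dwell times
to well under 10% (median); over-filtered fits show the dilation
signature — amplitude biased low in essentially every event — while
back-mapped dwell times of any event still passing the overlap
validation stay within 10%.

`filter_sweep_study()` emulates the whole recommendation workflow: 40
blockades of 150 µs with an intrinsic 6.5 µs RC edge through a 100 kHz
Bessel at 500 kHz, localized once at 5 kHz and characterized at cutoffs
of 1–100 kHz. Ideal rectangles were deliberately *not* used here: a
zero-rise-time edge has its amplitude-mode $F_{s,\text{event}}$ set
entirely by the acquisition filter (≈130 kHz for a 10 µs pulse through
100 kHz Bessel), above every cutoff admissible at a 250 kHz Nyquist, so
no sweep could ever observe its stable regime. A microsecond-range RC
constant is also what the pore-membrane system physically imposes. With
these conditions the ground-truth $F_{s,\text{event}}$ (≈28 kHz,
measured from a noiseless reference pulse through the same chain) lies
inside the sweep, dwell medians elongate below ~3 kHz and stabilize
above ~10 kHz, and the recommended lower bound lands within a factor of
two of the truth.

`recommend_filter()` selects the lower bound as the smallest cutoff
whose median $F_{s,\text{event}}$ agrees with the next cutoff up within
10% (relative), and the upper bound as the largest cutoff before the
median fitted amplitude starts decreasing again — the signature of
baseline noise blending into the events under under-filtering. The
full per-cutoff table is returned so the choice can be audited; cutoffs
with fewer than five usable events are flagged and excluded.

## Numerical choices

* $(|x-\mu|/\sigma)^\beta$ is evaluated in log space; far tails
  underflow to exactly 0 instead of producing NaN.
* For steep shapes the power underflows *near the localization* too;
  the CDF and quantile switch to the small-argument expansion
  $P(1/\beta, z^\beta) = z/\Gamma(1+1/\beta)$ when
  $\beta \ln z < -600$, keeping both functions smooth through the
  center (the relative error of the dropped series term is below
  $10^{-260}$ there).
* Overlap validation bisects to $10^{-6}$ in $p$; the sweep's
  stability tolerance is 10% relative; fit convergence follows the
  Levenberg–Marquardt information codes with the iteration cap (200)
  treated as non-convergence.
* Degenerate inputs: flat windows raise "no event signature" from
  `initial_guess()` unless signature checking is disabled, which is
  how `fit_event()` fits deliberate baseline windows and flags them
  `non_event`; empty detection tables propagate as empty, fully typed
  feature tables.

## Storage and interfaces

Events are stored in one SQLite file with three normalized tables —
`detections`, `fits`, `features` — plus a `meta` key/value table
(configuration snapshot, package version, filters used). Keeping
detections separate from optimized results lets the fit be validated
against the raw localization; re-runs replace rows by
`(trace_id, t_start)`. The store and the NPY trace format are accessed
through small bundled Python-stdlib/numpy helpers; CSV traces need no
helper. Axon Binary Files are not parsed by this build — the reader
reports the conversion path instead; additional loaders are
straightforward to add behind `read_trace()`.

## Known limitations

Single-level events only (no sub-states within a blockade); no
decomposition of overlapping events; white-noise assumption in both
the simulator and the uniform-weight fit; the RC correction assumes a
single dominant time constant; `beta` estimates at the domain bound
mean the edge steepness, and hence $F_{s,\text{event}}$, is not
resolvable at the given sampling rate.
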