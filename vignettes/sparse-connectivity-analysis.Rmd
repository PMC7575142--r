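---
title: "Quantifying sparse synaptic connectivity from multi-neuron recordings"
author: "sparseconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying sparse synaptic connectivity from multi-neuron recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparseconn)
```

# Scope and scientific background

`sparseconn` implements the quantitative analysis chain used to establish
how sparsely a brain region is wired internally, using the lateral
hypothalamus (LH) as the motivating system and neocortex (mPFC) as the
densely connected benchmark.  Four experimental designs are covered:

1. **Chemical-connection screening.**  In simultaneous multi-neuron
   whole-cell recordings, each cell in turn fires an imposed train of 5
   action potentials at 50 Hz while the membrane potential of every other
   cell is monitored.  With `n` cells this yields `n(n-1)` directed
   probes per configuration.  Averaging 30--50 trials pushes the noise
   floor of the mean trace down by `1/sqrt(N)`, so sub-millivolt PSPs
   become detectable.
2. **Electrical-coupling quantification.**  During a hyperpolarizing
   current step in one cell, the gap-junction coupling coefficient is the
   steady-state voltage change in the non-injected cell divided by that
   in the injected cell.
3. **Optogenetic circuit mapping.**  Light pulses drive an
   opsin-expressing population while PSCs are recorded in voltage clamp.
   Because spontaneous PSCs (sPSCs) typically reflect single presynaptic
   sources, the ratio of mean optogenetically evoked PSC (oPSC)
   amplitude to mean sPSC amplitude estimates how many connected
   presynaptic neurons the light actually recruits; rounding the ratio
   gives an integer source-count estimate.
4. **Network-oscillation induction.**  A 5 s linear light ramp drives the
   local network while membrane currents are recorded; spectrogram power
   in the 10--80 Hz beta--gamma band, ramp versus baseline, tells an
   oscillating network from a non-oscillating one.

No raw recordings from the original experiments are publicly deposited,
so the package pairs every analysis stage with a synthetic-data generator
(`simConfig()` and the `simulate*()` family) whose ground truth is known
exactly.  All validation claims in this package are claims about that
generator's output, not about re-analysis of the original recordings.

# Units, sign conventions and containers

Voltages are mV, currents pA, distances µm, frequencies Hz.  Time is
stored in seconds and reported in ms for latencies and kinetics.  Raw
voltage-clamp currents keep their physiological sign (inward negative at
a −60 mV holding potential); every reported "amplitude" is a magnitude.
Intersomatic distances are measured in the 2-D slice plane, as they would
be from a micrograph; depth below the slice surface is metadata, not part
of the distance.

The central containers are S4 classes: `Trace` (one sweep plus optional
stimulus channel), `ProtocolSweepSet` (simultaneous sweeps grouped by
protocol), `Session` (cells + sweep sets + optional simulation ground
truth) and `SpectralResult`.  Sessions serialize to a single versioned
container file via `writeSession()`/`readSession()`; the layout (cell
table, per-protocol trial groups keyed by cell id, ground-truth matrices)
is documented in `?writeSession` and validated field-by-field on read.
Result tables are plain data.frames written as CSV by `runPipeline()`.

# The synthetic generator

`simConfig()` fixes the study conditions; one integer seed fully
determines every trace, and each generator stage draws from its own
substream (fixed offsets from the global seed) so stages can be rerun
independently without perturbing one another or the caller's RNG.

Key defaults and why:

* **Connection rates.**  `p_chem` defaults to 1/2074 (LH preset) or
  43/362 (mPFC preset) per directed pair, and `p_elec` to 3/1037 or
  3/181 per unordered pair -- the screened rates of the two regimes.
* **Synaptic kernel.**  Every PSP/PSC is a difference of two
  exponentials (rise 1.5 ms, decay 8 ms) normalized to unit peak, so
  "amplitude" always means peak deviation.  With zero noise the
  generator is exactly linear: k simultaneous unit events equal k times
  one event, which the estimator stage relies on.
* **sPSC amplitude law.**  Log-normal with median 20.3 pA and log-sd
  0.6.  The median matches the reported mean sPSC scale; the log-sd was
  chosen once so that the implied coefficient of variation (~66%)
  matches the reported 20.3 ± 13.5 pA, giving the right-skewed histogram
  a heavy enough tail for the top-5% comparison to be meaningful.
* **sPSC rate.**  2 Hz.  The source experiments do not report an sPSC
  frequency; this is a free parameter of the generator, set to a typical
  slice value, and everything downstream is insensitive to it beyond
  requiring enough events (≥ 20) for stable per-cell statistics.
* **Optogenetic responses.**  Each light pulse triggers, per connected
  source, one PSC at latency `Normal(6, 1)` ms -- inside the reported
  2.4--11.5 ms monosynaptic range -- with amplitude drawn from the *same*
  log-normal law as the sPSCs.  With probability 0.1 a source fires a
  second spike 3--8 ms later (a multiplet), producing the compound
  multiphasic oPSCs the detector must handle.  Optional "runaway action
  current" artifacts (~600 pA, 0.6 ms) emulate an opsin-positive cell in
  voltage clamp and exercise the artifact veto.
* **Light ramps.**  1.5 s baseline, 5 s linear ramp.  The oscillatory
  regime adds a 40 Hz synaptic current whose envelope scales linearly
  with light intensity up to 20 pA (so the band-power increase at full
  intensity approaches A²/2 = 200 pA², and its ramp average A²/6 ≈ 67
  pA²); the non-oscillatory regime adds only a 30 pA tonic inward ramp
  with unchanged sPSC statistics.  The oscillation is phenomenological
  (amplitude-modulated narrowband current), not an explicit
  excitatory/inhibitory network: the object under test is spectral
  detection, not network mechanism.  Five ramp sweeps per cell are
  simulated, emulating repeated presentations.
* **Membrane model.**  Single-compartment RC (200 MΩ, 100 pF, τ = 20 ms)
  with threshold-reset spiking and stereotyped spike waveforms -- enough
  to give current steps, rheobase behaviour and AP trains the right
  shape without conductance-based detail.

What the generator does *not* emulate: access-resistance drift, seal
degradation, correlated (pink) noise, short-term plasticity across the
5-AP train, dendritic filtering, and opsin photocurrent kinetics.
Passing tests therefore demonstrate correctness of the analysis chain
under idealized slice physics, not robustness to every artifact of real
recordings.

# Detection rules and their calibration

**Evoked-response screening** (`detectEvokedResponse()`).  For each
imposed spike, the peak deviation from a local pre-spike baseline within
a 1--20 ms window is taken; the response amplitude is the mean of these
peaks in the majority polarity, and a connection additionally requires
polarity agreement in at least 3 of the 5 spikes.  The original screening
criterion is unreported, so the rule here is the package's own and is
exposed as configuration.  One point deserves emphasis: a threshold of
`k` baseline-sds on a *windowed peak* is not the `k`-sd tail probability
of a single Gaussian sample -- the maximum of ~200 baseline-noise samples
exceeds 3 sd about 40% of the time.  The default threshold is therefore
calibrated by an internal Monte-Carlo of the exact null statistic (window
length, local-baseline subtraction, polarity rule and spike count all
included) to a nominal per-test false-positive probability `alpha`
(default 0.01).  A user-supplied `k_sd` applies the literal rule instead.
The calibration uses an isolated RNG stream and is cached per geometry.

**PSC detection** (`detectEvents()`).  One template-matching algorithm
serves spontaneous and evoked currents alike -- the oPSC/sPSC comparison
is only meaningful if both kinds are measured identically, so
classification (`classifyOpto()`) happens after detection and only sets
labels.  The matched filter (unit-peak kernel, least-squares scale)
detects events; its response threshold is 4 robust (MAD) noise sds.
Because the template's autocorrelation is much broader than the kernel
rise, close events are resolved on the raw trace: peaks of the rising
slope mark successive release phases; phases closer than 5 ms merge into
one *compound* event (multiphasic rise -- no dip in the trace is needed),
phases at least 5 ms apart split into separate events.  Amplitudes use
the matched-filter estimate when the local baseline is clean (unbiased,
noise-optimal) and the raw smoothed peak relative to the local pre-onset
level for compound events or events riding on another event's decay
tail.  Compound events keep their full superposed peak (they are real
charge injected by multiplet spikes) but their kinetics are reported as
unavailable.  Detections narrower than 1 ms at half amplitude are
discarded as action-current artifacts.  Event onset is the 10%-of-peak
crossing; rise time is 20--80%; the decay constant is a least-squares
single exponential fitted in the linear domain from the 50%-of-peak
point of the falling limb to its 5% crossing -- fitting from the peak
itself would be biased by the still-active rising exponential, and
selecting fit samples by *value* on a noisy trace (rather than by time
on a smoothed copy) would bias the constant upward.

**Per-cell statistics** (`eventStats()`).  The top-5% sPSC mean uses the
`ceiling(0.05 n)` largest amplitudes (at least one), so small samples
never produce an empty set; at least 20 spontaneous events are expected
for a stable estimate and fewer triggers a warning.  The presynaptic
count is the oPSC/sPSC mean-amplitude ratio rounded to the nearest
integer, with two boundary rules: no oPSCs at all gives 0, and any
detected oPSC gives at least 1 (a ratio in (0, 0.5) still means a
response exists).

**Coupling** (`couplingCoefficient()`).  Steady state is the last 20% of
the step window; baseline is up to 100 ms immediately before the step
with a 5 ms guard.  Presynaptic deflections under 1 mV are refused (the
ratio would be noise over noise) and flagged rather than returned as a
number.  A pair counts as coupled when both directional coefficients
exceed 0.005 -- below the practical noise floor of the steady-state
estimate -- making "coupled" synonymous with the bidirectional phenotype.

**Rates and intervals.**  Connection-rate tables use exact
Clopper--Pearson intervals (`rateFromCounts()`): in a regime where 0 and
1 successes dominate, Wald intervals would be vacuous.  Directed
chemical tests and undirected coupling pairs are never conflated: each
simultaneously probed pair contributes two directed chemical tests but
one coupling pair.  Distance histograms use half-open bins `[lo, hi)`
of 25 µm.

# Spectral analysis choices

Spectrograms use 0.5 s windows with 95% overlap after zero-phase
high-pass filtering at 10 Hz (4th-order Butterworth run forward and
backward; zero-phase preserves event timing).  Each window is
Hann-tapered with the taper's power correction, and power is reported as
one-sided spectral *density*, so integrating over frequency recovers the
signal variance -- a 20 pA tone at 40 Hz integrates to 200 pA² within
5% (the packaged tests assert this Parseval check).  A 5 s trace yields
`floor((5 - 0.5)/(0.5 * 0.05)) + 1 = 181` windows.  Band integration is
trapezoidal over the half-open band `[10, 80)` Hz.  Per cell, spectrogram
power is averaged across repeated ramp sweeps *in the power domain*:
power averaging is insensitive to the oscillation's trial-varying phase
(trace averaging would cancel it) and damps the band-power contribution
of occasional very large spontaneous PSCs from the log-normal tail.  The
baseline interval is the 1 s immediately preceding ramp onset and the
stimulation interval is the full 5 s ramp; both are configurable, the
defaults are fixed for reproducibility.

# Statistics

`compareGroups()` wraps the study's toolkit: paired/unpaired Student's t
and Wilcoxon rank-sum/signed-rank, all two-sided, groups summarized as
mean ± sd.  Rank tests use the exact distribution when both groups have
at most 25 observations and no ties, the normal approximation otherwise,
so fixture-scale results are reproducible.  No multiple-testing
correction is applied anywhere, deliberately matching the source
analysis; identical paired groups return statistic 0 and p = 1 rather
than an error.

# Problem sizes used in validation

The packaged tests and the acceptance script size their simulations as
follows, chosen once as a balance between statistical resolution and a
test suite that runs in minutes on one CPU: 100 null screening sessions
(1200 directed tests) for false-positive calibration and 30 sessions for
edge recovery, 10 trials per driven cell; coupling recovery over
coefficients 0.01--0.1 with 5 trials per step; 100 optogenetic runs (25
per source count in {1, 2, 3, 5}) of 50 light pulses each; 100 seeds per
ramp regime with 5 sweeps per cell.  Amplitude-law checks use ~10⁴
generated events.

# Known limitations

* The screening detection rule is a calibrated reconstruction; the
  original criterion is unreported, so detection *rates* on real data
  would depend on that choice even though all reported arithmetic does
  not.
* Amplitudes of events detected on another event's decay tail are
  measured from the local tail level, which slightly underestimates very
  close (5--10 ms) followers; matched-filter amplitudes of such events
  would instead overestimate them.
* The decay-constant fit assumes a mono-exponential tail; genuinely
  bi-exponential decays will be summarized by an intermediate constant.
* The spectrogram reports density with a Hann taper; absolute power
  comparisons against analyses using a different normalization need a
  constant conversion factor, though all within-package contrasts are
  normalization-independent.
* Session containers use R serialization; they are self-contained and
  versioned but not language-neutral.  The documented layout makes a
  translation to a hierarchical scientific format mechanical if needed.

# A minimal end-to-end run

```{r, eval = FALSE}
cfg <- simConfig(preset = "lh", seed = 1, p_chem = 0.3, psp_amp = 0.5)
out <- runPipeline(cfg, out_dir = tempfile("demo"),
                   n_trials = 10, n_pulses = 30)
out$screen$rates          # connection rates with exact CIs
out$couple                # directional coupling coefficients per pair
out$events$stats          # sPSC/oPSC amplitudes, ratio, source count
out$spectral              # per-cell band-power increases, both regimes
```
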