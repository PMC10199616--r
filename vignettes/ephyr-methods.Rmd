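---
title: "Methods: synthetic-ground-truth analysis of hippocampal electrophysiology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic-ground-truth analysis of hippocampal electrophysiology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ephyr)
```

## What this package computes, and why on synthetic data

`ephyr` implements a hippocampal electrophysiology analysis chain spanning
three recording classes:

1. **Voltage-clamp current traces** from single neurons: detection of
   spontaneous postsynaptic currents (outward IPSCs / inward EPSCs under a
   low-chloride internal solution at −50 mV) and of slow outward network
   bursts, with the standard inclusion criteria and baseline-normalized
   drug-effect summaries.
2. **8×8 multi-electrode-array (MEA) recordings** of organotypic slices:
   spike detection, Poisson-surprise burst detection, and a spatial
   activity-propagation analysis that counts the largest spatially adjacent
   group of channels exceeding ±2 SD around each dentate-gyrus (DG) trigger
   spike.
3. **Awake linear-probe LFP**: Morlet band power by behavioral state,
   theta-phase → gamma-power coupling profiles compared between groups by an
   extra-sum-of-squares F test on quadratic fits, and ripple (150–200 Hz)
   detection by the envelope z-score method with duration statistics.

Raw recordings of this kind are rarely deposited, so every stage is
validated against **synthetic recordings with exact ground truth**. The
generators (`gen_patch_trace()`, `gen_mea_recording()`, `gen_lfp()`) are
first-class, tested code: each is a pure function of its parameter object
(seed included), and each returns the embedded truth (event times and
amplitudes, wave recruitment schedule, ripple times and durations, epoch
schedule) alongside the signal. The test suite and the acceptance script
measure *parameter recovery*: how well the analysis recovers what the
generator put in.

### What the generators emulate — and what they do not

The patch generator superimposes Poisson trains of bi-exponential events
(difference of exponentials normalized to unit peak; default rise 1.5 ms,
decay 12 ms; amplitudes from a truncated normal, 20 ± 5 pA) on Gaussian
white noise (2 pA RMS), with slow outward plateau envelopes (20 pA, 500 ms,
0.034 Hz — the burst rate typical of neonatal CA3) that multiply the IPSC
rate threefold while active. Default event rates (IPSC 4 Hz, EPSC 0.25 Hz)
match a neonatal recording. The MEA generator places biphasic spikes and a
DG-triggered recruitment wave (plateau deflections of 6 noise SD, recruited
ring-wise at 0.25 channels/ms after a 5 ms lag, 12 channels by default) on
white noise. The LFP generator builds a 7 Hz theta carrier, a gamma carrier
whose envelope is `base·(1 + m·cos(θ − φ0))`, Hann-windowed ripple bursts
placed only in idle epochs, and a 1/f + white noise floor.

Real data differ in ways the generators deliberately do not model: event
amplitude and kinetic heterogeneity beyond a single kernel, electrode drift
and line noise, non-stationary behavioral states, spatially correlated
noise across MEA channels, and ripples co-occurring with sharp waves.
Passing tests therefore demonstrate that the *algorithms* are correct and
calibrated under controlled conditions, not that any particular biological
effect would be recovered from arbitrary real recordings.

φ0 defaults to π/8, the center of the phase bin [0, π/4): a coupling phase
on a bin boundary would split its peak between two bins and make
"peak bin" ill-defined. The DG trigger channel carries only trigger spikes,
so trigger ground truth is unambiguous.

## Synaptic event detection: baseline design

The detection threshold is the conventional two times the baseline RMS
noise. The noise scale (`estimate_rms_noise()`) is the MAD (Gaussian-scaled)
of a > 1 kHz high-passed copy, corrected for the filter's white-noise gain,
so sparse events do not inflate it.

The delicate part is the *baseline* from which deviations are measured.  A
short (tens of ms) running median — the obvious choice — fails on realistic
traces for two reasons we verified on ground truth: single events occupy a
large fraction of such a window and drag the median, fabricating
opposite-polarity "undershoots" that are detected as spurious inward
events; and the median happily tracks a 500 ms burst plateau, so burst
edges masquerade as events. `detect_events()` therefore uses a **two-scale
baseline**:

* a *flat* component: a long (10 × `baseline_ms` = 2 s) running median,
  refined twice by masking every sample whose deviation is event-like
  (above half threshold, padded past the decay) and re-estimating the
  baseline as the median of the unmasked samples in sliding windows;
* no explicit slow component: a network burst simply becomes one long
  supra-threshold outward run, and its nested events are recovered by
  peak splitting.

Within each supra-threshold run, additional maxima are accepted only when
they are beyond the refractory window (5 ms) and separated by a trough
whose *prominence* below both peaks is at least one threshold. A relative
("50% dip") criterion fails in both directions: noise wiggles along a
decay split single events, and nested burst events never split. The
prominence rule handles both. The 50 ms *pre-event* median is still
reported per event as `local_baseline_pa`.

Recovery at the reference conditions (IPSC 4 Hz, EPSC 0.25 Hz, SNR ≥ 5,
300 s) is measured by the acceptance suite; the per-polarity bias is a few
percent, dominated by genuinely unresolvable overlaps (events closer than
the refractory window).

`detect_network_bursts()` isolates the slow envelope with a 200 ms running
median rather than a low-pass filter: a linear filter integrates a 4 Hz
barrage of 20 pA events into > 10 pA pseudo-envelopes (we measured ~30
false bursts per 300 s that way), while the median is essentially immune
to sparse fast events. Burst extent is measured where the envelope exceeds
half the 10 pA amplitude criterion; episodes closer than 100 ms are
merged; every reported burst satisfies amplitude ≥ 10 pA and duration
≥ 100 ms by construction.

The 0.008 Hz inclusion floor is applied per polarity by default (a cell
with zero EPSCs should not contribute an EPSC frequency of zero to a group
mean), with `exclusion_per_polarity = FALSE` restoring the total-frequency
reading.

## MEA spread analysis

Spikes are threshold crossings (4 robust SD by default) of a 300–3000 Hz
band-passed copy, one per 1 ms refractory window, timed at the absolute
peak. DG *trigger* detection in the spread pipeline uses 6 SD: trigger
spikes are large by definition and the trigger train must be essentially
false-positive-free, whereas ordinary spike counting tolerates the
documented Gaussian-tail false-positive rate at 4 SD.

Burst detection is the Legéndy–Salcman Poisson-surprise method: the
surprise of `n` spikes in `t` seconds at mean rate λ is
`S = −log10 P(N ≥ n)`, `N ~ Poisson(λt)`, computed on the log scale
(`poisson_surprise()` matches direct tail summation to ~1e−15 relative).
Candidate cores (runs of ISIs below half the mean ISI) are greedily
extended and trimmed to maximize S, then accepted iff `S ≥ 10`,
`n ≥ 10` spikes and duration ≥ 0.1 s. At `S ≥ 10` the per-window tail
probability is 1e−10, so false positives on homogeneous Poisson trains are
expected (and observed) to be zero at any realistic train length.

For the cluster analysis, recordings are decimated to 5 kHz (anti-aliased)
and demeaned with 1 s windows at 50% overlap, window means linearly
interpolated (and linearly extrapolated at the edges, where a clamped
interpolation would leave residual drift). An *activity cluster* at a time
point is a spatially adjacent (8-connected, the 2-D default of standard
connected-component labelling) set of channels whose preprocessed signal
exceeds +2 SD (positive) or −2 SD (negative); per-channel SDs are computed
over the whole preprocessed recording because MEA channels have
heterogeneous gains. Only the largest component per polarity enters, and
the per-bin scalar is the larger of the two polarities, with the polarity
recorded for audit.

The lag grid is 21 points at 5 ms spacing covering 0–100 ms *after* the
trigger spike (a spike-centered −50…+50 ms grid is available via
`centered = TRUE`). The post-spike grid is the one consistent with
normalizing to the *first 4 bins following the spike* (0–15 ms) and with
summary windows defined at 0–20 ms and 30–70 ms post-spike; a centered
grid would place 10 of 21 bins before the trigger where those summaries
are undefined. Normalized mean curves equal 1 over the first 4 bins by
construction; triggers whose 100 ms window leaves the recording are
skipped.

## LFP rhythms

`preprocess_lfp()` low-passes at 350 Hz (zero-phase) and removes channel
means. Zero-phase filtering here and everywhere else uses odd-reflection
padding so constants and ramps pass without end transients. Epochs are
tiled into non-overlapping 3 s segments that never straddle a state
boundary; remainders are discarded so segments are independent units for
statistics.

Morlet analysis uses energy-normalized (unit-L2) analytic wavelets with
`n_cycles = 7` by default. Energy normalization makes the expected power
of white noise equal at every analysis frequency, so band power — the mean
power over time summed over a 1 Hz frequency grid — is proportional to
band width on a flat spectrum, a property the tests verify. Edge samples
without full wavelet support (2 σ_t) are excluded. Canonical bands: theta
3–12 Hz (the analysis convention; a 4–12 Hz reading exists in the
literature and the edges are arguments), low theta 3–6, high theta 7–13,
gamma 20–90.

### Theta-phase → gamma-power coupling

Per sample, theta phase is the angle of the 7 Hz Morlet coefficient and
gamma power the mean `|W|²` over 20–90 Hz; samples are pooled into 8 equal
phase bins over [−π, π). Group differences in the modulation profile are
tested exactly as in the classical design: one quadratic
`power = a·θ² + b·θ + c` fitted to both groups pooled versus separate
quadratics per group, compared by the extra-sum-of-squares F test
(`compare_quadratic_fits()`).

Two design choices make this test *calibrated*, and both were validated by
null simulation (two independent uncoupled recordings compared):

* **Replicates per group.** The wavelet's temporal envelope smooths gamma
  power across neighbouring phase bins, so the 8 bin means of one profile
  are correlated; an F test on a single profile per group treats that
  smooth shape noise as residual and rejects far above nominal (~25%
  measured). `phase_gamma_replicates()` computes one profile per
  round-robin subset of segments (5 by default), so the residual contains
  genuine between-replicate shape variation — exactly the role replicate
  animals play in a group comparison. For the same reason the profile
  wavelet defaults to 3 cycles (band power keeps 7): at 7 cycles the
  smoothing spans about a full theta cycle and neighbouring bins are
  almost perfectly correlated.
* **Per-profile normalization.** Absolute power differs between recordings
  for reasons unrelated to coupling (impedance, noise floor); as a level
  shift common to all bins of a profile it would enter the F statistic as
  a spurious group effect. Profiles are normalized to unit mean power, so
  the comparison is about modulation *shape*. With these choices the
  measured null rejection rate is at the nominal 5% and power against a
  modulation depth of 0.8 versus 0 is essentially 100%.

### Ripples

`detect_ripples_kay()` implements the envelope z-score method: band-pass
150–200 Hz per channel, square, sum across channels, Gaussian-smooth
(σ = 4 ms), square-root, z-score against the idle-epoch mean and SD;
candidates are idle intervals with z ≥ 2, extended outward to a boundary
level, merged across sub-threshold gaps shorter than the configured
minimum, and dropped below 15 ms. Detection is invariant to a common gain
on all channels and monotone in the threshold. On event-free noise the
z ≥ 2 threshold *does* fire at the Gaussian-tail rate — that false-positive
rate is a documented property of the method, reported rather than hidden;
on recordings that contain real ripples the events themselves inflate the
idle SD and noise stays below threshold.

The boundary level defaults to z = 0.25 rather than the classical return
to the mean (z = 0): the smoothed envelope of 50 Hz-wide band noise is a
correlated process whose zero crossings wander, and on ground truth the
mean-return convention added tens of milliseconds of spread to event
durations; 0.25 marks essentially the same support with far less variance
(`boundary_z = 0` restores the convention).

Durations are estimated by default with a forward-model refit
(`duration_method = "template"`): each event's smoothed squared envelope is
fitted with a raised-cosine (Hann) burst at the event's estimated carrier
frequency passed through the *actual* detection chain — band-pass filter,
squaring, Gaussian smoothing. This matters because the band filter rings
for roughly the reciprocal bandwidth (~20 ms) and a boundary-crossing
duration inherits both that bias and the envelope noise. On synthetic
ground truth the template fit reduces duration RMSE to ~9–12 ms, about a
five-fold improvement over the boundary convention. Two limitations are
inherent: the template assumes a symmetric tapered envelope (appropriate
for the generator; real sharp-wave ripples are roughly spindle-shaped but
asymmetric), and even a near-maximum-likelihood estimator retains a
noise-limited error tail of a few percent of events beyond ±20 ms at
realistic SNR — we verified by multi-start refitting that this tail is not
an optimization artifact. Ripple statistics report the occurrence rate
over the full idle time, mean duration, and the percentage of events
strictly longer than 100 ms.

## Group statistics

`two_way_anova()` uses Type-II sums of squares via `car::Anova` (Type III
with sum-to-zero contrasts is a switch): Type II is the appropriate default
for the mildly unbalanced per-animal designs this pipeline produces.
`pairwise_tests()` wraps the standard two-sample machinery
(`wilcox.test`, `t.test`) per stratum — exact rank-test p-values for small
tie-free samples, normal approximation with tie correction otherwise —
with Holm–Šídák step-down adjustment
(`p'_(i) = 1 − (1 − p_(i))^(m−i+1)`, monotonicity enforced, never below the
raw p). Degenerate strata (no variation) are flagged rather than errored.
`slope_compare()` fits per-subject least-squares slopes over designated
trials (e.g. relearning trials after a goal relocation) and compares the
two groups' slope sets by a two-tailed unpaired t test. Null calibration
(rejection rate at α = 0.05 under label permutation) is part of the test
suite.

## Numerical choices and problem sizes

* All on-disk times are seconds; intervals are half-open `[start, end)`;
  tables are plain CSV with headers; the flat-binary container is
  little-endian int16 interleaved by time point with a key=value sidecar.
  Writing is deterministic, so repeated runs are byte-identical — a
  property the test suite asserts through the command-line interface.
* Quantization scale for writing defaults to `max|x|/32000`; round-trip
  error is bounded by half a scale step.
* The test and acceptance simulations use 300 s patch traces (20 seeds for
  rate recovery), 15 s MEA recordings at 10 kHz (10 seeds), 33 s LFP
  simulations for coupling (100 + 100 seeds in the acceptance suite) and a
  160 s idle LFP for ripple recovery (~50–60 events) — sizes chosen so the
  Monte-Carlo error of each recovered quantity is small against its
  tolerance.
* Seeds are mandatory in all generator parameter objects; identical
  parameters and seed give bit-identical output.

## Known limitations

* Event detection assumes a single PSC kernel family; strongly
  heterogeneous kinetics (e.g. mixed somatic/dendritic events) would blur
  the amplitude estimates, though counts are robust.
* In-burst *inward* events are hard to separate from the outward envelope
  by any threshold method and are not specifically recovered; they are a
  small fraction of events at realistic rates.
* The ripple duration template assumes a tapered symmetric envelope; for
  real data the boundary convention may be preferable for comparability
  with published numbers, and both are exposed.
* The CFC profile inherits all caveats of fixed-frequency theta phase
  (7 Hz): strongly non-sinusoidal or frequency-wandering theta would bias
  the phase estimate.
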