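---
title: "Methods: interictal dynamics, detectors and the closed-loop emulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interictal dynamics, detectors and the closed-loop emulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(interictal)
```

# Scope and model

This package analyses interictal dynamics in dual-site (hippocampus/HC and
medial prefrontal cortex/mPFC) LFP recordings from a progressive focal
epilepsy (kindling) model, and emulates the closed-loop intervention that
targets them. The scientific picture it operationalizes:

* Hippocampal **interictal epileptiform discharges (IEDs)** are large
  (0.5–2.5 mV) biphasic transients in NREM sleep. Each IED can reset the
  cortical slow oscillation, producing a cortical **DOWN state** at a
  ~150 ms latency followed by a **sleep spindle** (10–16 Hz) in the ensuing
  UP state.
* With kindling progression, hippocampal IED rate rises early; the
  cortical *responsiveness* to those IEDs (the IED→DOWN→spindle coupling)
  declines later, while the cortex begins to generate **independent IEDs**
  of its own (no hippocampal counterpart within 100 ms) and its LFP
  acquires a sharper, less predictable texture.
* A causal controller that detects hippocampal IEDs in real time (50–85 Hz
  band power threshold) and immediately stimulates the cortex can cancel
  the coupled DOWN/spindle response; chronically, this prevents the
  downstream progression (independent IEDs, sharpness rise).

Every analysis stage is exercised against a seeded synthetic generator
that embodies exactly this causal structure, so each detector and statistic
has ground truth.

# The synthetic world

`gen_params()` fixes the stated world; the defaults are chosen once and
documented here, not tuned per test.

* **Background**: pink (1/f) noise at 90 µV SD per channel, plus
  state-dependent narrowband components — cortical slow oscillation
  (0.5–4 Hz, 150 µV) and hippocampal delta in NREM, hippocampal theta
  (5–8 Hz, 120 µV) in REM. The background SD is set so that the paper-range
  IED amplitudes (0.5–2.5 mV) sit *below* the detector's own
  100-SD artifact-rejection bound: the detection rules and the amplitude
  range are both fixed, so the background must make them mutually
  consistent.
* **IED template**: difference-of-Gaussians sharp transient (σ = 2.5/5 ms,
  spectral content in the 50–85 Hz detection band) with an
  opposite-polarity slow wave (~250 ms).
* **Coupling**: with probability `p_couple`, an HC IED triggers a cortical
  DOWN (positive deflection then undershoot) at lag N(150 ms, 30 ms), and a
  spindle whose onset follows the DOWN peak by U(50, 150) ms.
* **Spindles** are tapered-cosine (Tukey, 30% taper) sinusoid bursts,
  0.5–1.5 s, 10–16 Hz, amplitude U(105, 165) µV. A pure Hann envelope (the
  first design intent) makes the supra-threshold extent of a 0.5 s spindle
  ~0.26 s — below the 350 ms acceptance duration — i.e. an internally
  inconsistent world; the Tukey envelope preserves waxing–waning morphology
  while the supra-threshold extent tracks the nominal duration. Amplitudes
  are placed mid-way between the detector's 4-SD and 14-SD clauses
  (computed against the clean-background band SD).
* **Background physiology**: spindles at 8/min and DOWN states at 8/min of
  NREM, independent of IEDs. The background spindle rate matters: the
  session-level coupling statistic M is a *relative* enrichment, and if
  nearly all spindles were IED-coupled, cancelling the coupling would
  remove numerator and baseline alike.
* **Spiking**: 20 putative pyramidal cells (~1.5 Hz) and 5 interneurons
  (~8 Hz), as piecewise inhomogeneous Poisson processes — transient gain
  after IEDs (per-unit gain drawn from a shared lognormal responsiveness,
  which also drives the independent-IED response, giving the cross-event
  per-unit correlation), ×0.1 thinning inside DOWN states, and a rebound
  gain for 500 ms after pathological DOWNs.
* **Kindling schedule** (`make_kindling_schedule()`): HC IED rate rises
  sigmoidally 1→10/min over days 1–10; `p_couple` falls 0.7→0.2 over days
  10–20 while the coupling-lag SD doubles (reduced temporal precision, as
  reported for late kindling). Crucially, the *downstream* progression is
  not scheduled: the independent-IED rate and the LFP sharpness gain of day
  *d* are logistic/saturating functions of the cumulative count of
  **surviving** coupled DOWN events per NREM minute on days < *d*. All
  three experimental arms share identical schedules; an intervention that
  cancels coupled events therefore mechanistically slows the emergence of
  independent IEDs and the sharpness rise, rather than being flagged to do
  so.
* What the generator does **not** emulate: real spike waveforms (units are
  point processes), volume-conduction geometry, seizures, REM physiology
  beyond theta, inter-animal variability. A green test therefore
  establishes that the *analysis rules* recover the *stated* structure at
  the stated SNR — not that they would perform identically on in vivo data.

# Detectors

All offline detectors use zero-phase (forward–backward) Butterworth
filtering — implemented in-package together with Hilbert envelopes,
Savitzky–Golay smoothing, Slepian tapers and Morlet wavelets, validated
against independently computed reference values — so event timing is
unbiased; the online emulator uses strictly causal biquads.

* **IED** (`detect_ied()`): 50–85 Hz bandpass, rectification; candidates
  where the envelope exceeds its NREM-baseline median by 5 SD. The
  baseline is *two-pass*: provisional supra-threshold epochs (±100 ms) are
  excluded before the final statistics, since the events themselves
  otherwise dominate the SD. Confirmation requires the >15 Hz waveform
  within ±50 ms of the peak to exceed the baseline mean by 10 SD;
  amplitudes beyond 100 SD are rejected as artifacts; candidates within
  100 ms merge keeping the larger peak.
* **Spindle** (`detect_spindles()`): 10–20 Hz order-4 Butterworth,
  analytic-signal envelope; events at baseline+2 SD with an interior peak
  in [4, 14] SD; <250 ms gaps merged; durations restricted to 0.35–3 s.
  The baseline excludes ±200 ms around cortical IEDs *and* (two-pass)
  provisional supra-2SD epochs; candidates peaking inside an IED epoch are
  discarded (IED band leakage is not a spindle).
* **DOWN state** (`detect_down_states()`): 0.5–6 Hz z-scored cortical LFP;
  (start, peak, end) from up–down–up zero crossings of dZ/dt; accepted when
  Z(peak) > 1 & Z(end) < −1.5 or Z(peak) > 2 & Z(end) < 0, duration
  0.15–0.5 s; validated when multiunit rate in peak±100 ms falls below half
  the session NREM rate; *pathological* when an HC IED peak lies in
  [start − 200 ms, peak] (the upper edge is the peak rather than the start
  because the zero-crossing-derived start jitters earlier than the
  physiological onset).
* **Sleep scoring** (`score_sleep()`): 1-s windows; WAKE on accelerometer
  power, REM on hippocampal theta/delta > 2, NREM when cortical delta
  log-power is not collapsed relative to the session's typical sleep level
  — a *robust* (median/MAD) z with threshold −1.5 plus a 5 µV RMS floor.
  A mean/SD z (the first design intent) fails on NREM-dominated sessions
  because the z centres on the NREM windows themselves. Labels are smoothed
  by a 5-window majority vote.

# Coupling statistics

`ccg_convolution()` bins target-event lags around reference events and
estimates the expected baseline by convolving the raw counts with a
**hollow Gaussian** kernel (centre bin zeroed, renormalized; default SD
100 ms at 10 ms bins), with pointwise 95% Poisson bounds. The coupling
modulation is `M = (a − b)/b`, with `a` the largest count inside the test
window among bins exceeding the upper bound and `b` the baseline there;
when nothing is significant `M = 0`. Two deliberate choices:

* The default ±50 ms peak-search window exists for jittered physiological
  couplings; under the null it pays an (uncorrected) multiplicity cost, so
  calibration checks of the null M use the literal zero-lag bin.
* For *session-level* IED→spindle coupling (`session_coupling_metrics()`),
  counts are small and latencies long (spindle onsets lag the IED by
  0.2–0.5 s), so M is computed on 0.2 s bins over a ±2 s window with a 1 s
  kernel and test window [0, 0.6] s: the wide kernel estimates the local
  background rate rather than tracking the coupled peak itself, keeping M
  monotone in the true coupling probability (and robust to the
  detection-depletion zone around stimulation artifacts).

Coherence uses 5 Slepian tapers (time–bandwidth 3) on seeded draws of
disjoint 10 s segments, spectra averaged over tapers and segments.
The Mann–Kendall test uses the tie-corrected normal approximation with
continuity correction, and the exact inversion-number null distribution
for n ≤ 10 without ties.

# Spiking statistics

The significance gate for peri-event modulation is a jittered-permutation
maximum-deviation test on the event-locked cumulative spike-time
distribution (the binning-free temporal-anomaly family): observed statistic
= sup-distance between the empirical lag distribution and uniform; null
from ±2 s uniform event jitters; p = (1+#{null ≥ obs})/(1+n_perm).
Sessions with fewer than 20 events are excluded, not tested. IFR amplitude
and latency come from a 10 ms-SD Gaussian-kernel event-averaged rate,
normalized by the unit's baseline rate (NREM time excluding ±1 s around
analysed events).

# Epileptogenicity index

Ten random disjoint 5-s NREM segments per session; each is Savitzky–Golay
filtered (window 11 samples, order 3), the absolute discrete gradient
taken, samples above 20× its median removed as artifact, and the segment
statistic is the median-based threshold itself:
`median(|g|) + 5 · 1.4826 · MAD(|g|)` (µV/sample). Session values are
z-scored against the pooled baseline-session segment values; the
longitudinal trend is summarized by the OLS slope on day and Mann–Kendall.
Because the statistic is deliberately robust, sparse transients barely move
it; what it tracks is a *broadband texture* change, which the generator
supplies as a continuous 50–150 Hz component scaled by the sharpness gain
(bands much above ~150 Hz are attenuated by the Savitzky–Golay filter
before the gradient and would be invisible to the index).

# Closed-loop emulator

`stream_detector()` is strictly causal: 4th-order causal bandpass (two
biquads), rectification, 20 ms causal moving average; the threshold is
frozen at mean + k·SD of the first 10 s of band power. The default
multiplier is k = 6: the source system customizes this per animal, and 6
is the value at which false triggers on the generator's baseline fall
below 1/min (at k = 5 they are ~2/min; online sensitivity at default SNR
is 1.0 at either value). Detections gate Gaussian cortical stimulation
under a 3 s refractory period (gating stimulation, not detection); an
accelerometer power veto suppresses movement-artifact triggers.
Stimulation within the effective window (IED onset to +150 ms after the
peak — always before the coupled DOWN) cancels that IED's planned cortical
response with probability `p_eff`. Stimulated sessions carry a 200 ms
artifact on the cortical channel only; `blank_artifacts()` interpolates
those samples and excludes them from cortical baselines and detection (the
hippocampal channel stays observable).

Sham stimulation draws the same number of stimulations uniformly over the
session (respecting the refractory period); chance hits still cancel.

# Numerical choices and degenerate inputs

* Canonical rate 1250 Hz; `read_session()` resamples other rates with a
  windowed-sinc anti-aliased polyphase filter. Times are seconds from
  session start; intervals are half-open; amplitudes µV.
* Zero-phase filtering pads by odd reflection (~3 cycles of the lowest
  band edge); narrow low-frequency bands are applied as second-order
  sections (the transfer-function form is numerically singular there).
* Empty/degenerate inputs: detectors error when NREM < 60 s (unreliable
  baselines); `coupling_modulation()` errors on a zero baseline; constant
  segments have sharpness 0; all-zero sessions score no NREM (noise
  floor).
* Sidecars and provenance files are JSON (no YAML parser available in the
  target environment); content is unchanged.

# Known limitations

* The generator's behavioral states are deterministic blocks, not a sleep
  model; sleep-scoring accuracy on it does not certify the scorer for real
  data.
* Session-level M values on the synthetic world are larger than typical
  published values (the synthetic coupling is cleaner than in vivo); only
  directions and calibrations are compared, not magnitudes.
* The closed-loop emulator models the network effect of stimulation as a
  Bernoulli cancellation (`p_eff`) plus an artifact; no dose–response or
  biophysics.
* ZETA-style significance is approximated by the jitter-permutation
  deviation test; the two agree in family (binning-free temporal
  deviation) but not in exact p-values.
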