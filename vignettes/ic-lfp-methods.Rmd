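---
title: "Methods: IC LFP transient and steady-state analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: IC LFP transient and steady-state analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icassr)
```

## The measurement problem

A depth electrode in the inferior colliculus (IC) records the local field
potential (LFP) while the animal hears either brief tone bursts or sustained
amplitude-modulated (AM) tones. Two complementary response modes are
quantified:

* the **transient evoked response** — a short-latency voltage deflection
  after each tone-burst onset, characterized by its peak latency and
  baseline-referenced amplitude after averaging over trials; and
* the **auditory steady-state response (ASSR)** — a sustained oscillation
  phase-locked to the AM envelope, characterized by narrowband power and by
  magnitude-squared coherence (msc) with the reference sine that encodes
  the envelope.

A second recorded channel carries the stimulus sync track (a square pulse
per burst, a reference sine per AM segment), so all analyses are locked to
recovered event times rather than nominal ones.

## Stimuli and event recovery

`buildTransientTrain()` renders gated 10-kHz carrier bursts: a 1-ms linear
rise, a 38-ms plateau and a 1-ms linear fall (40 ms total), one burst every
500 ms, 120 bursts over 60 s. The fall ramp mirrors the rise; the source
protocol describes the burst offset only qualitatively (an inclined fall),
so the mirrored 1-ms linear ramp is this package's reading, chosen for
symmetry and testability rather than claimed fidelity.

`buildAmTone()` uses the standard double-sideband AM convention
$x(t) = [1 + m\sin(2\pi f_m t)]\,\sin(2\pi f_c t)/(1+m)$ with depth
$m \in [0,1]$. The $1/(1+m)$ scaling guarantees $|x| \le 1$ at every depth
(no clipping on the 16-bit WAV path) while preserving the sideband/carrier
magnitude ratio $m/2$ that the tests verify by FFT.

`detectReferenceEvents()` thresholds the sync track at 50% of its peak,
bridges sub-threshold gaps shorter than 0.05 s (so the troughs of a
reference sine coalesce into one segment while 460-ms interpulse gaps keep
bursts distinct), classifies runs shorter than 0.5 s as square pulses and
longer runs as sine segments, and estimates each segment's frequency by
quadratic interpolation of the log-magnitude FFT peak (Hamming-tapered,
power-of-two length). For a 30-s segment the FFT bin is ~0.04 Hz and the
interpolation error is well below 0.01 Hz; burst onsets on a noiseless
track are exact to the sample. The detector is threshold-based by design
(parameter-light, auditable); heavily corrupted sync tracks are out of its
scope.

## Spectral estimation

All spectral quantities use a Hamming taper. The stated analysis protocol
specifies Hamming only for the STFT; the Welch/coherence taper is not
stated, and Hamming is used throughout for internal consistency.

* `welchPsd()` — averaged tapered periodograms, one-sided density scaled so
  the integral over frequency approximates the series variance (verified to
  5% on white noise, 1% on sines). No detrending: a DC offset shows up at
  0 Hz, as the constant-series test documents (with a Hamming taper a small
  fraction of DC power leaks into the first neighbouring bins).
* `msCoherence()` — $|P_{xy}|^2/(P_{xx}P_{yy})$ from segment-summed cross-
  and auto-spectra; at least two segments are required (one segment gives
  identically 1), partial final segments are discarded, zero-power bins are
  defined as 0. For $K$ independent segments the chance level is
  $\approx 1/K$, which the tests verify by simulation.
* `stftSpectrogram()` — frame-by-frame tapered spectra, default 32768
  points (0.366-Hz bins at 12 kHz). The hop is not specified by the source
  protocol; 50% (16384 samples) is the default and is configurable.
* `bandPower()` integrates half-open bins $[lo, hi)$ so adjacent bands
  (theta 4–12, beta 12–30, gamma 30–80 Hz) never double-count;
  `narrowbandPower()` uses a closed interval $f_0 \pm$ half-bandwidth,
  matching the $f_m \pm 1.0$ Hz and $53.71 \pm 0.6$ Hz conventions.

## Analysis pipelines

**Transient.** Epochs span (−20, 0] and (0, +20] ms around each onset with
the onset sample at $t=0$; the baseline is the mean over $t \le 0$ and the
peak search runs over $t > 0$, so the onset sample itself is excluded from
the peak. The peak is the maximum *absolute* deviation from baseline by
default, since evoked polarity depends on electrode referencing; a polarity
flag restricts the search. Latency adds a signed propagation correction,
default +2 ms: sound travels 70 cm in ~2.04 ms, and the correction is kept
additive with its documented sign following the source protocol's wording
(a physically minded user can set `delay_correction_ms = -2.04` to
reference ear-arrival time instead; the package does not guess intent).
Onsets lacking full context are dropped with a warning — in particular a
burst at $t = 0$ s.

**ASSR.** Within each AM segment, `selectMinVarianceWindow()` elects the
10-s candidate window (stride 0.5 s by default, per-sample stride available)
with minimum sample variance — an automatic guard against movement
artifacts; ties break to the earliest window. The elected stride is a free
choice (the protocol names none); 0.5 s keeps election O(segment) while the
tests show its elected variance is within 1% of the exhaustive scan on
smooth signals, and exactly equal on the oracle comparisons. Narrowband
power and msc at $f_m$ (bin-averaged over $f_m \pm$ half-bandwidth,
mirroring the power convention) are computed on that window. The coherence
reference is the *recorded* sync channel by default; `ideal_reference =
TRUE` regenerates a unit sine at $f_m$ instead.

**CS-normalized power.** Per CS presentation: mean STFT band power across
frames inside the 30-s CS divided by the same quantity over the 30 s
immediately before it; the session value is the arithmetic mean over the
five presentations (the aggregation rule is not stated in the source
protocol; the mean is this package's documented choice). Because it is a
ratio, the statistic is invariant to global amplitude rescaling, which the
tests assert.

**Baseline profile.** Total power is integrated from 1 Hz (the hardware
high-pass floor of the emulated acquisition chain) to Nyquist, plus the
three canonical band powers, on the elected 10-s window of the silent
period.

**Freezing.** An epoch (5 s) freezes iff it contains a contiguous immobile
run of at least 3 s, inclusive at the boundary; a bout spanning an epoch
boundary counts in any epoch where its within-epoch portion reaches 3 s
(the rule is silent on spanning bouts; this reading is local and
monotone). Whole-period scoring counts time inside bouts ≥ 3 s. The 3-s
minimum is reused for the contextual task, where no bout criterion is
stated, and is configurable.

## The synthetic generator and what passing tests mean

No quantitative signal model is published for these recordings, so every
generator default is a preset chosen once as a realistic midbrain-LFP
scale, not a literature claim:

| parameter | default | meaning |
|---|---|---|
| `noise_sigma_uV` | 20 | SD of the 1/f background |
| `spectral_exponent` | 1 | PSD ∝ 1/f above 1 Hz |
| `band_oscillations` | 6 Hz/5 µV, 40 Hz/2 µV | ongoing theta/gamma |
| `entrain_amp_uV` | 10 | ASSR component amplitude |
| `phase_jitter_sd_rad` | 0.1 | per-cycle phase random-walk SD |
| `evoked_latency_ms` / `evoked_amp_uV` | 5 / 80 | kernel peak |
| `evoked_width_ms` | 2 | Gaussian kernel SD |
| `trial_latency_jitter_ms` | 0.2 | per-trial latency SD |

Design notes:

* **Phase jitter as a cumulative random walk** (innovation SD per cycle)
  rather than i.i.d. phase noise: coherence then degrades smoothly with
  jitter while the instantaneous frequency stays near $f_m$, mimicking
  imperfect entrainment. With 1-s coherence segments the within-segment
  phase wander is $\sigma\sqrt{f_m}$; beyond ~0.3 rad/cycle the msc
  saturates at the $1/K$ chance floor, so monotonicity across a jitter
  ladder is asserted strictly where resolvable and by a pooled rank test
  (plus chance-level ties) across the full ladder.
* **Ongoing band oscillations drift in phase** (0.2 rad/cycle random walk):
  a mathematically pure sine at 6 Hz would be exactly commensurate with the
  500-ms burst period and survive trial averaging as a spurious evoked
  component, which real, non-stimulus-locked theta does not.
* **Colored noise via FFT shaping** of white noise (exact target PSD,
  O(n log n)); the spectrum is flat below 1 Hz and the DC bin is zeroed.
* **Evoked kernel** is a Gaussian-envelope monophasic peak (positive by
  default, configurable); the waveform family is a modelling choice, not a
  measured shape.
* `generateSession()` seeds the RNG from `cfg$seed`, making sessions
  bit-identical under a fixed seed.

Passing the recovery tests shows the pipelines are *self-consistent* against
this generator — latency within ±0.5 ms and amplitude within ±10% at SNR ≥ 5
with 120 trials, narrowband power quadratic in entrainment amplitude
(R² ≥ 0.95 on a 5-point ladder clear of the narrowband noise floor), and
chance-level nulls with zero entrainment. It does not certify performance on
real data, whose artifacts (electrode drift, chewing/movement broadband
transients, line noise, nonstationary background) are richer than the
generator's low-frequency bursts.

## Problem sizes and numerical choices in the shipped tests

Unit and property tests run the full 120-burst/60-s transient protocol and
the five-CS conditioning protocol once each at the native 10/12-kHz rates;
Monte-Carlo ladders (jitter, amplitude, null calibration) use 10-s AM
segments at 12 kHz and 20 replicate seeds, and window-election oracle scans
use 25-s segments at 200–500 Hz — sizes chosen to exercise every code path
with comfortable statistical resolution while the whole suite stays fast.
Tolerances follow each statistic's sampling error at those sizes (e.g. a
10-s window gives K = 10 one-second Welch segments, hence ~8% SD per
8-bin band power; band-ratio checks therefore average five sessions).

## Known limitations

* The event detector assumes a reasonably clean sync channel; it recovers
  frequency robustly under additive noise but boundary times only to within
  the envelope-threshold crossing (~1/(12 f_m) for a sine segment).
* Single-trial latency estimation and multi-peak component labelling are
  out of scope; the transient pipeline characterizes the grand average.
* Group-level inference (ANOVA, post hoc) is deliberately not included;
  `sessionReport()` emits tidy tables for external statistics tools.
* PSD units follow the input's units squared per Hz; the package performs
  no µV/mV calibration, and sound level (dB SPL) is carried as metadata
  only.
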