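---
title: "Methods: ECG cancellation and breath-wise EMGdi amplitude analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ECG cancellation and breath-wise EMGdi amplitude analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices, numerical
decisions and known limitations of the package. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## 1. The estimand

Diaphragm activation is reported per minute of a test as
EMGdi/EMGdiMax%: the mean, over the usable tidal breaths of the minute,
of the per-breath mean inspiratory RMS amplitude, divided by EMGdiMax —
the largest activation recorded during inspiratory-capacity (IC)
maneuvers. The per-breath statistic is a *mean over the full inspiration*
(an integral measure of drive), not a peak.

## 2. Signal chain (semi-automated path)

1. **Export/resample** to 1000 Hz (`resample_recording()`): zero-phase
   8th-order-equivalent Butterworth anti-alias low-pass at
   0.45 × target rate, then decimation.
2. **ECG cancellation** (`lms_clean()`): plain LMS adaptive FIR,
   70 taps, step size 0.01, weights initialised at zero, zero-padded
   reference history (output stays aligned with flow), no
   re-initialisation at breath boundaries. The filter estimates the
   quasi-static linear coupling path from the ECG reference electrode
   into each EMG channel; heart-rate drift therefore does not degrade
   removal.
3. **High-pass** at 20 Hz (`highpass()`): zero-phase 4th-order
   Butterworth, the conventional motion-artifact filter. *Order of
   operations*: the canceller runs on the raw signals and the high-pass
   afterwards. Running the high-pass first would strip most sub-20 Hz
   QRS energy from both reference and target, leaving the canceller
   less correlation to exploit while changing nothing it could not
   remove itself; running it after also removes any sub-20 Hz residue of
   the cancellation. (Whether the original acquisition chain filtered
   before or after adapting is not documented; this is our choice.)
4. **RMS envelope** (`rms_envelope()`): centred moving-window RMS,
   default 50 ms. The window is a compromise: long enough to suppress
   carrier-level fluctuation, short enough to preserve the intra-breath
   envelope shape that drives the manual-rater mechanisms (Section 6).
   Windows are truncated at record edges — no fabricated samples can
   enter a breath mean.
5. **Breath segmentation** (`detect_breaths()`): inspiratory onset at a
   negative-going zero crossing of flow (negative flow = inspiration),
   inspiratory end at the next positive-going crossing, expiration to
   the following negative-going crossing. A crossing counts only if
   |flow| subsequently dwells beyond 0.05 L/s for ≥ 50 ms (hysteresis
   against chatter; the behaviour of acquisition-software scripts at
   noise-level crossings is undocumented, so this is our
   operationalisation). Breaths shorter than 0.3 s of inspiration
   (conservatively below the physiological range — end-exercise Ti is
   ~0.8 ± 0.2 s) or with peak inspiratory flow < 0.05 L/s are dropped.
6. **IC detection**: by `ic_maneuver` event markers when present,
   otherwise by inspired volume > 1.5 × running-median tidal volume.
7. **Exclusions** (`exclude_outlier_breaths()`): the visual rule
   "short sighs or visible noise" is operationalised as inspiratory
   duration below threshold, or mean inspiratory envelope more than 4
   robust z-scores (median/MAD) from the minute median.
8. **Summaries**: reporting channel = channel with the largest average
   IC signal (ties to the lowest index); minutes are 1-based half-open
   `[60(k−1), 60k)` intervals from the `rest_start` marker (or t0);
   breaths belong to the minute of their inspiratory onset; IC breaths
   are excluded from tidal summaries; minutes without usable breaths are
   reported missing, never zero.

## 3. LMS design decisions

**Plain vs normalised update.** The published operating point is plain
LMS with μ = 0.01 and L = 70. We keep that default and offer the
power-normalised update (`normalized = TRUE`) as an option.

**Reference scaling (a deliberate deviation).** Standardising the
reference to unit variance looks attractive (it makes μ portable across
recordings) but is *empirically unstable* here: an ECG is impulsive, and
during a QRS burst the instantaneous 70-tap reference energy ‖x(n)‖²
reaches several hundred — far beyond the mean-power stability heuristic
μ < 2/(L·σ²). Plain LMS with μ = 0.01 on a unit-variance ECG reference
genuinely diverges (a test demonstrates this; the divergence guard
aborts with a diagnostic). On raw physiological amplitudes (reference
R-peak a fraction of a volt) the same μ is slow, stable and low-noise —
which is also the regime in which gradient noise injected into the
cleaned EMG (excess MSE ∝ μ·L·σx²·EMG power) stays far below the
artifact power being removed. Default: `standardize_ref = FALSE`.

**Guard.** ‖w‖∞ > 10⁴ aborts with a message naming the step size.

**Exact additivity.** `cleaned + residual_estimate` equals the input to
machine precision at every sample, by construction.

## 4. EMGdiMax statistic (a deliberate deviation)

"Largest RMS amplitude during any IC maneuver" can be read as the peak
of the running RMS trace. The maximum of a 50 ms windowed RMS estimate
over several one-second IC inspirations and several maneuvers carries a
positive stochastic bias of several percent (max of ~20 weakly
correlated chi-distributed window estimates per IC), which deflates
*every* normalised value and is large enough to defeat a ±5 pp
recovery requirement on its own. Since the per-breath numerator is a
mean, the default denominator is the matching mean statistic: the
largest, over IC inspirations and channels, of the per-IC *mean*
inspiratory RMS (`emgdimax_stat = "mean"`). The literal peak statistic
remains available (`"peak"`).

## 5. The synthetic world

`simulate_recording()` builds, per channel c:
`emg_c = gain_c · A(t) · carrier_c(t) + (coupling_c ⋆ ecg)(t) + noise`.

* **Carrier**: unit-variance Gaussian noise band-limited to 20–250 Hz
  (FFT masking), independent per channel.
* **Activation envelope** `A(t)`: zero in expiration; within an
  inspiration a raised-cosine family — `flat` (15 % cosine ramps, the
  trained pattern), `late_peak` (peak at u = 0.8, the untrained
  pattern of rising activation toward end-inspiration; default) and
  `early_peak`. **Calibration**: tidal envelopes are scaled so that the
  ratio of mean inspiratory amplitude (tidal) to mean inspiratory
  amplitude (IC) equals the configured per-minute activation exactly;
  IC maneuvers have activation 1. The generator's
  `true_activation_per_minute` is therefore the exact value of the
  estimand of Section 1.
* **Scale anchors**: maximal IC amplitude 0.15 V on a gain-1 channel
  (typical reported maximal activation ~0.146 V); channel gains
  (1, 0.7, 0.3, 0.7, 1) — outer electrode pairs largest, middle
  smallest, the signature of correct catheter position.
* **ECG**: Gaussian-lobe Q/R/S complex (R lobe σ = 8 ms — sharp enough
  that substantial QRS energy lies above 20 Hz, as in real recordings;
  a smoother first draft was rejected because the 20 Hz high-pass alone
  removed it, contradicting the band-overlap premise), P and T waves at
  15 % and 25 % of R, reference R-peak 0.5 V, heart rate ramping
  80 → 124 bpm with 10 ms beat jitter.
* **Coupling**: per-channel delayed (2–6 ms), smoothed, scaled impulses;
  artifact peaks ~0.09–0.13 V — larger than resting EMG (~0.02–0.03 V
  RMS), smaller than peak end-exercise EMG (~0.15–0.18 V), the regime
  in which manual analysis is hard. No amplitude link between reference
  and artifact is published; these are our choices, frozen before any
  acceptance measurement.
* **Respiration**: breath rate 22 → 32 /min, Ti fraction 0.40, peak
  tidal flow 0.5 → 1.1 L/s, ~4 heartbeats per breath; IC maneuvers at
  scheduled times with 2.8× tidal flow amplitude and 0.9× Ti
  (inspired volume 2.52× tidal — satisfying both the "2–3× amplitude"
  description and the 2.5× volume separation used by volume-mode IC
  detection).
* **Noise**: 1 mV white instrumentation noise (SNR ~30 against resting
  EMG).
* **Seeds**: one master seed expands into fixed per-component
  substreams (ECG jitter, each carrier, each noise channel, breath
  timing), so changing one component never perturbs the others.

What the generator does **not** emulate: arrhythmia, electrode-motion
transients, esophageal peristalsis, tonic expiratory EMG, amplitude
nonstationarity of the ECG, within-minute activation drift. A green
test therefore establishes algorithmic correctness under the stated
statistical structure, not clinical performance.

## 6. Manual-method emulation

QRS detection: |ecg| maxima above 0.5 × a rolling 95th percentile with
a 250 ms refractory period. Blanking 60 ms before to 100 ms after each
R peak covers the QRS and early T onset; P/T energy outside the blank
deliberately remains selectable, mirroring assessors who had no
instructions for P/T/U interference. Within each inspiration the
maximal blank-free sub-intervals of at least 50 ms (cursor realism) are
enumerated; the two documented strategies pick the interval with the
largest mean (`highest`, ties to the *latest* interval, matching the
end-inspiratory tendency) or the longest interval (`widest`, ties to
the *earliest*). Per minute, the last five usable tidal breaths are
averaged; EMGdiMax uses the same machinery on IC breaths (whose short
Ti typically leaves a single interval, which is why manual EMGdiMax
agrees between strategies while tidal values do not). With `late_peak`
envelopes the highest strategy lands on end-inspiratory intervals and
exceeds the widest strategy; flattening the envelope shrinks the gap —
the package reproduces both directions and tests them with paired sign
tests.

## 7. Agreement statistics

ICC: absolute-agreement, average-measures coefficient from the two-way
mean-squares decomposition, `(MSR − MSE) / (MSR + (MSC − MSE)/n)`; the
"mixed vs random" label changes interpretation, not the estimate. CI:
F-based interval for the single-measures coefficient with a
Satterthwaite denominator df, stepped up by Spearman–Brown. Bland–Altman
limits are bias ± 1.96 × SD of the paired differences. The
method × time interaction is the two-within-factor repeated-measures F
(`MS[m×t] / MS[m×t×subject]`), no sphericity correction by default
(Greenhouse–Geisser optional). Cohort analyses pool subject-minutes as
single points, replicating the source methodology; this ignores
within-subject correlation and is a documented caveat, not a
recommendation.

## 8. Numerical notes

* Butterworth filters are designed from the analog prototype via the
  bilinear transform with prewarping; coefficients match SciPy's to
  machine precision, and tests compare realised gains against the
  closed-form prewarped magnitude response.
* Zero-phase filtering uses odd-reflection padding plus steady-state
  initial conditions (the `lfilter_zi` construction); without the
  steady-state state a constant input leaks a step transient.
* Sample intervals are half-open everywhere; sample *i* covers
  `[(i−1)/fs, i/fs)`; minute boundaries belong to the later minute.
* Marker times are stored in seconds and survive resampling exactly.
* The delimited-text format stores 17 significant digits; write → read
  round trips are bit-exact.

## 9. Findings the validation study surfaced

* **Ratio self-correction**: at the EMGdi/EMGdiMax% level the uncleaned
  path can look nearly as accurate as the cleaned path, because ECG
  contamination inflates tidal numerator and IC denominator roughly
  proportionally. Cleaning unambiguously improves the per-breath
  amplitude in volts (tested); the normalised ratio is a poor probe of
  contamination. Consequently, studies reporting only normalised values
  may understate the benefit of artifact removal for absolute
  amplitudes.
* **Stability folklore**: the white-input bound μ < 2/(L·power) does
  not certify stability for impulsive references (Section 3).

## 10. Limitations

Single static coupling path per channel (no electrode movement); the
manual emulator models two idealised deterministic strategies, not
human perceptual noise; EDF ingestion is not implemented (no reader
available in the supported dependency set) — the delimited-text dialect
is the interchange format; agreement CIs assume exchangeable pooled
pairs.
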