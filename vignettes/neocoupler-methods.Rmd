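---
title: "Methods: detecting and quantifying discontinuous neonatal oscillations and their cross-region coupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and quantifying discontinuous neonatal oscillations and their cross-region coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, estimators and numerical choices in
`neocoupler`, what the synthetic-data generator does and does not emulate,
and the design decisions taken where the methodology was genuinely open.

## The data model

A session consists of one multi-channel LFP block per region (µV, common
sampling rate, strictly monotonic channel depths with larger = deeper),
sorted spike times per unit, and optionally a pulse-train stimulation
protocol. The neonatal regime the package targets is *discontinuous*
activity: theta-band (4–12 Hz) bursts of a few seconds separated by
silence, large sharp waves (SPWs) that reverse polarity across the CA1
pyramidal layer with fast ripple oscillations superimposed, and a sparse
(<1 Hz) unit population whose firing is organized by these events.

## Signal conditioning

All filtering is zero-phase Butterworth (forward–backward, order 3 unless
stated, so the effective magnitude response is 6th order). Coefficients
are designed by bilinear transform of the analog prototype and agree with
standard references to ~1e-12. Two numerical details matter:

* each pass subtracts the appropriate steady-state offset before
  filtering, so constants map exactly to the filter's DC response (no
  start-up transients on DC or near-DC segments);
* for signals longer than 2^18 samples the forward–backward pass is
  applied in the frequency domain as the squared magnitude response
  |H(f)|², evaluated stably as a product over pole/zero factors. With the
  same odd-reflection padding the two paths agree to ~1e-4 relative even
  for the high-Q 1 Hz band edge, and the FFT path is ~4x faster on
  hour-long signals.

Decimation applies a 3rd-order anti-aliasing low-pass at 0.4x the target
rate and keeps every k-th sample; only integer factors are supported (the
hardware-relevant step, 32 kHz to 3.2 kHz, is integer).

## Oscillatory event detection

The detector follows the variance-adaptive RMS scheme: the 1–100 Hz
band-passed channel is reduced to a centered 200-ms sliding RMS, a
histogram of RMS values (Freedman–Diaconis bins) is built from 0 to the
histogram's global maximum, a Gaussian is fitted to that restricted range
(nonlinear least squares; empirical mean/SD fallback with a warning), and
the detection threshold is μ + kσ with k = 3 by default.

Two design decisions depart from a literal supra-threshold reading and
are deliberate:

* **Boundaries at return-to-baseline.** The threshold sits 3σ above the
  background mode, so threshold-crossing boundaries clip the smooth
  onset/offset of an enveloped burst and bias duration low by >20%. Each
  supra-threshold core is therefore extended outward to the RMS trace's
  first return to the fitted background mean μ. The 200-ms merge rule is
  applied to cores, and the >1 s minimum-duration rule is applied to the
  *merged core span*: a brief noise excursion never survives the duration
  rule by virtue of its baseline extension. On pure 1/f background the
  false-positive rate is below 0.5 events/min and in practice ~0.
* **Amplitude from the theta envelope.** The event amplitude is the
  Hilbert envelope of the dominant 4–12 Hz component, smoothed over two
  theta cycles, averaged over a 1-s window centred on the envelope
  argmax. A max-of-|signal| statistic is biased upward 15–25% at
  realistic SNR by the extreme-value statistics of noise riding on the
  carrier peaks; the windowed-envelope estimator recovers injected
  envelope peaks to within ~2%. The raw max |4–100 Hz| deflection is kept
  per event as `amplitude_raw`.

In sessions containing SPWs, detection runs on the pyramidal-layer
channel, where SPWs cancel by symmetry — the same reason the original
recordings were analyzed at the stratum-pyramidale site. Elsewhere the
SPW transients themselves would be scored as oscillations and inflate
occurrence by ~20%.

## Sharp-wave detection

SPWs are detected on the subtracted trace d(t) = (channel 100 µm above
str. pyr.) − (channel 100 µm below), both filtered 1–300 Hz; nearest
depths are used (with a warning) if no site sits at exactly ±100 µm.
Peaks with |d| > 5 SD(d), separated by a 100-ms refractory gap, are
returned with polarity. Amplitude is |d| averaged over ±5 ms around the
peak — again trading the single-sample max (biased ~+10% at i/vHP-like
amplitude-to-noise) for a near-unbiased local mean. The pyramidal channel
can be recovered automatically (`select_pyr_channel`) as the interior
channel whose flanking channels show the most anti-correlated
event-triggered deflections.

## Spectral estimation

Welch PSDs average one-sided Hann-tapered periodograms over
non-overlapping windows "glued" from the supplied segments; window
lengths follow the analysis (1 s for oscillatory periods, 300 ms for SPW
pre/post, 100 ms for ripples, 3 s for light-evoked epochs). Integrated
PSD matches signal variance (Parseval) within 10% in the property tests.
Relative power is the pointwise ratio of within-event to non-oscillatory
baseline spectra; zero-power baseline bins become NA and are excluded
from band means. Time–frequency maps use an L1-normalized complex Morlet
wavelet with 6 cycles (standard resolution trade-off; configurable).

For stimulation epochs the pre- and during-train spectra are averaged
across trains *before* the ratio is formed: with a single 3-s window per
epoch the per-train ratio is F(2,2)-distributed and has no finite mean,
so ratio-then-average does not converge.

## Coupling

**Imaginary coherence** uses the squared form
C_XY(f) = Im(P_XY(f))²/(P_XX(f)·P_YY(f)) with cross/auto spectra averaged
over the same Hann windows as the PSD. Identical signals give exactly 0
(volume conduction is invisible to the imaginary part); an unsquared
|Im(coherency)| variant is available via `squared = FALSE`.

**gPDC** is computed from a VAR fit:
Ā(f) = I − Σ_r A_r e^(−i2πfr/fs) and
π_ij(f) = (|Ā_ij(f)|/σ_i) / sqrt(Σ_k |Ā_kj(f)|²/σ_k²), which satisfies
the column normalization Σ_i π_ij(f)² = 1 to machine precision (asserted
at 1e-10 in the tests). The pipeline restricts analysis to detected
oscillatory epochs, denoises each segment at the native rate (Daubechies-4
periodic DWT, 5 levels, soft universal threshold — denoising *before*
decimation, where the wavelet basis compresses the oscillation well),
decimates to 200 Hz so theta/beta dynamics dominate the fit, selects the
VAR order by BIC up to 20, verifies stability (companion spectral radius
< 1), and averages band means across epochs. Directionality recovery and
a centred null are demonstrated in the acceptance suite with both regions
carrying their own, uncorrelated oscillations — a pure-noise destination
region makes the null asymmetric because the fitted cross-terms inherit
the source's oscillatory structure.

## Unit analyses

Spike phases are the analytic (Hilbert) phase of the band-filtered LFP at
the nearest sample, with 0 rad at the LFP peak and phases in (−π, π].
Phase locking is tested per unit with the Rayleigh statistic R (mean
resultant length) and the small-sample-corrected approximation
p = exp(sqrt(1 + 4n + 4(n² − (nR)²)) − (1 + 2n)); units with fewer than
10 spikes are flagged untested. The approximation is validated against a
simulation null in the tests (type-I error 5% ± 2% at α = 0.05;
agreement within 20% relative on p in [0.001, 0.2]). The lock criterion
is raw p < 0.05 (no multiple-testing correction, matching how such counts
are conventionally reported); PSTHs default to ±3 s windows with 100-ms
bins. Light-evoked spiking uses the 15-ms post-onset window: efficacy is
the per-pulse probability of at least one spike in that window, and for
homogeneous Poisson trains matches 1 − e^(−0.015r) within 2%.

## The synthetic-data generator

Defaults describe an i/vHP-like session: bursts at 8.1/min, duration
3.5 ± 0.1 s, envelope peak 110.6 µV, an 8 Hz carrier plus a 20% 12–40 Hz
component; SPWs at 8.6/min and 223.8 µV on the subtracted trace
(difference-of-Gaussians biphasic waveform, ~15 ms core; 150 Hz ripple at
20% amplitude on the pyramidal channel); 1/f background at 20 µV RMS;
units at 0.45 Hz with 20% theta-locked (von Mises κ = 2), half
SPW-modulated (×3 in ±50 ms), and configurable light responses (<10 ms
latency). A dHP-like condition uses 5.2/min, 4.3 s, 92.9 µV, SPWs 6.6/min
at 712.8 µV. Directed coupling adds the theta-filtered hippocampal signal
to the prelimbic channels with configurable gain and 15-ms lag.

Two generator choices deserve emphasis:

* **Event placement is a hard-core renewal process** (exponential free
  gaps plus a 1-s silence margin; 0.5 s refractory for SPWs), calibrated
  so the *realized* event rate equals the configured rate. Naive Poisson
  placement with overlap rejection — the obvious alternative — saturates
  ~5% below the configured rate at realistic densities and ~7% for SPWs
  with refractory thinning, which would poison every rate-recovery check.
* **Burst envelope is a Tukey (r = 0.25) taper by default** ("hann" is
  available). A fully tapered Hann bell keeps ~15% of the burst below the
  noise floor, so no threshold detector can recover the support duration
  within 5%; the Tukey envelope keeps smooth, spindle-like on/offsets
  while making the burst's extent operationally well defined. Burst
  amplitude semantics: the theta carrier's envelope peak equals the
  configured amplitude; the beta component rides on top.

What the generator does *not* emulate: non-stationary background (drifts,
movement artifacts), electrode-specific noise, spatial amplitude
gradients within a region (bursts are injected coherently on all channels
of a region), spike sorting errors, and any biophysics. A green test
therefore establishes estimator correctness against the stated
statistical structure, not robustness to real-world artifacts.

## Acceptance scale and determinism

`scripts/acceptance.R` regenerates every target from scratch: 10 sessions
x 60 min for burst occurrence/duration/amplitude (per region
configuration), 10 x 30 min for SPWs, and 50 Poisson units x 15 min for
firing rate. Sessions are generated at 1 kHz rather than the hardware
3.2 kHz — every analysis band involved is ≤ 300 Hz — which keeps the
script around 10 minutes on one CPU. All randomness derives from the
`--seed` argument; the same seed reproduces the report bit-for-bit, and
across seeds the reported values move only by the expected sampling
noise (<2% for rates, <1% for durations/amplitudes).

## Known limitations

* Rational-ratio resampling is not implemented (integer decimation only).
* gPDC is reported without surrogate significance bands; the package
  demonstrates directionality by ground-truth recovery, not by
  inferential testing.
* The session container is a plain-text directory (CSV + JSON), chosen
  for portability and diff-ability; hour-long multi-channel sessions are
  better regenerated from config than stored.
* Group-level inferential statistics (t-tests, ANOVA, Mann–Whitney) are
  out of scope; reports carry descriptive mean ± SEM only.
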