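---
title: "Methods: simulated oddball flight EEG and the workload classification pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated oddball flight EEG and the workload classification pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
conventions behind `flightload`, in the spirit of a methods section: what
is computed, under which assumptions, and where the design was genuinely
open.

## The problem

A passive BCI for workload monitoring must decide, from short stretches of
EEG, whether the user is in a low-load (monitoring) or high-load (actively
flying) state. Two feature families compete: stimulus-locked ERP amplitudes
around an auditory oddball probe (the P300 shrinks when the primary task
absorbs attention), and oscillatory band power (parietal alpha and
occipital theta drop as load and arousal rise). The package implements both
single-trial pipelines plus the group-level ERP statistics, and — because
flight EEG of this kind is not publicly available — a generator that
produces data with exactly the statistical structure those analyses assume.

## The synthetic-data generator

`sim_config()` fixes the study layout: 6 channels (Fz, Cz, Pz, Oz, P3, P4)
at 500 Hz, ~500 s per load condition, a session total of 320 oddball
stimuli of which 25 % are targets (exact shuffled split, so a session is
always 80/240), inter-trial interval 2000 ms with a ±1000 ms uniform
jitter, and a 30-s artifact-free calibration lead-in per recording.

The signal model has three additive parts:

* **Background**: four diffuse 1/f sources (amplitude-spectrum exponent 1,
  flattened below 1 Hz to bound drift) mixed into the montage through a
  Gaussian spatial falloff, plus 20 % independent per-channel sensor noise,
  scaled to 10 µV RMS per channel. The mixing mimics volume conduction:
  neighbouring channels are strongly correlated, which the QC
  channel-correlation criterion (0.85) presumes. The 10 µV level was chosen
  so that a single-trial P300 has SNR < 1, the regime in which ERP sample
  features are expected to fail while band-power features survive.
* **Oscillators**: per band (delta/theta/alpha/beta at 2.5/6/10/14 Hz) a
  fixed-amplitude sinusoid whose phase is redrawn uniformly every 1-s block
  and shared across channels. Amplitude-fixed sinusoids were preferred over
  AR oscillators because the induced band power is exactly `a²/2`, which
  makes every downstream power computation testable against a closed form.
  The default `band_power_map` plants the two load effects — alpha at Pz
  4 µV (low) vs 2 µV (high), theta at Oz 3 µV vs 1.5 µV — on top of
  load-independent resting amplitudes (delta/theta 1.5, alpha 2,
  beta 1 µV). The 2:1 amplitude ratios (4:1 in power) are deliberate,
  clearly recoverable effects: the generator validates the pipeline, it is
  not calibrated to the flight study (whose single-trial SNR is unknown).
* **P300**: a Gaussian-windowed positivity added at each target onset,
  peak latency 0.45 s (inside the conventional 0.35–0.6 s analysis
  window), width 0.06 s, truncated at ±3σ. The topography is
  parietal-dominant (Pz 1.0, P3/P4 0.8, Oz 0.6, Cz 0.5, Fz 0.3), scaled by
  the per-condition amplitude (defaults 8 µV low, 4 µV high). Only a shape
  family is defensible here — no published waveform is being fit — and a
  Gaussian makes peak location, amplitude and integral all analytic.

Artifacts are Poisson-injected outside the calibration lead-in (defaults: 6
blinks and 2 bursts per minute): blinks are biphasic low-frequency pulses
with a frontal topography peaking at 150 µV at Fz; bursts are broadband
noise segments of 0.3–0.6 s on a random channel subset (default 100 µV
RMS). Every injected interval is logged, so artifact-removal tests have
exact ground truth, and the generator also returns the pre-injection
signal.

What the generator does **not** emulate: a realistic head-model forward
projection, non-stationary spectra, heteroscedastic artifact families
(electrode pops, sweat drifts), acoustic properties of the stimuli, or
realistic inter-subject variability. Passing tests therefore demonstrate
that the algorithms recover planted structure under controlled conditions,
not that the real-flight accuracies would be reproduced.

## Preprocessing conventions

* **FIR filters** are Hamming-windowed sinc designs of even order (default
  250, i.e. 251 symmetric taps) so the group delay of order/2 samples is
  integral and can be compensated exactly. Band-passes are built by the
  Octave-compatible difference-of-lowpasses construction with the passband
  centre scaled to unit gain; at order 250 and fs 500 this puts the 8–12 Hz
  response at 10 Hz within 1 ± 0.06 while a product of half-order high- and
  low-pass kernels would not reach unit passband gain at these transition
  widths. High-passes are built by spectral inversion of a DC-normalized
  low-pass, which nulls DC exactly at any order — relevant for the 0.5 Hz
  drift filter. Edges are reflection-padded (the calibration segment must
  not carry onset transients).
* **Epochs** use the half-open convention `[tmin, tmax)`: −0.2 to 1.0 s at
  500 Hz is exactly 600 samples, 0–0.6 s at 50 Hz exactly 30. Events whose
  window leaves the recording are dropped and counted, not errors.
* **Downsampling** to 50 Hz is pure decimation (keep-first phase), valid
  because the pipeline's 1–15 Hz filter has already band-limited the
  signal.

## Artifact Subspace Reconstruction

Calibration estimates the clean-EEG covariance from 0.5-s windows with 50 %
overlap — arithmetic mean for the classic variant, the affine-invariant
Riemannian (Karcher) mean for rASR (fixed-point iteration, tolerance 1e-6,
max 50 iterations, warm-started at the arithmetic mean). The mixing matrix
is the principal square root of that covariance; per eigencomponent the
detection threshold is `mean + k·SD` of windowed component RMS, with the
lenient burst criterion `k = 70` as the default.

Two implementation points matter:

* **Detection statistics are computed on spectrally pre-emphasized data**
  (first-difference high-pass, `y[t] = x[t] − 0.95·x[t−1]`). On a 1/f
  background the windowed RMS distribution is otherwise so wide (a 0.5-s
  window holds few low-frequency cycles) that `mean + 70·SD` never fires;
  pre-emphasis flattens the spectrum, the RMS statistics tighten, and
  broadband bursts stand out by orders of magnitude while
  calibration-level oscillations stay far below threshold. Reference ASR
  implementations apply an analogous spectral-shaping filter before their
  statistics. Reconstruction is applied to the raw (unshaped) signal.
* **Reconstruction is window-granular**: flagged eigencomponents of a
  window are replaced by their projection through the calibration mixing
  (clean-subspace remixing, Moore–Penrose inverse of the masked projected
  mixing), and windows are blended by a raised-cosine overlap-add.
  Unflagged windows pass through bit-identically, so ASR is exactly the
  identity on its own calibration data at `k = 70`. Because flagging is
  per window, correction can spill up to one window length beyond a burst;
  distortion guarantees are therefore stated outside the corrected
  windows, not outside the artifact sample interval itself.

A consequence of `k = 70` with pre-emphasized statistics is that only
high-amplitude broadband events are corrected; low-frequency blinks pass
through largely untouched. That matches the intent of a deliberately
lenient burst criterion.

The QC criteria mirror common clean-raw settings: channels with ≥5 s
constant runs are removed; per 1-s window a channel is flagged when its
correlation with a leave-one-out least-squares prediction from the other
five channels falls below 0.85 (full RANSAC subsampling is pointless with
six channels) or when its line-noise score (SD of the high-frequency
residual over SD of the smoothed signal) is more than 4 robust SDs above
the recording-wide distribution; a window is dropped when more than 10 % of
channels are flagged.

## Features and classification

The stimulus-locked pipeline cuts −1 to +1 s epochs, applies per-epoch rASR
with the model calibrated once on the first 30 s (calibration data are
never classified), then branches: the ERP branch (1–15 Hz, baseline
−0.2–0 s, 0–0.6 s window, 50 Hz) concatenates samples channel-major into
180 features; the frequency branch band-passes each of delta (1–4), theta
(4–8), alpha (8–12) and low beta (12–16) Hz, applies two pairs of CSP
filters per band ("two pairs" = 4 filters, forced by the 4 × 4 = 16 feature
arithmetic), squares, averages over 0–0.6 s and takes the natural log. The
continuous pipeline does the same over non-overlapping 2-s windows cut
after the calibration lead-in. Because the average of the squared filtered
signal equals the quadratic form `wᵀCw` of the window covariance, per-epoch
band covariances are the sufficient statistics for both CSP fitting and the
features, which keeps cross-validation with per-fold refits cheap.

CSP solves `Σ_low w = λ(Σ_low + Σ_high) w` after whitening by the
composite covariance; class covariances are averaged per-epoch covariances
shrunk toward a scaled identity with an intensity driven by the dispersion
of the epoch covariances around their mean (a Ledoit–Wolf-style estimator
at the matrix level — the per-epoch sample paths are no longer available at
that point). Filters are ordered extremes-first and normalized to
`wᵀ(Σ_low + Σ_high)w = 1`. The sLDA uses Ledoit–Wolf analytic shrinkage of
the pooled within-class covariance, clipped to [0, 1], with full shrinkage
when the empirical dispersion around the scaled-identity target is
numerically zero; the bias places the boundary at the midpoint of the
projected class means (equal priors — the load conditions are balanced by
design even though the oddball itself is 25/75). The positive class is
high load, which defines sensitivity.

mRMR discretizes each feature into 8 equal-frequency bins (ties broken by
first occurrence) and greedily maximizes `I(f; y) − mean_s I(f; s)`; ties
go to the lowest column index, making selection deterministic. The fused
pipeline selects 20 features per training fold.

Cross-validation shuffles epochs once with the run seed and deals them
round-robin within class, so fold proportions match within one epoch. All
data-dependent fitting — CSP, mRMR, shrinkage, sLDA — happens on training
folds only.

## Interpretation and group statistics

Linear decoders are interpreted through the forward-model (activation
pattern) transform `Σ·w`, with `Σ` the training-fold feature covariance at
the sLDA level and the training composite channel covariance at the CSP
level (training data are what the model saw; the package takes that as the
covariance of record). The most-informative tally takes, per fold, the
argmax |pattern| feature → its (band, CSP filter), then that filter's
argmax |pattern| channel; ties break at the lowest index.

The group contrast is a paired sign-flip bootstrap: the observed statistic
is the subject-mean condition difference, the null is built by
sign-flipping each subject's difference (default 10,000 iterations), and
the two-sided p-value uses the add-one estimator
`(1 + #{|null| ≥ |obs|}) / (n_boot + 1)`, which is valid by construction.
Sign-flipping is the natural exact scheme for paired condition contrasts;
inference is pointwise at α = 0.01 with no cluster correction, and both the
pointwise waveform test and the 0.35–0.6 s window-mean scalar are provided.

## Morlet band power

The wavelet is a 6-cycle complex Morlet (the conventional time–frequency
trade-off; nothing in the analysis is sensitive to ±1 cycle). Scales are
spaced 1 Hz inside each band; per scale the squared magnitude is divided by
the wavelet's noise-equivalent bandwidth, making it a one-sided PSD
estimate, and band power is the scale-averaged PSD integrated over the band
width. Under this normalization a pure tone contributes its mean-square
power `a²/2` and white-noise band power grows proportionally with
bandwidth. With 6 cycles the alpha/beta separation of a 10 Hz tone is about
9.5×: adjacent bands see the tail of the wavelet bandwidth, which is a
property of the wavelet, not an implementation artifact.

## Problem sizes used by the test suite

The suite generates everything in code. The heavier checks use: one full
default session (2 × 500 s) for the continuous-pipeline recovery and its
100-permutation null; five 120-s recordings for burst suppression; 500
null simulations (n = 18, 999 flips) per α for bootstrap calibration; ten
18-subject cohorts of reduced sessions (80 stimuli per condition, 220 s)
for the P300 power check; and ten short sessions for interpretation
recovery. These sizes were chosen as the smallest at which the binomial
bounds quoted in the tests are meaningful.

## Known limitations

* The generator's effects are stationary and large; real flight EEG is
  non-stationary, artifact-ridden and individual. Perfect synthetic
  accuracies say nothing about real-data accuracy.
* ASR here is offline and window-granular, without the state-carrying
  streaming machinery of online implementations, and the burst criterion's
  scale depends on the pre-emphasis convention documented above.
* The repeated-measures ANOVAs of a full group analysis are deliberately
  out of scope; base R (`aov`, `car`) covers them. The bootstrap contrast
  is the implemented statistic.
* EDF output quantizes to 16 bits over a symmetric physical range
  (~0.006 µV resolution at ±200 µV), which is below EEG noise floors but
  not lossless.
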