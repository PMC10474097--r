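---
title: "Heartbeat detection from phonocardiograms: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heartbeat detection from phonocardiograms: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcgbeat)
```

## The problem

A phonocardiogram (PCG) records the acoustic vibrations of the heart on the
chest wall.  The two loudest events of each cardiac cycle are the first
heart sound S1 (closure of the atrioventricular valves, start of systole)
and the second heart sound S2 (closure of the semilunar valves, start of
diastole).  Locating S1 and S2 beat by beat gives a non-electrical route to
heart-rate monitoring, which is attractive wherever ECG electrodes are
impractical.  `pcgbeat` implements a complete direct-segmentation detector
for S1/S2, the ECG-anchored protocol used to score such detectors, and a
seeded simulator that generates PCG+ECG recordings with known ground truth
so the whole chain can be validated without clinical data.

## The detection pipeline

The detector operates on a single PCG channel sampled uniformly (the
simulator's default rate is 2.56 kHz, typical of multichannel acoustic
acquisition systems).

**Preprocessing.**  A zero-phase 2nd-order Butterworth band-pass with edges
at 2 and 100 Hz removes baseline wander and out-of-band noise; the energy of
S1 and S2 lies below 100 Hz.  The signal is then denoised with a discrete
wavelet transform (Daubechies db12, 5 decomposition levels): all detail
bands are soft-thresholded with the universal threshold
$\hat\sigma\sqrt{2\ln N}$, where $\hat\sigma$ is the median-absolute-
deviation noise estimate from the finest detail band, and the approximation
band is left untouched.  Finally the signal is rescaled to $[-1, 1]$ inside
consecutive 1 s windows, each window divided by its own peak magnitude, so a
single large artifact cannot crush the amplitude of the rest of the trace.

**Envelope.**  The normalized signal $x_n$ is transformed into third-order
Shannon energy,

$$E_S(i) = -\lvert x_n^3(i)\rvert \,\log \lvert x_n^3(i)\rvert,$$

which emphasizes medium-amplitude oscillatory bursts while suppressing both
the noise floor and full-scale samples.  The energy is smoothed by a
zero-phase 2nd-order Butterworth low-pass at 10 Hz and standardized to zero
mean and unit variance using the global mean $\mu$ and standard deviation
$\sigma$ of the smoothed envelope:

$$E_N(t) = \frac{E_S(t) - \mu}{\sigma}.$$

**Peak picking.**  Strict local maxima of $E_N$ above the threshold
$Th_1 = -0.9\,\mu/\sigma$ are candidate events; because heart sounds last on
the order of 150 ms, candidates closer than 150 ms are pruned by repeatedly
removing the lower-amplitude member of the closest violating pair.  A second
threshold $Th_2$ — the envelope mean, i.e. zero on the standardized scale —
separates the prominent peaks used for rhythm analysis from weak ones.

**Rhythm analysis.**  When S1 and S2 alternate, the interval between every
*other* prominent peak equals the beat period.  The *presumed heart period*
$\hat T_{S\text{-}S}$ is the mode (10 ms bins, ties to the smallest value)
of these lag-2 intervals.  The consecutive intervals between prominent peaks
are then clustered by one-dimensional K-means with $k = 3$ and initial
centroids at $0.35\,\hat T$, $0.65\,\hat T$ and $1.0\,\hat T$ — the
approximate systole/diastole split of a resting beat and the full period.
The peak that opens a "systole" interval is labelled S1, the peak that opens
a "diastole" interval S2; peaks opening "longer" intervals, the final peak,
and everything below $Th_2$ stay unclassified.

**Confirmation.**  Two interval-ratio rules repair the labelling: a
same-label gap shorter than $0.8\,\hat T$ demotes the second peak to
unclassified, and a gap longer than $1.3\,\hat T$ opens a 300 ms recovery
window centred one period after the earlier peak — the unclassified peak
closest to the window centre (ties to the earlier peak) is promoted to the
label.  Demotion runs to a fixed point before recovery; a promotion that
would itself create a too-short gap is skipped, so the demotion invariant
holds in the final output.

## The reference-ECG branch and evaluation protocol

The reference ECG is filtered with a zero-phase 1–150 Hz band-pass and a
48–52 Hz band-stop (mains interference).  R peaks are local maxima above 70%
of the maximum within consecutive 5 s windows, de-duplicated by a 0.25 s
refractory rule, and corrected with the same 0.8/1.3 interval-ratio
machinery applied to the median R–R interval (recovery candidates are local
ECG maxima inside the 300 ms window).  The T-wave maximum of each beat is
the ECG maximum in the window $(R + 0.12\ \mathrm{s},\, R + 0.4\,\bar
T_{R\text{-}R}]$, clipped before the next R.

Detections are scored in per-beat windows anchored on the R peaks:

* S1 window: $[R,\ R + 0.2\,\bar T_{R\text{-}R})$,
* S2 window: $[R + 1.2\,\bar T_{R\text{-}T},\ R + 0.6\,\bar T_{R\text{-}R})$,

where $\bar T_{R\text{-}R}$ and $\bar T_{R\text{-}T}$ are the median R–R and
R-to-T-maximum intervals.  Both windows shrink as heart rate rises.  Each
window credits at most one true positive; surplus or stray detections are
false positives and empty windows false negatives, giving

$$SE = \frac{TP}{TP+FN}\cdot 100\%, \qquad PPV = \frac{TP}{TP+FP}\cdot 100\%.$$

Undefined ratios (no detections, or no windows) are reported as missing,
never as zero.  Collections of per-record scores are summarized by median
and interquartile range $IQR = Q_3 - Q_1$ with type-7 (linearly
interpolated) quartiles.

Heart rate is estimated per 2 s tumbling window as $60$ divided by the
median of the inter-event intervals whose midpoints fall in the window,
separately from S1 sequences, S2 sequences and R peaks.  PCG- and
ECG-derived series are compared with a paired Wilcoxon signed-rank test at
$\alpha = 0.05$ on the windows where both are defined; zero differences are
discarded, two fully identical series give $p = 1$ by convention, the exact
null is used up to 25 non-zero pairs and the continuity-corrected normal
approximation above.

## The simulator

`simulation_spec()` / `generate_recording()` emulate the features the
detector relies on:

* quasi-periodic beats: R peaks at $60/\mathrm{HR}$ spacing with optional
  Gaussian period jitter (default SD 3 ms), spanning the whole record;
* electromechanical timing: S1 at $R + 40$ ms; S2 at S1 plus the systole
  duration, with the systole fraction of the beat rising linearly from 0.35
  at 60 bpm to 0.50 at 130 bpm (resting beats split roughly 35%/65% into
  systole and diastole, converging near 130 bpm);
* heart-sound morphology: Hann-windowed sinusoids, S1 at 35 Hz for 120 ms
  (amplitude 1) and S2 at 50 Hz for 100 ms (amplitude 0.8) — inside the
  sub-100 Hz band the sensing chain passes, with the relative S2 attenuation
  typical of sternum recordings; an `s2_attenuation` factor emulates the
  weak-S2 pathology;
* ECG morphology: Gaussian R spikes (12 ms width) and T bumps (40 ms width,
  amplitude 0.3) with the T maximum $0.25\sqrt{RR}$ after R, a Bazett-like
  rate scaling that keeps the T wave inside its physiologic position at all
  supported rates;
* contamination: white noise at a requested SNR (default 20 dB against the
  clean PCG), baseline wander below 2 Hz (sinusoid pair plus scaled random
  walk), and optional exponentially decaying motion spikes (default rate 0:
  the baseline condition is a still, resting subject).

All stochastic draws pass through one stream seeded from `spec$seed`, so
records are bit-reproducible; `make_cohort()` derives per-record seeds
deterministically from a master seed.

What the simulator does **not** model: murmurs, S3/S4, split S2, respiratory
modulation of heart rate and sound amplitude, sensor-contact variation, and
the non-stationary coloured noise of real wards.  Passing tests on this
synthetic material therefore demonstrates the internal consistency of the
pipeline and its behaviour under the modelled disturbances — not clinical
performance.

## Numerical and design choices

Choices the underlying method description leaves open were fixed as
follows; all are exposed in `pipeline_config()`.

* **Logarithm base of the Shannon energy**: natural log.  The base only
  rescales the energy by a positive constant, which cancels in both
  thresholds.
* **Which signal $\mu$ and $\sigma$ summarize**: the 10 Hz-smoothed
  envelope of the whole recording — the same signal whose peaks are picked —
  so $Th_1$ and $Th_2$ are constants across the trace.
* **Zero-phase filtering everywhere**: detected envelope maxima are the
  annotation times, and the evaluation windows are anchored on them, so
  phase delay anywhere in the chain would bias every score.  Filters are
  applied forward and backward over an odd-reflection extension of the
  signal (the magnitude response is squared in the process).
* **Wavelet thresholding rule**: universal soft threshold from the finest
  detail band, details only.  The DWT is applied in periodized form to a
  symmetrically padded copy of the signal: periodization keeps the
  transform exactly orthogonal (reconstruction to machine precision), while
  the pad keeps the wrap-around seam away from the data so denoising adds
  no edge spikes.
* **Mode of continuous intervals**: 10 ms quantization, ties to the
  smallest bin — far below the systole/diastole contrast at rest.
* **Minimum-spacing removal order**: closest violating pair first, iterated
  to a fixed point; deterministic, and verified in the tests against an
  exhaustive implementation of the same rule.
* **Empty K-means cluster**: keeps its centroid for that iteration, so
  $k = 3$ survives sparse interval sets; distance ties go to the
  lower-indexed centroid.
* **Confirmation order and ties**: one demotion pass to a fixed point, then
  recovery passes until stable; equidistant recovery candidates resolve to
  the earlier peak; a promotion that would violate the 0.8-period minimum
  gap is skipped.
* **Degenerate inputs**: all-zero (or sub-$10^{-12}$) normalization windows
  pass through as zeros; a constant envelope, fewer than 3 prominent peaks,
  or a record shorter than 3 s abort with named errors rather than
  guessing; trailing partial normalization windows are scaled by their own
  maximum.
* **Scoring precedence**: one TP credit per window; if an S2 window would
  overlap its beat's S1 window (possible at high rates), the S1 window wins
  and the S2 start is clipped, with the overlap counted.
* **Quartile rule**: type-7 linear interpolation, R's default, fixed and
  documented since the IQR definition does not pick one.

Problem sizes in the shipped validation: the end-to-end checks use a
20-record cohort of one-minute recordings at 60–90 bpm and 20 dB SNR with a
fixed master seed, the brute-force oracle suites 1000 randomized instances
per operation.  `scripts/acceptance.R` re-runs the same protocol from a
user-supplied seed.

## Known limitations

* **Weak S2 breaks more than S2.**  If S2 is strongly attenuated (factor
  0.1; cardiac pathology or an unfavourable sensor site), the cubed Shannon
  energy pushes S2 below even $Th_1$, so the prominent-peak train contains
  only S1.  The lag-2 mode then returns *two* beat periods, the interval
  clusters degenerate, and the 0.8-period demotion rule strips most S1
  labels as well: in the shipped failure-mode experiment S1 sensitivity
  collapses alongside S2 (from ~100% to a few percent).  This cascade is
  intrinsic to period estimation from the prominent-peak train; detecting
  it (e.g. flagging a presumed period near twice the R–R median when an ECG
  is present) is possible, but correcting it is out of scope here.
* **Resting rhythms only.**  Interval-based S1/S2 discrimination assumes
  systole clearly shorter than diastole; near 130 bpm the contrast vanishes
  and the K-means split becomes arbitrary.  The simulator can generate such
  rates, but the detector makes no claim there.
* **The T-wave locator is deliberately simple** (maximum in a fixed
  post-R window); it is adequate for the clean simulated ECG that anchors
  the scoring windows, not a clinical delineator.
* **Scores are protocol-dependent.**  SE/PPV are measured against
  ECG-anchored windows, so errors in the ECG branch propagate into the PCG
  scores; the simulator keeps the ECG branch essentially error-free, which
  real recordings will not.
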