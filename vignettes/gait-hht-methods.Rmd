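---
title: "Methods: gait abnormality detection with EMD and the Hilbert spectrum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gait abnormality detection with EMD and the Hilbert spectrum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaithht)
```

## The problem

Markerless, video-based gait analysis estimates 2-D body keypoints per frame
with a pose-estimation network and asks clinical questions of the resulting
time series. This package addresses one such question: can the *transition*
between two walking bouts — the turn — distinguish normal gait from
Parkinsonian and other disordered gait? Healthy subjects turn in roughly two
seconds; Parkinsonian subjects can take on the order of ten. The package
therefore (i) converts hip–knee–ankle keypoint triples into knee
flexion/extension angle signals, (ii) decomposes each signal with empirical
mode decomposition (EMD), (iii) computes the Hilbert spectrum and a
time-resolved oscillation energy, (iv) detects turns as prolonged low-energy
segments and measures their durations, and (v) classifies recordings as
normal walking (NW), other-disorder walking (OW) or Parkinson-like (PD) from
IMF, energy and turn features.

## From keypoints to an angle signal

A keypoint track is a long tibble (frame × joint) of image coordinates with
per-detection confidence in [0, 1]. Detections below a confidence threshold
(default 0.5, the conventional pose-estimator operating point) are marked
missing; missing runs up to `max_gap_s` (default 0.5 s — occlusions are
brief relative to a ~1.1 s stride) are filled by per-coordinate linear
interpolation, never by extrapolation beyond the first or last valid frame.

Knee flexion is the unsigned angle `180° − ∠(thigh, shank)` at the knee,
with the thigh vector knee→hip and shank vector knee→ankle; 0° is a fully
extended leg. 2-D keypoints cannot resolve signed anatomical flexion
robustly, and an unsigned angle is invariant to translation, rotation,
uniform scaling, y-axis flips (image vs mathematical coordinates) and
walking direction, all of which vary freely across videos. The analysis side
is configurable with `left` as the default; the two sides are treated
identically and a symmetric subject yields identical signals.

## Empirical mode decomposition

EMD is implemented from scratch, since it is the methodological core:

1. locate interior maxima and minima (`find_extrema()`); a flat plateau
   contributes its midpoint index, which keeps everything deterministic;
2. fit natural cubic splines through the maxima and through the minima
   (`stats::spline`), after mirroring the two extrema nearest each end
   across the boundary sample — this suppresses the end swings that
   otherwise corrupt short recordings;
3. form the mean envelope `m(t) = (e_max(t) + e_min(t))/2` and the candidate
   `c(t) = x(t) − m(t)`;
4. repeat (sift) until the candidate is an intrinsic mode function (IMF),
   record it, subtract it, and continue on the remainder;
5. stop when the remainder has fewer than two interior extrema (it is then
   the residual trend) or `max_imfs` (default 8) is reached.

Note the mean envelope is the *average* of the two envelopes. A
half-difference `(e_max − e_min)/2` is the envelope half-width — it is
nonnegative by construction and cannot serve as the local mean that sifting
subtracts; with it, a zero-mean sinusoid would never become an IMF.

The IMF acceptance criterion is the standard count criterion — the numbers
of extrema and zero crossings differ by at most one, and the candidate
actually oscillates (at least one maximum and one minimum) — combined with
the Cauchy stopping rule `SD = Σ(c_prev − c)² / Σ c_prev² < 0.2`, capped at
50 sifts per IMF. The 0.2 threshold and the cap are the conventional values
from the EMD literature; the source method statement leaves them open.
Completeness, `x(t) = Σ c_i(t) + r(t)`, is an algebraic identity of the
recursion and holds to numerical precision for every input regardless of
stopping parameters; the tests assert it below 1e-9 on a hundred random
signals, and assert two-tone separation (2 Hz + 0.2 Hz) against closed
forms and an independent minimal reference implementation.

## Hilbert spectral analysis

Each IMF's analytic signal is built in the frequency domain (zero the
negative frequencies, double the positive ones, keep DC and Nyquist).
Instantaneous amplitude is the modulus; instantaneous frequency is the
derivative of the unwrapped phase (central differences, one-sided at the
ends) divided by 2π, clipped to the physical band [0, fps/2] with the
clipped fraction reported. Samples with amplitude below 1e-12 have no
meaningful phase and are reported as undefined rather than zero.

The Hilbert spectrum deposits each IMF's amplitude (or squared amplitude in
energy mode) into the frequency bin containing its instantaneous frequency,
on a uniform grid of 64 bins over [0, fps/2] by default. The time-resolved
energy trace is `E(t) = Σ_j a_j(t)²` over the included IMFs — the residual
is a trend, not an oscillation, and is always excluded — smoothed by a
centered 1 s moving average. One second averages out within-stride
oscillation of `E` while leaving a 2 s turn resolvable.

## Turn detection

During a turn the knee oscillation is smaller and slower, so `E(t)` drops.
Turns are maximal runs with `E < 0.5 × median(E)`; runs separated by less
than 0.25 s are merged and runs shorter than 1 s are discarded. The median
is robust as long as turning occupies a minority of the trace; the 1 s floor
excludes stride-level dips. All three constants are configurable. Because
the threshold is relative, detection is invariant to rescaling the energy —
amplitude units cancel. Segments touching the first or last second are
flagged `boundary` rather than dropped, since recordings begin and end
mid-activity.

## Features and classification

Classification uses windows (default 2 s, hop 1 s) as the sampling unit:
each window contributes statistics of one configured IMF (default index 6,
falling back to the last available IMF when the decomposition is shallower),
statistics of `E(t)`, and turn features (fraction of the window inside a
turn, plus the signal's maximal turn duration and turn count). Two models
sit behind one interface: a random forest (100 trees, the default) and
k-nearest neighbours (k = 5, on z-scored features). Evaluation reports, per
class, `TPR = TP/(TP + FN)` and `FNR = 1 − TPR`; classes absent from the
truth get undefined (NA) rates rather than zero. Both models, the window
scheme, and all hyperparameters are recorded in the fitted object.

## The synthetic generator

No public dataset accompanies the method — the source recordings are
third-party videos — so every stage is validated on seeded synthetic data
with known ground truth. The angle model is

`θ(t) = mean + A(t)·sin(2π∫f(t)dt) + drift + noise`,

with defaults: 30 s at 30 frames/s, stride 0.9 Hz, mean flexion 30°,
excursion 25°, Gaussian noise SD 1°, and a slow 0.03 Hz drift of 3°
amplitude standing in for posture and camera trends. Inside a turn window,
amplitude drops to 0.3× and frequency to 0.5× with 0.5 s cosine-tapered
edges; bundled presets inject 2 s (`normal`), 5 s (`neuropathy`), 6 s
(`pd_mild`) and 10 s (`pd_severe`) turns, the 2 s and 10 s values being the
published normal and Parkinsonian turn times the pipeline must recover. The
kinematic defaults are ordinary normal-gait figures; the method's source
publishes no numeric signal ranges, so they are documented fixture choices,
chosen once.

`generate_keypoint_track()` inverts the angle formula exactly: the hip moves
along a smooth horizontal path, the thigh swings ±12°, and the ankle is
placed by rotating the thigh direction by the interior knee angle, so the
kinematics module recovers `θ(t)` to machine precision. Baseline confidence
is 0.95 with configurable occlusion dips.

What the generator does *not* emulate: pose-estimator jitter correlated
across joints, perspective foreshortening, double support asymmetry,
festination, and multi-person confusion. Passing tests therefore demonstrate
the signal-processing chain is correct and recovers known turns under
realistic noise — not that the classifier's accuracy transfers to real
video, which the method's own evaluation found limited by data volume.

## Numerical choices and edge cases

- Plateau extrema take the midpoint index; all tie-breaks are deterministic
  and the EMD path contains no randomness at all.
- A constant signal decomposes to zero IMFs with the input as residual;
  non-finite samples are rejected up front.
- A candidate that stops being siftable mid-loop (too few extrema) is
  accepted as-is and the reason recorded per IMF.
- Envelope splines are natural cubics; spline tolerance at the knots is
  asserted at 1e-6.
- Detection confidence exactly at the threshold survives (`<`, not `≤`),
  matching the usual estimator convention.
- Windows at the signal tail shorter than `window_s` are truncated, not
  padded.

## Problem sizes

The validation suite uses 30 s recordings at 30 Hz (900 samples), 100
random signals of 256–4096 samples for the completeness property, 20 seeded
scenarios per condition for turn-duration recovery, and a 14-subject corpus
(5 NW, 6 OW, 3 PD) for the end-to-end determinism check — sizes at which
the full suite runs in well under a minute on one core while still covering
multi-IMF decompositions.

## Known limitations

- Only 2-D, single-person, sagittal-ish views are supported; the angle is
  unsigned, so hyperextension is folded onto flexion.
- Instantaneous frequency by phase differentiation is noisy where amplitude
  is small; the spectrum reports, rather than hides, the affected samples.
- The turn detector assumes walking occupies the majority of the trace; a
  recording that is mostly turning would invert the median threshold.
- The classifier is only as good as its features; with the small corpora
  this package targets, reports should be read as sanity checks, not
  clinical claims.
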