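# gaithht

Video-based gait analysis without wearables: **gaithht** turns 2-D
pose-estimation keypoint tracks into knee flexion/extension angle signals,
decomposes them with empirical mode decomposition (EMD), computes the
Hilbert energy spectrum, detects walking→turning transitions as prolonged
low-energy segments, and classifies gait as normal walking (NW),
other-disorder walking (OW) or Parkinson-like (PD). It is aimed at
researchers studying gait abnormalities from ordinary video: healthy
subjects turn in about 2 s, while Parkinsonian subjects can take about 10 s,
and that duration is the package's headline measurement.

## The method

Given a knee-angle signal $x(t)$ sampled at `fps` Hz:

1. **EMD** (implemented from scratch). Sifting subtracts the mean of the
   cubic-spline envelopes through the extrema,
   $m(t) = \tfrac{1}{2}\,(e_{\max}(t) + e_{\min}(t))$, $c(t) = x(t) − m(t)$,
   until $c$ is an intrinsic mode function (extrema and zero-crossing counts
   differ by at most one; Cauchy criterion
   $SD = \sum(c_{prev}−c)^2 / \sum c_{prev}^2 < 0.2$). The signal becomes
   $x(t) = \sum_i c_i(t) + r(t)$ exactly — completeness is asserted to
   1e-9 in the tests.
2. **Hilbert spectral analysis.** Per IMF, the analytic signal gives
   instantaneous amplitude $a_j(t)$ and frequency
   $\omega_j(t) = \tfrac{1}{2\pi}\,d\theta_j/dt$; the spectrum distributes
   $a_j(t)$ (or $a_j^2$) over the time–frequency plane, and the energy trace
   is $E(t) = \sum_j a_j(t)^2$, smoothed over 1 s.
3. **Turn detection.** Turning produces smaller oscillation energy than
   walking, so turns are maximal runs with
   $E(t) < 0.5 \times \mathrm{median}(E)$ lasting at least 1 s (0.25 s gaps
   merged). Durations are the discriminative output.
4. **Classification.** Windowed features (statistics of a configured IMF,
   default the 6th; energy statistics; turn features) feed a random forest
   or KNN; evaluation reports per-class $TPR = TP/(TP+FN)$ and
   $FNR = 1 − TPR$.

Because the source recordings of this line of work are unavailable videos,
the package ships a seeded synthetic generator (`gait_scenario()`,
`generate_gait_signal()`, `generate_keypoint_track()`) whose ground truth
(stride frequency, turn interval, occlusions) is known exactly, so every
stage is testable end to end.

## Worked example

```r
library(gaithht)

sc  <- gait_scenario_preset("pd_severe", seed = 1)  # 10 s turn, 30 s @ 30 Hz
sig <- generate_gait_signal(sc)
dec <- emd(sig)
glance(dec)
#> # A tibble: 1 × 5
#>   n_imfs n_samples   fps total_sifts decomposition_stop
#> 1      5       900    30          17 residual_extrema

tr  <- energy_trace(dec)                 # E(t), 1 s window
seg <- detect_transitions(tr)
tibble::as_tibble(seg)
#> # A tibble: 1 × 6
#>   start_s end_s duration_s mean_energy_in mean_energy_out boundary
#> 1    10.2  20.0       9.73           96.8            894. FALSE
turn_durations(seg)$max
#> [1] 9.733333
```

The decomposition produced 5 IMFs; the energy trace drops by roughly a
factor of nine inside the injected turn, and the detector recovers the 10 s
turn to within 0.3 s. An `autoplot()` method exists for every result type
(`gait_signal`, `gait_imf`, `hilbert_spectrum`, `energy_trace`), and
`run_pipeline()` chains all stages over a corpus of tracks, returning a
feature table, per-subject segments and (with labels) a TPR/FNR report.

Keypoint input is read from OpenPose-style per-frame JSON
(`read_openpose_json()`, BODY_25 or COCO-18 order) or a flat
`frame,joint,x,y,confidence` CSV (`read_keypoint_csv()`); a thin CLI over
the same functions is installed at `inst/cli/gait-hht`.

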