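# Shared fixtures: all synthetic, generated in code.

# Uniform time grid, half-open [0, dur) so a whole number of periods fits.
time_grid <- function(dur_s, fps) seq(0, dur_s - 1 / fps, by = 1 / fps)

tone <- function(freq_hz, dur_s, fps, amp = 1, phase = 0) {
  amp * sin(2 * pi * freq_hz * time_grid(dur_s, fps) + phase)
}

# Indices of the central (1 - 2*frac) portion of a series.
interior_idx <- function(n, frac = 0.05) {
  lo <- max(1L, ceiling(n * frac))
  hi <- min(n, floor(n * (1 - frac)))
  lo:hi
}

# Tiny 2-frames x 2-joints keypoint data frame.
mini_track_df <- function() {
  data.frame(
    frame = c(0L, 0L, 1L, 1L),
    joint = rep(c("left_knee", "left_hip"), 2),
    x = c(1, 2, 3, 4),
    y = c(5, 6, 7, 8),
    confidence = c(0.9, 0.8, 0.7, 0.6)
  )
}

# Longest detected turn for a preset scenario run through the default
# EMD -> energy -> transition pipeline.
detected_turn <- function(preset, seed, ...) {
  sc <- gait_scenario_preset(preset, seed = seed, ...)
  sig <- generate_gait_signal(sc)
  seg <- detect_transitions(energy_trace(emd(sig)))
  turn_durations(seg)$max
}
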