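#' Define a synthetic gait scenario
#'
#' A scenario fully specifies a seeded quasi-periodic knee flexion signal:
#' baseline stride oscillation, an optional embedded turning segment in which
#' amplitude and frequency drop (with cosine-tapered edges), a slow drift
#' trend, Gaussian angle noise, and optional occlusion windows that depress
#' keypoint detection confidence.
#'
#' Defaults describe a 30 s recording at 30 frames/s of a walker with a
#' 0.9 Hz stride, mean knee flexion 30 degrees and excursion 25 degrees;
#' during a turn the oscillation shrinks to 0.3 of its amplitude and 0.5 of
#' its frequency.
#'
#' @param duration_s Recording length in seconds.
#' @param fps Frames per second.
#' @param stride_freq_hz Walking oscillation frequency in Hz.
#' @param flexion_mean_deg,flexion_amp_deg Mean and amplitude of the knee
#'   flexion oscillation, degrees.
#' @param turn_start_s Turn onset in seconds; `NULL` centers the turn.
#' @param turn_duration_s Turn length in seconds (0 = no turn).
#' @param turn_amp_factor,turn_freq_factor Multiplicative amplitude and
#'   frequency factors inside the turn, in (0, 1].
#' @param noise_sd_deg Gaussian angle noise SD, degrees.
#' @param drift_amp_deg Amplitude of the slow (0.03 Hz) drift trend, degrees.
#' @param taper_s Cosine taper width at the turn edges, seconds.
#' @param occlusion Data frame with columns `start_s`, `duration_s`,
#'   `confidence_level`, or `NULL`.
#' @param seed Integer seed; same seed gives bit-identical output.
#' @param subject_id Optional label.
#' @return A `gait_scenario` list.
#' @export
gait_scenario <- function(duration_s = 30, fps = 30, stride_freq_hz = 0.9,
                          flexion_mean_deg = 30, flexion_amp_deg = 25,
                          turn_start_s = NULL, turn_duration_s = 0,
                          turn_amp_factor = 0.3, turn_freq_factor = 0.5,
                          noise_sd_deg = 1, drift_amp_deg = 3, taper_s = 0.5,
                          occlusion = NULL, seed = 1, subject_id = NULL) {
  if (fps <= 0) abort("`fps` must be positive.")
  if (duration_s <= 0) abort("`duration_s` must be positive.")
  if (flexion_amp_deg < 0 || drift_amp_deg < 0 || noise_sd_deg < 0) {
    abort("Amplitudes and noise SD must be nonnegative.")
  }
  if (turn_amp_factor <= 0 || turn_amp_factor > 1 ||
      turn_freq_factor <= 0 || turn_freq_factor > 1) {
    abort("Turn factors must lie in (0, 1].")
  }
  turn_start_s <- turn_start_s %||% ((duration_s - turn_duration_s) / 2)
  if (turn_duration_s > 0 &&
      (turn_start_s < 0 || turn_start_s + turn_duration_s > duration_s)) {
    abort("Turn window must be contained in [0, duration_s].")
  }
  if (!is.null(occlusion)) {
    req <- c("start_s", "duration_s", "confidence_level")
    if (!all(req %in% names(occlusion))) {
      abort("`occlusion` needs columns start_s, duration_s, confidence_level.")
    }
  }
  structure(
    list(
      duration_s = duration_s, fps = fps, stride_freq_hz = stride_freq_hz,
      flexion_mean_deg = flexion_mean_deg, flexion_amp_deg = flexion_amp_deg,
      turn_start_s = turn_start_s, turn_duration_s = turn_duration_s,
      turn_amp_factor = turn_amp_factor, turn_freq_factor = turn_freq_factor,
      noise_sd_deg = noise_sd_deg, drift_amp_deg = drift_amp_deg,
      taper_s = taper_s, occlusion = occlusion, seed = seed,
      subject_id = subject_id %||% paste0("subject_", seed)
    ),
    class = "gait_scenario"
  )
}

#' Bundled named scenarios
#'
#' `normal` embeds a 2 s turn (healthy subjects turn briskly), `pd_mild` a
#' 6 s turn, `pd_severe` a 10 s turn (Parkinsonian subjects take on the
#' order of ten seconds), and `neuropathy` a 5 s turn.
#'
#' @param name One of `"normal"`, `"pd_mild"`, `"pd_severe"`, `"neuropathy"`.
#' @param seed Integer seed.
#' @param ... Overrides passed to [gait_scenario()].
#' @return A `gait_scenario`.
#' @export
gait_scenario_preset <- function(name = c("normal", "pd_mild", "pd_severe",
                                          "neuropathy"), seed = 1, ...) {
  name <- match.arg(name)
  turn <- switch(name, normal = 2, pd_mild = 6, pd_severe = 10, neuropathy = 5)
  args <- utils::modifyList(
    list(turn_duration_s = turn, seed = seed,
         subject_id = paste0(name, "_", seed)),
    list(...)
  )
  do.call(gait_scenario, args)
}

# Turn depth profile d(t) in [0, 1]: 0 outside the window, cosine ramps of
# width taper_s just inside its edges, 1 in the core.
turn_depth <- function(t, start_s, duration_s, taper_s) {
  d <- numeric(length(t))
  if (duration_s <= 0) return(d)
  end_s <- start_s + duration_s
  taper <- min(taper_s, duration_s / 2)
  inside <- t >= start_s & t <= end_s
  d[inside] <- 1
  if (taper > 0) {
    ramp_in <- t >= start_s & t < start_s + taper
    d[ramp_in] <- (1 - cos(pi * (t[ramp_in] - start_s) / taper)) / 2
    ramp_out <- t > end_s - taper & t <= end_s
    d[ramp_out] <- (1 - cos(pi * (end_s - t[ramp_out]) / taper)) / 2
  }
  d
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic knee-angle gait signal with known ground truth
#'
#' The angle trajectory is
#' `theta(t) = mean + A(t) sin(2 pi integral f(t) dt) + drift + noise`,
#' where amplitude `A` and frequency `f` drop to the scenario's turn factors
#' inside the turn window (cosine-tapered edges), the drift is a slow 0.03 Hz
#' sine of the scenario's drift amplitude, and the noise is Gaussian. The
#' result is clipped to [0, 180] degrees. Output is deterministic per seed.
#'
#' @param scenario A `gait_scenario`.
#' @return A `gait_signal` tibble (`time_s`, `angle_deg`) whose `truth`
#'   attribute records the exact turn interval and generator parameters.
#' @export
generate_gait_signal <- function(scenario) {
  stopifnot(inherits(scenario, "gait_scenario"))
  s <- scenario
  n <- round(s$duration_s * s$fps)
  t <- (seq_len(n) - 1) / s$fps
  d <- turn_depth(t, s$turn_start_s, s$turn_duration_s, s$taper_s)
  A <- s$flexion_amp_deg * (1 - d * (1 - s$turn_amp_factor))
  f <- s$stride_freq_hz * (1 - d * (1 - s$turn_freq_factor))
  phase <- 2 * pi * cumsum(f) / s$fps
  core <- s$flexion_mean_deg + A * sin(phase)
  noise <- with_seed(s$seed, {
    drift_phase <- runif(1, 0, 2 * pi)
    drift <- s$drift_amp_deg * sin(2 * pi * 0.03 * t + drift_phase)
    drift + rnorm(n, 0, s$noise_sd_deg)
  })
  theta <- pmin(pmax(core + noise, 0), 180)
  structure(
    tibble::tibble(time_s = t, angle_deg = theta),
    class = c("gait_signal", class(tibble::tibble())),
    fps = s$fps, side = "left", subject_id = s$subject_id,
    truth = list(
      turn_start_s = if (s$turn_duration_s > 0) s$turn_start_s else NA_real_,
      turn_end_s = if (s$turn_duration_s > 0) s$turn_start_s + s$turn_duration_s else NA_real_,
      turn_duration_s = s$turn_duration_s,
      stride_freq_hz = s$stride_freq_hz,
      scenario = s
    )
  )
}

# Rotation of 2-d row vectors by `deg` degrees (y-down image plane).
rotate2 <- function(v, deg) {
  a <- deg * pi / 180
  cbind(cos(a) * v[, 1] - sin(a) * v[, 2],
        sin(a) * v[, 1] + cos(a) * v[, 2])
}

#' Generate a synthetic keypoint track whose knee angle is known exactly
#'
#' Places the hip on a smooth horizontal path and synthesizes knee and ankle
#' positions by inverse kinematics so that [knee_flexion_angle()] applied to
#' the track reproduces the scenario's angle trajectory exactly (fixed thigh
#' and shank lengths, a small thigh swing). Both sides are generated
#' symmetrically. Baseline confidence is 0.95, depressed to the configured
#' level inside occlusion windows.
#'
#' @param scenario A `gait_scenario`.
#' @return A `keypoint_track` tibble with the six lower-limb joints; the
#'   `truth` attribute carries the exact angle trajectory and turn interval.
#' @export
generate_keypoint_track <- function(scenario) {
  sig <- generate_gait_signal(scenario)
  s <- scenario
  n <- nrow(sig)
  t <- sig$time_s
  theta <- sig$angle_deg
  thigh_len <- 100
  shank_len <- 90

  hip <- cbind(60 + 25 * t, rep(120, n))
  swing <- 12 * sin(2 * pi * s$stride_freq_hz * t)   # thigh swing, degrees
  thigh_dir <- cbind(sin(swing * pi / 180), cos(swing * pi / 180)) # y-down
  knee <- hip + thigh_len * thigh_dir
  u <- -thigh_dir                                    # knee -> hip unit vector
  shank_dir <- rotate2(u, 180 - theta)
  ankle <- knee + shank_len * shank_dir

  conf <- rep(0.95, n)
  if (!is.null(s$occlusion)) {
    for (i in seq_len(nrow(s$occlusion))) {
      w <- t >= s$occlusion$start_s[i] &
        t < s$occlusion$start_s[i] + s$occlusion$duration_s[i]
      conf[w] <- s$occlusion$confidence_level[i]
    }
  }

  per_side <- function(side) {
    tibble::tibble(
      frame = rep(seq_len(n) - 1L, 3),
      joint = rep(paste0(side, c("_hip", "_knee", "_ankle")), each = n),
      x = c(hip[, 1], knee[, 1], ankle[, 1]),
      y = c(hip[, 2], knee[, 2], ankle[, 2]),
      confidence = rep(conf, 3)
    )
  }
  df <- dplyr::bind_rows(per_side("left"), per_side("right"))
  track <- new_keypoint_track(df, fps = s$fps, subject_id = s$subject_id)
  attr(track, "truth") <- list(
    angle_deg = theta,
    turn_start_s = attr(sig, "truth")$turn_start_s,
    turn_end_s = attr(sig, "truth")$turn_end_s,
    turn_duration_s = s$turn_duration_s,
    scenario = s
  )
  track
}

#' Write a keypoint track as per-frame OpenPose-style JSON files
#'
#' One file per frame (`frame_%06d_keypoints.json`), each holding
#' `people[[1]]$pose_keypoints_2d` as a flat x, y, confidence triple list in
#' the chosen body-model joint order; joints the track does not carry are
#' written as zeros. Frames where every joint is missing serialize as
#' `"people": []`. Coordinates are written at full precision so the files
#' round-trip through [read_openpose_json()] exactly.
#'
#' @param track A `keypoint_track`.
#' @param directory Output directory (created if needed).
#' @param model `"body25"` or `"coco18"` joint ordering.
#' @return Invisibly, the vector of file paths written.
#' @export
write_openpose_json <- function(track, directory, model = c("body25", "coco18")) {
  model <- match.arg(model)
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("Cannot create directory '%s'.", directory))
  }
  idx_map <- openpose_joint_indices(model)
  n_joints <- if (model == "body25") 25L else 18L
  frames <- sort(unique(track$frame))
  wide <- tidyr::pivot_wider(
    track,
    id_cols = "frame",
    names_from = "joint",
    values_from = c("x", "y", "confidence", "missing")
  )
  paths <- character(length(frames))
  for (i in seq_along(frames)) {
    row <- wide[wide$frame == frames[i], ]
    flat <- numeric(3 * n_joints)
    any_present <- FALSE
    for (jn in names(idx_map)) {
      if (!paste0("x_", jn) %in% names(row)) next
      miss <- isTRUE(row[[paste0("missing_", jn)]])
      if (!miss) any_present <- TRUE
      k <- idx_map[[jn]] * 3L
      flat[k + 1L] <- if (miss) 0 else row[[paste0("x_", jn)]]
      flat[k + 2L] <- if (miss) 0 else row[[paste0("y_", jn)]]
      flat[k + 3L] <- if (miss) 0 else row[[paste0("confidence_", jn)]]
    }
    obj <- if (any_present) {
      list(version = 1.3,
           people = list(list(pose_keypoints_2d = flat)))
    } else {
      list(version = 1.3, people = list())
    }
    paths[i] <- file.path(directory,
                          sprintf("frame_%06d_keypoints.json", frames[i]))
    jsonlite::write_json(obj, paths[i], auto_unbox = TRUE, digits = I(17))
  }
  invisible(paths)
}
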