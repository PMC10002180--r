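#' Knee flexion/extension angle from hip, knee and ankle keypoints
#'
#' Flexion is defined as `180 - interior angle at the knee`, where the
#' interior angle is between the thigh vector (knee to hip) and the shank
#' vector (knee to ankle). A fully extended (collinear) leg therefore reads
#' 0 degrees, and the result always lies in [0, 180]. The angle is unsigned:
#' 2-D keypoints cannot resolve signed anatomical flexion robustly, and it is
#' invariant to translation, rotation, uniform scaling and axis flips of the
#' image coordinates.
#'
#' @param hip,knee,ankle Length-2 numeric vectors `(x, y)`, or n x 2
#'   matrices for vectorized evaluation.
#' @return Flexion angle(s) in degrees.
#' @examples
#' knee_flexion_angle(c(0, 0), c(0, 1), c(0, 2)) # 0: fully extended
#' knee_flexion_angle(c(0, 0), c(0, 1), c(1, 1)) # 90
#' @export
knee_flexion_angle <- function(hip, knee, ankle) {
  as_mat <- function(p) if (is.matrix(p)) p else matrix(p, ncol = 2)
  hip <- as_mat(hip); knee <- as_mat(knee); ankle <- as_mat(ankle)
  thigh <- hip - knee
  shank <- ankle - knee
  nt <- sqrt(rowSums(thigh^2))
  ns <- sqrt(rowSums(shank^2))
  if (any(nt == 0 | ns == 0)) {
    abort("Degenerate geometry: coincident hip/knee or knee/ankle points.")
  }
  cosang <- rowSums(thigh * shank) / (nt * ns)
  cosang <- pmin(pmax(cosang, -1), 1)
  interior <- acos(cosang) * 180 / pi
  180 - interior
}

#' Build a knee-angle gait signal from a keypoint track
#'
#' Applies [knee_flexion_angle()] frame by frame to one side's hip, knee and
#' ankle. The track must have no unresolved missing frames for those joints —
#' run [filter_by_confidence()] and [interpolate_gaps()] first.
#'
#' @param track A `keypoint_track`.
#' @param side `"left"` (default; study analyses use the left knee) or
#'   `"right"`.
#' @param smooth_window Optional centered moving-average window in samples
#'   (default `NULL`, no smoothing); recorded in the signal's metadata.
#' @return A `gait_signal` tibble with columns `time_s`, `angle_deg` and
#'   attributes `fps`, `side`, `subject_id`, `smooth_window`.
#' @export
build_gait_signal <- function(track, side = c("left", "right"),
                              smooth_window = NULL) {
  side <- match.arg(side)
  fps <- attr(track, "fps")
  need <- paste0(side, c("_hip", "_knee", "_ankle"))
  absent <- setdiff(need, unique(track$joint))
  if (length(absent)) {
    abort(sprintf("Track lacks joint(s): %s.", paste(absent, collapse = ", ")))
  }
  get_joint <- function(jn) {
    sub <- dplyr::arrange(track[track$joint == jn, ], .data$frame)
    if (any(sub$missing)) {
      bad <- sub$frame[sub$missing]
      abort(sprintf(
        "Joint '%s' has %d unresolved missing frame(s) (e.g. %s); run interpolate_gaps() first.",
        jn, length(bad), paste(head(bad, 5), collapse = ", ")
      ), class = "gaithht_missing_frames")
    }
    sub
  }
  hip <- get_joint(need[1]); knee <- get_joint(need[2]); ankle <- get_joint(need[3])
  ang <- knee_flexion_angle(cbind(hip$x, hip$y), cbind(knee$x, knee$y),
                            cbind(ankle$x, ankle$y))
  if (!is.null(smooth_window) && smooth_window > 1) {
    ang <- moving_average(ang, as.integer(smooth_window))
  }
  structure(
    tibble::tibble(time_s = hip$frame / fps, angle_deg = ang),
    class = c("gait_signal", class(tibble::tibble())),
    fps = fps,
    side = side,
    subject_id = attr(track, "subject_id"),
    smooth_window = smooth_window
  )
}
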