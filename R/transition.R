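#' Detect walking-to-turning transitions as prolonged low-energy segments
#'
#' Turning produces a smaller Hilbert energy than straight walking, so
#' transitions are detected as maximal runs of the energy trace below a
#' relative threshold `rel_threshold * median(E)`. Runs separated by less
#' than `merge_gap_s` are merged, then runs shorter than `min_duration_s`
#' are discarded. The median makes the threshold robust to the turn itself
#' occupying a minority of the trace, and the duration floor excludes
#' within-stride energy dips. Segments touching the first or last second of
#' the trace are flagged `boundary`, since recordings begin and end
#' mid-activity.
#'
#' @param trace An `energy_trace` tibble (see [energy_trace()]).
#' @param rel_threshold Fraction of the median energy (default 0.5).
#' @param min_duration_s Minimum segment duration in seconds (default 1).
#' @param merge_gap_s Merge low-energy runs closer than this (default 0.25).
#' @param boundary_s Width of the boundary-unreliable zone (default 1).
#' @return A `gait_segments` tibble with columns `start_s`, `end_s`,
#'   `duration_s`, `mean_energy_in`, `mean_energy_out`, `boundary`.
#' @export
detect_transitions <- function(trace, rel_threshold = 0.5, min_duration_s = 1,
                               merge_gap_s = 0.25, boundary_s = 1) {
  fps <- attr(trace, "fps") %||% (1 / diff(trace$time_s[1:2]))
  E <- trace$energy
  n <- length(E)
  if (n < 2 * min_duration_s * fps) {
    abort("Energy trace is too short for the requested minimum duration.")
  }
  empty <- tibble::tibble(
    start_s = numeric(0), end_s = numeric(0), duration_s = numeric(0),
    mean_energy_in = numeric(0), mean_energy_out = numeric(0),
    boundary = logical(0)
  )
  if (all(E == 0)) {
    warn("Energy trace is identically zero; no transitions detectable.")
    return(as_gait_segments(empty, rel_threshold, NA_real_))
  }
  threshold <- rel_threshold * median(E)
  below <- E < threshold
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  run_start <- starts[r$values]
  run_end <- ends[r$values]
  if (length(run_start) == 0) {
    return(as_gait_segments(empty, rel_threshold, threshold))
  }
  # merge runs separated by short above-threshold gaps
  gap_frames <- merge_gap_s * fps
  ms <- run_start[1]
  me <- run_end[1]
  seg_start <- integer(0)
  seg_end <- integer(0)
  for (i in seq_along(run_start)[-1]) {
    if (run_start[i] - me - 1L < gap_frames) {
      me <- run_end[i]
    } else {
      seg_start <- c(seg_start, ms); seg_end <- c(seg_end, me)
      ms <- run_start[i]; me <- run_end[i]
    }
  }
  seg_start <- c(seg_start, ms)
  seg_end <- c(seg_end, me)

  dur <- (seg_end - seg_start + 1L) / fps
  keep <- dur >= min_duration_s
  seg_start <- seg_start[keep]; seg_end <- seg_end[keep]; dur <- dur[keep]
  if (length(seg_start) == 0) {
    return(as_gait_segments(empty, rel_threshold, threshold))
  }
  inside <- rep(FALSE, n)
  for (i in seq_along(seg_start)) inside[seg_start[i]:seg_end[i]] <- TRUE
  total_s <- n / fps
  out <- tibble::tibble(
    start_s = (seg_start - 1L) / fps,
    end_s = seg_end / fps,
    duration_s = dur,
    mean_energy_in = vapply(seq_along(seg_start), function(i) {
      mean(E[seg_start[i]:seg_end[i]])
    }, numeric(1)),
    mean_energy_out = if (all(inside)) NA_real_ else mean(E[!inside]),
    boundary = (seg_start - 1L) / fps < boundary_s |
      seg_end / fps > total_s - boundary_s
  )
  as_gait_segments(out, rel_threshold, threshold)
}

as_gait_segments <- function(df, rel_threshold, threshold) {
  structure(
    df,
    class = c("gait_segments", class(tibble::tibble())),
    rel_threshold = rel_threshold,
    threshold = threshold
  )
}

#' Turn durations and their summary
#'
#' @param segments A `gait_segments` tibble from [detect_transitions()].
#' @return A list with `durations` (seconds, in input order), `count`,
#'   `max` and `total` (0 when no segments were detected).
#' @export
turn_durations <- function(segments) {
  d <- segments$duration_s %||% numeric(0)
  list(
    durations = d,
    count = length(d),
    max = if (length(d)) max(d) else 0,
    total = sum(d)
  )
}
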