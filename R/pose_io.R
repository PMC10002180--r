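lower_limb_joints <- c("left_hip", "left_knee", "left_ankle",
                       "right_hip", "right_knee", "right_ankle")

# 0-based keypoint indices of the lower-limb joints in the two common
# body-model orderings.
openpose_joint_indices <- function(model) {
  switch(model,
    body25 = list(right_hip = 9L, right_knee = 10L, right_ankle = 11L,
                  left_hip = 12L, left_knee = 13L, left_ankle = 14L),
    coco18 = list(right_hip = 8L, right_knee = 9L, right_ankle = 10L,
                  left_hip = 11L, left_knee = 12L, left_ankle = 13L),
    abort(sprintf("Unknown body model '%s'; use 'body25' or 'coco18'.", model))
  )
}

#' Construct a keypoint track
#'
#' A keypoint track is a long tibble with one row per joint per frame:
#' `frame` (0-based), `time_s`, `joint`, `x`, `y` (pixels, y-down image
#' coordinates), `confidence` in [0, 1], and a logical `missing` mask.
#' Every joint covers every frame in the track's frame range.
#'
#' @param df Data frame with columns `frame`, `joint`, `x`, `y`,
#'   `confidence`, and optionally `missing`.
#' @param fps Frames per second (positive).
#' @param subject_id Optional label.
#' @return A `keypoint_track` tibble.
#' @export
new_keypoint_track <- function(df, fps, subject_id = NULL) {
  if (!is.numeric(fps) || fps <= 0) abort("`fps` must be a positive number.")
  req <- c("frame", "joint", "x", "y", "confidence")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    abort(sprintf("Track is missing column(s): %s.", paste(miss, collapse = ", ")))
  }
  for (col in c("frame", "x", "y", "confidence")) {
    if (!is.numeric(df[[col]])) {
      abort(sprintf("Column '%s' must be numeric.", col))
    }
  }
  if (!"missing" %in% names(df)) df$missing <- FALSE
  df$missing <- df$missing | !is.finite(df$x) | !is.finite(df$y)
  if (any(df$confidence < 0 | df$confidence > 1, na.rm = TRUE)) {
    abort("Confidence values must lie in [0, 1].")
  }
  if (nrow(df) == 0) abort("Track has zero frames.")
  # complete the frame x joint grid; absent pairs are missing
  frames <- seq(min(df$frame), max(df$frame))
  full <- tidyr::complete(
    tibble::as_tibble(df),
    frame = frames, joint = unique(df$joint),
    fill = list(x = NA_real_, y = NA_real_, confidence = 0, missing = TRUE)
  )
  full <- dplyr::arrange(full, .data$joint, .data$frame)
  full$time_s <- full$frame / fps
  full <- dplyr::select(full, "frame", "time_s", "joint", "x", "y",
                        "confidence", "missing")
  structure(
    full,
    class = c("keypoint_track", class(tibble::tibble())),
    fps = fps,
    subject_id = subject_id
  )
}

#' Read OpenPose-style per-frame JSON keypoints
#'
#' Reads a directory of per-frame JSON files (or a single file), each
#' following the OpenPose dialect: `people[[k]]$pose_keypoints_2d` is a flat
#' list of x, y, confidence triples in body-model order. Person index 1 is
#' taken (study recordings are single-subject); frames with no detected
#' person are marked missing with confidence 0. Only the six lower-limb
#' joints (hip, knee, ankle, both sides) are retained.
#'
#' @param path Directory of `*.json` files (read in sorted name order) or a
#'   single JSON file.
#' @param fps Frames per second (default 30).
#' @param model Keypoint ordering: `"body25"` (default) or `"coco18"`.
#' @param subject_id Optional label.
#' @return A `keypoint_track`.
#' @export
read_openpose_json <- function(path, fps = 30, model = c("body25", "coco18"),
                               subject_id = NULL) {
  if (length(model) == 1 && !model %in% c("body25", "coco18")) {
    abort(sprintf("Unknown body model '%s'; use 'body25' or 'coco18'.", model))
  }
  model <- match.arg(model)
  files <- if (dir.exists(path)) {
    sort(list.files(path, pattern = "\\.json$", full.names = TRUE))
  } else if (file.exists(path)) {
    path
  } else {
    abort(sprintf("Path '%s' does not exist.", path))
  }
  if (length(files) == 0) abort(sprintf("No JSON frame files under '%s'.", path))
  idx_map <- openpose_joint_indices(model)

  rows <- purrr::map(seq_along(files), function(i) {
    obj <- tryCatch(
      jsonlite::read_json(files[i]),
      error = function(e) {
        abort(sprintf("Malformed JSON in '%s': %s", files[i], conditionMessage(e)))
      }
    )
    frame <- i - 1L
    if (length(obj$people) == 0) {
      return(tibble::tibble(
        frame = frame, joint = names(idx_map),
        x = NA_real_, y = NA_real_, confidence = 0, missing = TRUE
      ))
    }
    kp <- unlist(obj$people[[1]]$pose_keypoints_2d)
    purrr::map_dfr(names(idx_map), function(jn) {
      k <- idx_map[[jn]] * 3L
      tibble::tibble(
        frame = frame, joint = jn,
        x = kp[k + 1L], y = kp[k + 2L],
        confidence = kp[k + 3L],
        missing = kp[k + 3L] == 0
      )
    })
  })
  new_keypoint_track(dplyr::bind_rows(rows), fps = fps, subject_id = subject_id)
}

#' Read a flat keypoint CSV
#'
#' Expects columns `frame`, `joint`, `x`, `y`, `confidence`, one row per
#' joint per frame; (frame, joint) pairs without a row are marked missing.
#'
#' @param path CSV file path.
#' @param fps Frames per second.
#' @param subject_id Optional label.
#' @return A `keypoint_track`.
#' @export
read_keypoint_csv <- function(path, fps = 30, subject_id = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("frame", "joint", "x", "y", "confidence")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    abort(sprintf("CSV '%s' is missing column(s): %s.",
                  path, paste(miss, collapse = ", ")))
  }
  for (col in c("frame", "x", "y", "confidence")) {
    if (!is.numeric(df[[col]])) {
      abort(sprintf("Column '%s' in '%s' is not numeric.", col, path))
    }
  }
  new_keypoint_track(df, fps = fps, subject_id = subject_id)
}

#' Write a keypoint track to the flat CSV format
#' @param track A `keypoint_track`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_keypoint_csv <- function(track, path) {
  out <- dplyr::select(track[!track$missing, ],
                       "frame", "joint", "x", "y", "confidence")
  readr::write_csv(out, path)
  invisible(path)
}

#' Mark low-confidence detections as missing
#'
#' Joint detections with confidence below the threshold (default 0.5, the
#' conventional pose-estimator operating point) are flagged missing.
#' Coordinates are retained. The returned track carries a `survival`
#' attribute: the per-joint fraction of frames still valid. Idempotent at a
#' fixed threshold.
#'
#' @param track A `keypoint_track`.
#' @param threshold Confidence threshold in [0, 1] (default 0.5).
#' @return A filtered `keypoint_track`.
#' @export
filter_by_confidence <- function(track, threshold = 0.5) {
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1) {
    abort("`threshold` must lie in [0, 1].")
  }
  track$missing <- track$missing | track$confidence < threshold
  surv <- dplyr::summarise(dplyr::group_by(track, .data$joint),
                           survival = mean(!.data$missing))
  attr(track, "survival") <- surv
  attr(track, "conf_threshold") <- threshold
  track
}

#' Fill short missing runs by linear interpolation
#'
#' Missing runs up to `max_gap_s` long with valid flanking frames on both
#' sides are filled per coordinate by linear interpolation; longer runs and
#' leading/trailing runs (which would require extrapolation) stay missing and
#' are listed in the `gap_report` attribute. Non-missing samples are never
#' altered.
#'
#' @param track A `keypoint_track`.
#' @param max_gap_s Longest gap to fill, seconds (default 0.5 — short
#'   occlusions are brief relative to a stride).
#' @return A `keypoint_track` with a `gap_report` attribute (tibble of
#'   unfilled gaps: `joint`, `start_s`, `end_s`, `duration_s`).
#' @export
interpolate_gaps <- function(track, max_gap_s = 0.5) {
  fps <- attr(track, "fps")
  max_frames <- max_gap_s * fps
  pieces <- split(seq_len(nrow(track)), track$joint)
  unfilled <- list()
  for (jn in names(pieces)) {
    ri <- pieces[[jn]]
    sub <- track[ri, ]
    valid <- !sub$missing
    if (sum(valid) < 2) {
      abort(sprintf("Joint '%s' has fewer than 2 valid frames; unusable.", jn),
            class = "gaithht_unusable_joint")
    }
    r <- rle(sub$missing)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      s <- starts[k]; e <- ends[k]
      interior <- s > 1 && e < nrow(sub)
      if (interior && r$lengths[k] <= max_frames) {
        for (col in c("x", "y")) {
          x0 <- sub[[col]][s - 1L]; x1 <- sub[[col]][e + 1L]
          w <- seq_len(r$lengths[k]) / (r$lengths[k] + 1L)
          track[ri[s:e], col] <- x0 + w * (x1 - x0)
        }
        track$missing[ri[s:e]] <- FALSE
      } else {
        unfilled[[length(unfilled) + 1L]] <- tibble::tibble(
          joint = jn,
          start_s = sub$time_s[s],
          end_s = sub$time_s[e] + 1 / fps,
          duration_s = r$lengths[k] / fps
        )
      }
    }
  }
  attr(track, "gap_report") <- if (length(unfilled)) {
    dplyr::bind_rows(unfilled)
  } else {
    tibble::tibble(joint = character(0), start_s = numeric(0),
                   end_s = numeric(0), duration_s = numeric(0))
  }
  track
}

#' Per-joint confidence summary and empirical density
#'
#' @param tracks A `keypoint_track` or a list of them.
#' @param n_bins Bins for the empirical density over [0, 1] (default 50).
#' @return A list with `summary` (tibble: `track`, `joint`, `mean`, `min`,
#'   `max`) and `density` (tibble: `joint`, `mid`, `density`; the density is
#'   a normalized histogram over [0, 1] pooled across tracks, integrating
#'   to 1).
#' @export
confidence_summary <- function(tracks, n_bins = 50) {
  if (inherits(tracks, "keypoint_track")) tracks <- list(tracks)
  if (length(tracks) == 0) abort("Need at least one track.")
  all_df <- dplyr::bind_rows(purrr::imap(tracks, function(tr, i) {
    id <- attr(tr, "subject_id") %||% as.character(i)
    dplyr::mutate(tibble::as_tibble(tr)[, c("joint", "confidence")], track = id)
  }))
  summary <- dplyr::summarise(
    dplyr::group_by(all_df, .data$track, .data$joint),
    mean = mean(.data$confidence),
    min = min(.data$confidence),
    max = max(.data$confidence),
    .groups = "drop"
  )
  edges <- seq(0, 1, length.out = n_bins + 1)
  width <- 1 / n_bins
  density <- dplyr::bind_rows(lapply(split(all_df, all_df$joint), function(d) {
    bin <- findInterval(d$confidence, edges, rightmost.closed = TRUE,
                        all.inside = TRUE)
    counts <- tabulate(bin, nbins = n_bins)
    tibble::tibble(
      joint = d$joint[1],
      mid = (edges[-1] + edges[-length(edges)]) / 2,
      density = counts / (sum(counts) * width)
    )
  }))
  list(summary = summary, density = density)
}
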