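pipeline_defaults <- list(
  fps = 30,
  conf_threshold = 0.5,
  max_gap_s = 0.5,
  side = "left",
  max_imfs = 8,
  sd_threshold = 0.2,
  max_sifts = 50,
  n_freq_bins = 64,
  energy_window_s = 1,
  rel_threshold = 0.5,
  min_duration_s = 1,
  imf_index = 6,
  feature_window_s = 2,
  feature_hop_s = 1,
  model = "rf",
  seed = 17
)

#' Pipeline configuration
#'
#' Validated bundle of every stage's tunable parameters at its documented
#' default: confidence threshold 0.5, 30 fps sampling, Cauchy sift threshold
#' 0.2 with at most 50 sifts and 8 IMFs, 64 frequency bins, 1 s energy
#' window, transition threshold at 0.5 x median energy with a 1 s duration
#' floor, the 6th IMF as the feature component, 2 s / 1 s feature windows,
#' and a random-forest classifier. Unknown keys are rejected.
#'
#' @param ... Named overrides of the defaults.
#' @return A `gait_config` list.
#' @export
gait_config <- function(...) {
  over <- list(...)
  unknown <- setdiff(names(over), names(pipeline_defaults))
  if (length(unknown)) {
    abort(sprintf("Unknown configuration key(s): %s.",
                  paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(pipeline_defaults, over)
  stopifnot_cfg <- function(ok, msg) if (!ok) abort(msg)
  stopifnot_cfg(cfg$conf_threshold >= 0 && cfg$conf_threshold <= 1,
                "conf_threshold must lie in [0, 1].")
  stopifnot_cfg(cfg$fps > 0, "fps must be positive.")
  stopifnot_cfg(cfg$rel_threshold > 0, "rel_threshold must be positive.")
  stopifnot_cfg(cfg$max_imfs >= 1, "max_imfs must be at least 1.")
  stopifnot_cfg(cfg$side %in% c("left", "right"), "side must be left or right.")
  stopifnot_cfg(cfg$model %in% c("rf", "knn"), "model must be rf or knn.")
  structure(cfg, class = "gait_config")
}

# One subject through filter -> interpolate -> angle -> EMD -> energy ->
# transitions -> features.
process_track <- function(track, cfg) {
  track <- filter_by_confidence(track, cfg$conf_threshold)
  track <- interpolate_gaps(track, cfg$max_gap_s)
  signal <- build_gait_signal(track, side = cfg$side)
  process_signal(signal, cfg)
}

process_signal <- function(signal, cfg) {
  dec <- emd(signal, max_imfs = cfg$max_imfs, sd_threshold = cfg$sd_threshold,
             max_sifts = cfg$max_sifts)
  attr(dec, "subject_id") <- attr(signal, "subject_id")
  trace <- energy_trace(dec, window_s = cfg$energy_window_s)
  segments <- detect_transitions(trace, rel_threshold = cfg$rel_threshold,
                                 min_duration_s = cfg$min_duration_s)
  features <- extract_features(dec, trace, segments,
                               imf_index = cfg$imf_index,
                               window_s = cfg$feature_window_s,
                               hop_s = cfg$feature_hop_s,
                               subject_id = attr(signal, "subject_id"))
  list(signal = signal, imfset = dec, trace = trace, segments = segments,
       features = features)
}

#' Run the full gait-analysis pipeline
#'
#' Executes read/filter/interpolate -> knee angles -> empirical mode
#' decomposition -> Hilbert energy -> transition detection -> windowed
#' features, and optionally trains and evaluates a classifier when labels
#' are supplied (resubstitution on the provided subjects; windows inherit
#' their subject's label). Any stage failure is re-signalled with the stage
#' and subject named.
#'
#' @param input A `keypoint_track`, a `gait_signal`, a list of either, or a
#'   directory containing per-subject keypoint CSVs (`*.csv`) and/or
#'   subdirectories of OpenPose-style frame JSON.
#' @param config A [gait_config()].
#' @param labels Optional named character vector of class labels keyed by
#'   subject id (or unnamed, in input order).
#' @return A `gait_run` list: `manifest`, `features` (one row per window),
#'   per-subject `segments`, `imfsets`, `traces`, and — when labels are given
#'   — `classifier` and `report`.
#' @export
run_pipeline <- function(input, config = gait_config(), labels = NULL) {
  if (!inherits(config, "gait_config")) abort("`config` must be a gait_config().")
  items <- collect_inputs(input, config)
  if (length(items) == 0) abort("No inputs found.")

  results <- purrr::imap(items, function(item, id) {
    tryCatch(
      {
        if (inherits(item, "keypoint_track")) process_track(item, config)
        else if (inherits(item, "gait_signal")) process_signal(item, config)
        else abort("Inputs must be keypoint_track or gait_signal objects.")
      },
      error = function(e) {
        abort(sprintf("Pipeline failed for subject '%s': %s",
                      id, conditionMessage(e)), parent = e)
      }
    )
  })

  features <- dplyr::bind_rows(purrr::map(results, "features"))
  manifest <- list(
    config = unclass(config),
    n_subjects = length(results),
    subjects = names(results),
    n_feature_rows = nrow(features),
    n_imfs = purrr::map_int(results, ~ n_imfs(.x$imfset)),
    n_segments = purrr::map_int(results, ~ nrow(.x$segments)),
    package_version = as.character(utils::packageVersion("gaithht"))
  )

  out <- list(
    manifest = manifest,
    features = features,
    segments = purrr::map(results, "segments"),
    imfsets = purrr::map(results, "imfset"),
    traces = purrr::map(results, "trace")
  )

  if (!is.null(labels)) {
    lab <- if (is.null(names(labels))) {
      setNames(labels, names(results))
    } else {
      labels
    }
    row_labels <- lab[features$subject_id]
    if (anyNA(row_labels)) abort("Labels missing for some subjects.")
    clf <- train_classifier(features, row_labels, model = config$model,
                            seed = config$seed)
    preds <- predict(clf, features)
    out$classifier <- clf
    out$report <- evaluate(preds, row_labels)
    manifest$model <- config$model
    out$manifest <- manifest
  }
  structure(out, class = "gait_run")
}

collect_inputs <- function(input, cfg) {
  if (inherits(input, c("keypoint_track", "gait_signal"))) {
    input <- list(input)
  }
  if (is.character(input) && length(input) == 1) {
    if (!dir.exists(input)) abort(sprintf("Input directory '%s' not found.", input))
    csvs <- sort(list.files(input, pattern = "\\.csv$", full.names = TRUE))
    dirs <- sort(list.dirs(input, recursive = FALSE))
    items <- c(
      lapply(csvs, function(p) {
        read_keypoint_csv(p, fps = cfg$fps,
                          subject_id = tools::file_path_sans_ext(basename(p)))
      }),
      lapply(dirs, function(d) {
        read_openpose_json(d, fps = cfg$fps, subject_id = basename(d))
      })
    )
    input <- items
  }
  ids <- purrr::imap_chr(input, function(item, i) {
    attr(item, "subject_id") %||% paste0("subject_", i)
  })
  setNames(input, ids)
}

#' @export
print.gait_run <- function(x, ...) {
  m <- x$manifest
  cat("<gait_run>", m$n_subjects, "subject(s),",
      m$n_feature_rows, "feature window(s)\n")
  cat("  IMFs per subject:", paste(m$n_imfs, collapse = ", "), "\n")
  cat("  segments per subject:", paste(m$n_segments, collapse = ", "), "\n")
  if (!is.null(x$report)) {
    cat("  classification report:\n")
    print(tibble::as_tibble(x$report))
  }
  invisible(x)
}
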