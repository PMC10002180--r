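#' Extract a feature table from a decomposition, energy trace and segments
#'
#' Features follow the pipeline's design: statistics of one configured IMF
#' (default the 6th — the slow component whose level drops during turning),
#' statistics of the Hilbert energy trace, and turn features from the
#' detected transition segments. With `window_s` set, the signal is cut into
#' overlapping windows (default hop 1 s) and one feature row is produced per
#' window, which is the sampling unit for classification; otherwise a single
#' row summarises the whole signal.
#'
#' Per-row features: `imf_mean`, `imf_sd`, `imf_rms`, `imf_domfreq` (median
#' defined instantaneous frequency of the configured IMF, Hz), `energy_mean`,
#' `energy_min`, `energy_sd`, `turn_frac` (fraction of the window inside a
#' detected turn), plus signal-level `turn_max_s` and `turn_count`.
#'
#' @param imfset A `gait_imf`.
#' @param trace An `energy_trace` for the same signal.
#' @param segments A `gait_segments` tibble.
#' @param imf_index Which IMF to summarise (default 6; falls back to the last
#'   available IMF with a warning).
#' @param window_s Window length in seconds, or `NULL` for one row.
#' @param hop_s Window hop in seconds (default 1).
#' @param subject_id Row label (defaults to the decomposition's, if any).
#' @return A tibble, one row per window.
#' @export
extract_features <- function(imfset, trace, segments, imf_index = 6,
                             window_s = NULL, hop_s = 1, subject_id = NULL) {
  k <- n_imfs(imfset)
  if (k == 0) abort("Decomposition has no IMFs; cannot extract features.")
  if (imf_index > k) {
    warn(sprintf("Requested IMF %d but only %d available; using IMF %d.",
                 imf_index, k, k))
    imf_index <- k
  }
  fps <- attr(imfset, "fps")
  subject_id <- subject_id %||% attr(imfset, "subject_id") %||% "signal"
  comp <- imfset[[paste0("imf_", imf_index)]]
  at <- instantaneous_attributes(comp, fps)
  E <- trace$energy
  n <- length(comp)
  td <- turn_durations(segments)
  in_turn <- rep(FALSE, n)
  if (td$count > 0) {
    for (i in seq_len(nrow(segments))) {
      lo <- max(1L, floor(segments$start_s[i] * fps) + 1L)
      hi <- min(n, ceiling(segments$end_s[i] * fps))
      in_turn[lo:hi] <- TRUE
    }
  }

  windows <- if (is.null(window_s)) {
    tibble::tibble(lo = 1L, hi = n)
  } else {
    wlen <- round(window_s * fps)
    hop <- max(1L, round(hop_s * fps))
    starts <- seq(1L, max(1L, n - wlen + 1L), by = hop)
    tibble::tibble(lo = starts, hi = pmin(n, starts + wlen - 1L))
  }

  purrr::pmap_dfr(windows, function(lo, hi) {
    seg <- comp[lo:hi]
    freqs <- at$inst_freq[lo:hi]
    domfreq <- median(freqs, na.rm = TRUE)
    tibble::tibble(
      subject_id = subject_id,
      window_start_s = (lo - 1) / fps,
      imf_mean = mean(seg),
      imf_sd = sd(seg),
      imf_rms = sqrt(mean(seg^2)),
      imf_domfreq = if (is.finite(domfreq)) domfreq else 0,
      energy_mean = mean(E[lo:hi]),
      energy_min = min(E[lo:hi]),
      energy_sd = sd(E[lo:hi]),
      turn_frac = mean(in_turn[lo:hi]),
      turn_max_s = td$max,
      turn_count = td$count
    )
  })
}

feature_columns <- function(features) {
  keep <- vapply(features, is.numeric, logical(1))
  keep["window_start_s"] <- FALSE
  names(features)[keep]
}

#' Train a gait classifier
#'
#' Fits either a random forest (default; the evaluation classifier) or a
#' k-nearest-neighbour model (the alternative named in the pipeline design)
#' on a numeric feature table. Features are standardized with the training
#' set's mean and SD before KNN. Training is deterministic given `seed`.
#'
#' @param features Tibble of feature rows (non-numeric columns and
#'   `window_start_s` are ignored as predictors).
#' @param labels Class labels, one per row (e.g. `"NW"`, `"OW"`, `"PD"`).
#' @param model `"rf"` (default, 100 trees) or `"knn"` (k = 5).
#' @param seed Integer seed.
#' @param trees Random-forest tree count.
#' @param k KNN neighbour count.
#' @return A `gait_classifier` object with a [predict()] method.
#' @export
train_classifier <- function(features, labels, model = c("rf", "knn"),
                             seed = 1, trees = 100, k = 5) {
  model <- match.arg(model)
  labels <- factor(labels)
  if (nrow(features) != length(labels)) {
    abort("`features` and `labels` lengths differ.")
  }
  if (nlevels(droplevels(labels)) < 2) {
    abort("Training needs at least two classes.")
  }
  cols <- feature_columns(features)
  X <- as.matrix(as.data.frame(features)[cols])
  center <- colMeans(X)
  scale_ <- apply(X, 2, sd)
  scale_[scale_ == 0 | !is.finite(scale_)] <- 1
  Xs <- scale(X, center = center, scale = scale_)
  fit <- if (model == "rf") {
    with_seed(seed, randomForest::randomForest(
      x = Xs, y = droplevels(labels), ntree = trees
    ))
  } else {
    NULL # KNN is lazy: training data is the model
  }
  structure(
    list(
      model = model, fit = fit,
      train_x = Xs, train_y = droplevels(labels),
      center = center, scale = scale_, columns = cols,
      k = k, trees = trees, seed = seed
    ),
    class = "gait_classifier"
  )
}

#' Predict gait classes
#' @param object A `gait_classifier`.
#' @param newdata Feature tibble with the training columns.
#' @param ... Unused.
#' @return Factor of predicted labels.
#' @export
predict.gait_classifier <- function(object, newdata, ...) {
  X <- as.matrix(as.data.frame(newdata)[object$columns])
  Xs <- scale(X, center = object$center, scale = object$scale)
  if (object$model == "rf") {
    predict(object$fit, Xs)
  } else {
    # seed the vote tie-break so prediction is deterministic
    with_seed(object$seed, class::knn(
      train = object$train_x, test = Xs, cl = object$train_y, k = object$k
    ))
  }
}

#' Per-class true-positive and false-negative rates
#'
#' For each class present in the truth labels: `TPR = TP / (TP + FN)` and
#' `FNR = FN / (TP + FN) = 1 - TPR`. Classes absent from the truth get
#' `NA` rates (not 0 — the rate is undefined there).
#'
#' @param predictions,truth Equal-length label vectors or factors.
#' @return A `gait_class_report` tibble with columns `class`, `tp`, `fn`,
#'   `tpr`, `fnr`.
#' @export
evaluate <- function(predictions, truth) {
  if (length(predictions) != length(truth)) {
    abort("`predictions` and `truth` lengths differ.")
  }
  if (length(truth) < 1) abort("Need at least one pair.")
  predictions <- as.character(predictions)
  truth <- as.character(truth)
  classes <- sort(unique(c(predictions, truth)))
  rows <- purrr::map_dfr(classes, function(cl) {
    tp <- sum(predictions == cl & truth == cl)
    fn <- sum(predictions != cl & truth == cl)
    pos <- tp + fn
    tibble::tibble(
      class = cl, tp = tp, fn = fn,
      tpr = if (pos > 0) tp / pos else NA_real_,
      fnr = if (pos > 0) fn / pos else NA_real_
    )
  })
  structure(rows,
            class = c("gait_class_report", class(tibble::tibble())))
}
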