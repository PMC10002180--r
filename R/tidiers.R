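#' Tidy a decomposition into long format
#' @param x A `gait_imf`.
#' @param ... Unused.
#' @return Tibble with `time_s`, `component`, `value`; components are the
#'   IMFs in order then the residual.
#' @export
tidy.gait_imf <- function(x, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(x), -"time_s",
                              names_to = "component", values_to = "value")
  long$component <- factor(long$component,
                           levels = c(paste0("imf_", seq_len(n_imfs(x))),
                                      "residual"))
  long
}

#' One-row summary of a decomposition
#' @param x A `gait_imf`.
#' @param ... Unused.
#' @export
glance.gait_imf <- function(x, ...) {
  tibble::tibble(
    n_imfs = n_imfs(x),
    n_samples = attr(x, "source_length"),
    fps = attr(x, "fps"),
    total_sifts = sum(attr(x, "sift_counts")),
    decomposition_stop = attr(x, "decomposition_stop")
  )
}

#' Tidy a Hilbert spectrum into long format
#' @param x A `hilbert_spectrum`.
#' @param ... Unused.
#' @return Tibble with `time_s`, `freq_hz`, `value` (only nonzero cells).
#' @export
tidy.hilbert_spectrum <- function(x, ...) {
  idx <- which(x$H != 0, arr.ind = TRUE)
  tibble::tibble(
    time_s = x$time_s[idx[, 2]],
    freq_hz = x$freq_hz[idx[, 1]],
    value = x$H[idx]
  )
}

#' One-row summary of a gait classifier
#' @param x A `gait_classifier`.
#' @param ... Unused.
#' @export
glance.gait_classifier <- function(x, ...) {
  tibble::tibble(
    model = x$model,
    n_train = nrow(x$train_x),
    n_features = length(x$columns),
    trees = if (x$model == "rf") x$trees else NA_integer_,
    k = if (x$model == "knn") x$k else NA_integer_,
    seed = x$seed
  )
}

#' One-row summary of detected transition segments
#' @param x A `gait_segments` tibble.
#' @param ... Unused.
#' @export
glance.gait_segments <- function(x, ...) {
  td <- turn_durations(x)
  tibble::tibble(count = td$count, max_s = td$max, total_s = td$total)
}

#' @export
print.hilbert_spectrum <- function(x, ...) {
  cat("<hilbert_spectrum>", x$mode, "mode,",
      length(x$freq_hz), "bins x", length(x$time_s), "samples,",
      x$skipped_samples, "undefined sample(s) skipped\n")
  invisible(x)
}
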