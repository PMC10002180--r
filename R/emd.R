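#' Locate interior extrema of a series
#'
#' Finds strict interior local maxima and minima. A flat plateau that is a
#' local extremum contributes the midpoint index of the plateau (integer
#' division), which makes the decomposition fully deterministic.
#'
#' @param x Numeric vector, length at least 3.
#' @return A list with integer vectors `maxima` and `minima` (1-based indices).
#' @examples
#' find_extrema(c(0, 1, 0, -1, 0, 1, 0))
#' @export
find_extrema <- function(x) {
  if (!is.numeric(x) || length(x) < 3) {
    abort("`x` must be a numeric vector of length >= 3.")
  }
  r <- rle(as.numeric(x))
  k <- length(r$values)
  if (k < 3) {
    return(list(maxima = integer(0), minima = integer(0)))
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  mids <- as.integer((starts + ends) %/% 2L)
  v <- r$values
  interior <- 2:(k - 1L)
  is_max <- v[interior] > v[interior - 1L] & v[interior] > v[interior + 1L]
  is_min <- v[interior] < v[interior - 1L] & v[interior] < v[interior + 1L]
  list(
    maxima = mids[interior][is_max],
    minima = mids[interior][is_min]
  )
}

count_zero_crossings <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2) return(0L)
  sum(diff(s) != 0)
}

# A candidate is siftable when both envelopes can be fitted.
is_siftable <- function(extrema) {
  length(extrema$maxima) >= 2 && length(extrema$minima) >= 2
}

# Mirror the two extrema nearest each end across the first/last sample, so the
# envelope spline is anchored beyond the data and end swings are suppressed.
mirror_knots <- function(idx, val, n) {
  m <- min(2L, length(idx))
  left_t <- 2L - idx[seq_len(m)]
  left_v <- val[seq_len(m)]
  right_pick <- seq.int(length(idx), by = -1L, length.out = m)
  right_t <- 2L * n - idx[right_pick]
  right_v <- val[right_pick]
  t_all <- c(left_t, idx, right_t)
  v_all <- c(left_v, val, right_v)
  ord <- order(t_all)
  t_all <- t_all[ord]
  v_all <- v_all[ord]
  keep <- !duplicated(t_all)
  list(t = t_all[keep], v = v_all[keep])
}

#' Upper/lower spline envelopes and their mean
#'
#' Fits natural cubic splines through the interior maxima (upper envelope) and
#' minima (lower envelope). The two extrema nearest each end are mirrored
#' across the boundary sample before fitting, and the mean envelope is
#' `m(t) = (e_max(t) + e_min(t)) / 2` — the local mean that sifting subtracts.
#'
#' @param x Numeric series.
#' @param maxima,minima Integer index vectors as returned by [find_extrema()];
#'   at least two of each are required.
#' @return An object of class `envelope_pair`: list with numeric vectors
#'   `e_max`, `e_min`, `m`, each the length of `x`.
#' @export
envelopes <- function(x, maxima, minima) {
  if (length(maxima) < 2 || length(minima) < 2) {
    abort("Envelope fitting needs at least 2 maxima and 2 minima.",
          class = "gaithht_not_siftable")
  }
  n <- length(x)
  up <- mirror_knots(maxima, x[maxima], n)
  lo <- mirror_knots(minima, x[minima], n)
  e_max <- spline(up$t, up$v, xout = seq_len(n), method = "natural")$y
  e_min <- spline(lo$t, lo$v, xout = seq_len(n), method = "natural")$y
  structure(
    list(e_max = e_max, e_min = e_min, m = (e_max + e_min) / 2),
    class = "envelope_pair"
  )
}

#' One sifting pass
#'
#' Subtracts the mean envelope from the series: `c(t) = x(t) - m(t)`.
#'
#' @param x Numeric series.
#' @return Numeric series `c`, or signals a `gaithht_not_siftable` condition
#'   when the series has too few extrema for envelopes.
#' @export
sift_once <- function(x) {
  ext <- find_extrema(x)
  if (!is_siftable(ext)) {
    abort("Series has too few extrema to sift.", class = "gaithht_not_siftable")
  }
  x - envelopes(x, ext$maxima, ext$minima)$m
}

#' Intrinsic mode function criterion
#'
#' A candidate is accepted as an IMF when (i) it oscillates (has at least one
#' interior maximum and one interior minimum), (ii) its extrema and
#' zero-crossing counts differ by at most one, and (iii) the Cauchy sifting
#' criterion `SD = sum((c_prev - c)^2) / sum(c_prev^2)` from the producing
#' sift loop fell below `sd_threshold`.
#'
#' @param c Numeric candidate series.
#' @param sd SD value from the producing sift iteration (default 0, i.e. the
#'   loop converged; pass the recorded value when checking a live loop).
#' @param sd_threshold Cauchy stopping threshold (default 0.2).
#' @return Logical scalar.
#' @export
is_imf <- function(c, sd = 0, sd_threshold = 0.2) {
  ext <- find_extrema(c)
  n_ext <- length(ext$maxima) + length(ext$minima)
  oscillates <- length(ext$maxima) >= 1 && length(ext$minima) >= 1
  count_ok <- abs(n_ext - count_zero_crossings(c)) <= 1
  oscillates && count_ok && sd < sd_threshold
}

# Inner sift loop: iterate c <- c - m until the IMF criterion and Cauchy SD
# are met, or the sift cap is reached, or the candidate stops being siftable.
sift_to_imf <- function(x, sd_threshold, max_sifts) {
  h <- x
  sifts <- 0L
  repeat {
    ext <- find_extrema(h)
    if (!is_siftable(ext)) {
      # cannot refine further; accept current candidate as-is
      return(list(imf = h, sifts = sifts, stop_reason = "not_siftable"))
    }
    m <- envelopes(h, ext$maxima, ext$minima)$m
    h_new <- h - m
    sifts <- sifts + 1L
    denom <- sum(h^2)
    sd_val <- if (denom > 0) sum((h - h_new)^2) / denom else 0
    h <- h_new
    if (is_imf(h, sd = sd_val, sd_threshold = sd_threshold)) {
      return(list(imf = h, sifts = sifts, stop_reason = "sd_converged"))
    }
    if (sifts >= max_sifts) {
      return(list(imf = h, sifts = sifts, stop_reason = "max_sifts"))
    }
  }
}

#' Empirical mode decomposition
#'
#' Decomposes a signal into intrinsic mode functions (IMFs) by iterated
#' sifting: envelopes through the extrema are averaged and subtracted until
#' the candidate satisfies the IMF criterion, the candidate is recorded as
#' `c_i`, and sifting continues on `x - c_i`. Decomposition stops when the
#' residual has fewer than two interior extrema or `max_imfs` is reached. By
#' construction the IMFs plus the residual reconstruct the input exactly.
#'
#' @param x A `gait_signal` (see [build_gait_signal()]) or a numeric vector.
#' @param max_imfs Maximum number of IMFs to extract (default 8).
#' @param sd_threshold Cauchy sifting threshold (default 0.2).
#' @param max_sifts Cap on sifting passes per IMF (default 50).
#' @param fps Sampling rate in Hz; taken from `x` when it is a `gait_signal`
#'   (default 30 for a bare vector).
#' @return A `gait_imf` tibble with columns `time_s`, `imf_1` .. `imf_N` and
#'   `residual`, carrying attributes `fps`, `sift_counts`, `stop_reason`
#'   (per IMF) and `decomposition_stop`.
#' @examples
#' t <- seq(0, 10, by = 1 / 30)
#' dec <- emd(sin(2 * pi * 2 * t) + sin(2 * pi * 0.2 * t))
#' glance(dec)
#' @export
emd <- function(x, max_imfs = 8, sd_threshold = 0.2, max_sifts = 50, fps = NULL) {
  if (inherits(x, "gait_signal")) {
    fps <- fps %||% attr(x, "fps")
    x <- x$angle_deg
  }
  fps <- fps %||% 30
  x <- as.numeric(x)
  if (length(x) < 8) abort("Signal must have at least 8 samples.")
  if (!all(is.finite(x))) abort("Signal contains non-finite values.")

  imfs <- list()
  sift_counts <- integer(0)
  stop_reasons <- character(0)
  resid <- x
  decomposition_stop <- "residual_extrema"
  while (length(imfs) < max_imfs) {
    ext <- find_extrema(resid)
    if (length(ext$maxima) + length(ext$minima) < 2 || !is_siftable(ext)) {
      decomposition_stop <- "residual_extrema"
      break
    }
    res <- sift_to_imf(resid, sd_threshold, max_sifts)
    imfs[[length(imfs) + 1L]] <- res$imf
    sift_counts <- c(sift_counts, res$sifts)
    stop_reasons <- c(stop_reasons, res$stop_reason)
    resid <- resid - res$imf
    decomposition_stop <- "max_imfs"
  }

  n_imf <- length(imfs)
  out <- tibble::tibble(time_s = (seq_along(x) - 1) / fps)
  if (n_imf > 0) {
    names(imfs) <- paste0("imf_", seq_len(n_imf))
    out <- dplyr::bind_cols(out, tibble::as_tibble(imfs))
  }
  out$residual <- resid
  structure(
    out,
    class = c("gait_imf", class(tibble::tibble())),
    fps = fps,
    source_length = length(x),
    sift_counts = sift_counts,
    stop_reason = stop_reasons,
    decomposition_stop = if (n_imf == max_imfs) "max_imfs" else decomposition_stop
  )
}

#' Number of IMFs in a decomposition
#' @param imfset A `gait_imf` object.
#' @return Integer count (residual excluded).
#' @export
n_imfs <- function(imfset) {
  sum(grepl("^imf_\\d+$", names(imfset)))
}

# IMF columns as a plain matrix (time in rows), residual excluded.
imf_matrix <- function(imfset) {
  cols <- grep("^imf_\\d+$", names(imfset), value = TRUE)
  as.matrix(as.data.frame(imfset)[cols])
}
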