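#' Analytic signal via the frequency domain
#'
#' Builds the complex analytic extension of a real series: forward FFT, zero
#' the negative frequencies, double the positive ones (DC and Nyquist kept
#' single), inverse FFT. The real part equals the input to numerical
#' precision; the imaginary part is the Hilbert transform.
#'
#' @param c Numeric series, length at least 4, all finite.
#' @return Complex vector the length of `c`.
#' @export
analytic_signal <- function(c) {
  if (!is.numeric(c) || length(c) < 4) abort("Series must be numeric, length >= 4.")
  if (!all(is.finite(c))) abort("Series contains non-finite values.")
  n <- length(c)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  fft(fft(c) * h, inverse = TRUE) / n
}

#' Instantaneous amplitude, phase and frequency of a component
#'
#' Amplitude is the modulus of the analytic signal; phase is the unwrapped
#' argument; instantaneous frequency is the phase derivative
#' (central differences, one-sided at the ends) divided by 2*pi, clipped to
#' the physical band `[0, fps/2]`. Samples where the amplitude is below
#' 1e-12 have undefined phase, so their frequency is reported as `NA`.
#'
#' @param c Numeric series (one IMF).
#' @param fps Sampling rate in Hz.
#' @return An `analytic_attributes` tibble with columns `time_s`,
#'   `amplitude`, `phase`, `inst_freq`; attribute `clip_fraction` records the
#'   fraction of defined samples that hit the `[0, fps/2]` clip.
#' @export
instantaneous_attributes <- function(c, fps) {
  if (!is.numeric(fps) || fps <= 0) abort("`fps` must be a positive number.")
  z <- analytic_signal(c)
  n <- length(z)
  amplitude <- Mod(z)
  phase <- signal::unwrap(Arg(z))
  dphase <- numeric(n)
  dphase[1] <- phase[2] - phase[1]
  dphase[n] <- phase[n] - phase[n - 1]
  if (n > 2) {
    dphase[2:(n - 1)] <- (phase[3:n] - phase[1:(n - 2)]) / 2
  }
  inst_freq <- dphase * fps / (2 * pi)
  clipped <- inst_freq < 0 | inst_freq > fps / 2
  inst_freq <- pmin(pmax(inst_freq, 0), fps / 2)
  undefined <- amplitude < 1e-12
  inst_freq[undefined] <- NA_real_
  structure(
    tibble::tibble(
      time_s = (seq_len(n) - 1) / fps,
      amplitude = amplitude,
      phase = phase,
      inst_freq = inst_freq
    ),
    class = c("analytic_attributes", class(tibble::tibble())),
    fps = fps,
    clip_fraction = mean(clipped[!undefined])
  )
}

#' Hilbert amplitude/energy spectrum of a decomposition
#'
#' For each IMF and each time sample, deposits the instantaneous amplitude
#' (or squared amplitude in energy mode) into the uniform frequency bin
#' containing the instantaneous frequency. The residual is excluded;
#' samples with undefined frequency are skipped and counted.
#'
#' @param imfset A `gait_imf` object with at least one IMF.
#' @param fps Sampling rate in Hz (defaults to the decomposition's).
#' @param n_freq_bins Number of uniform bins over `[0, fps/2]` (default 64).
#' @param mode `"energy"` (squared amplitude, default) or `"amplitude"`.
#' @return A `hilbert_spectrum` object: list with `time_s`, `freq_hz` (bin
#'   centers), the nonnegative matrix `H` (frequency rows x time columns),
#'   `edges`, `mode` and the skipped-sample count.
#' @export
hilbert_spectrum <- function(imfset, fps = NULL, n_freq_bins = 64,
                             mode = c("energy", "amplitude")) {
  mode <- match.arg(mode)
  fps <- fps %||% attr(imfset, "fps")
  if (n_freq_bins < 2) abort("`n_freq_bins` must be at least 2.")
  M <- imf_matrix(imfset)
  if (ncol(M) < 1) abort("Decomposition has no IMFs.")
  n <- nrow(M)
  edges <- seq(0, fps / 2, length.out = n_freq_bins + 1)
  H <- matrix(0, nrow = n_freq_bins, ncol = n)
  skipped <- 0L
  for (j in seq_len(ncol(M))) {
    at <- instantaneous_attributes(M[, j], fps)
    ok <- !is.na(at$inst_freq)
    skipped <- skipped + sum(!ok)
    bin <- findInterval(at$inst_freq[ok], edges, rightmost.closed = TRUE,
                        all.inside = TRUE)
    w <- if (mode == "energy") at$amplitude[ok]^2 else at$amplitude[ok]
    tt <- which(ok)
    H[cbind(bin, tt)] <- H[cbind(bin, tt)] + w
  }
  structure(
    list(
      time_s = (seq_len(n) - 1) / fps,
      freq_hz = (edges[-1] + edges[-length(edges)]) / 2,
      H = H,
      edges = edges,
      mode = mode,
      skipped_samples = skipped
    ),
    class = "hilbert_spectrum"
  )
}

# Centered moving average preserving length; partial windows at the edges.
moving_average <- function(x, w) {
  if (w <= 1) return(x)
  n <- length(x)
  half <- (w - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(1L, i - half)
  hi <- pmin(n, i + half)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Time-resolved Hilbert energy trace
#'
#' `E(t) = sum_j a_j(t)^2` over the included IMFs (the residual trend is
#' never included), optionally smoothed with a centered moving average so
#' that within-stride oscillation is averaged out while multi-second turns
#' remain resolved.
#'
#' @param imfset A `gait_imf` object.
#' @param fps Sampling rate in Hz (defaults to the decomposition's).
#' @param included_imfs Integer indices of IMFs to include (default all).
#' @param window_s Moving-average window in seconds (default 1; 0 disables).
#' @return An `energy_trace` tibble with columns `time_s`, `energy`.
#' @export
energy_trace <- function(imfset, fps = NULL, included_imfs = NULL, window_s = 1) {
  fps <- fps %||% attr(imfset, "fps")
  M <- imf_matrix(imfset)
  if (ncol(M) < 1) abort("Decomposition has no IMFs.")
  included_imfs <- included_imfs %||% seq_len(ncol(M))
  if (length(included_imfs) == 0) abort("`included_imfs` must not be empty.")
  if (any(included_imfs < 1 | included_imfs > ncol(M))) {
    abort(sprintf("IMF indices must be in 1..%d.", ncol(M)))
  }
  E <- rowSums(sapply(included_imfs, function(j) {
    Mod(analytic_signal(M[, j]))^2
  }))
  if (window_s > 0) {
    w <- 2L * (floor(window_s * fps) %/% 2L) + 1L
    E <- moving_average(E, w)
  }
  structure(
    tibble::tibble(time_s = (seq_len(nrow(M)) - 1) / fps, energy = E),
    class = c("energy_trace", class(tibble::tibble())),
    fps = fps,
    included_imfs = included_imfs,
    window_s = window_s
  )
}
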