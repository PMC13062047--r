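#' Canonical frequency bands
#'
#' The delta band appears twice on purpose: 0.5--4 Hz is the display and
#' classification band; 0.9--3.9 Hz over a 0.9--99 Hz total is the band
#' used by the reported delta ratio. The two are never conflated.
#'
#' @export
SPECTRAL_BANDS <- list(
  delta_display = c(0.5, 4),
  delta_ratio_numerator = c(0.9, 3.9),
  theta = c(4, 8),
  total = c(0.9, 99)
)

# One-sided periodogram density for each column of a segment matrix
# (segments already detrended). density integrates (sum * df) to the
# windowed mean square: P[k] = |X[k]|^2 / (fs * sum(w^2)), doubled except
# at DC and Nyquist.
periodogram_matrix <- function(segs, fs) {
  L <- nrow(segs)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / L)   # periodic Hann
  U <- sum(w^2)
  X <- stats::mvfft(segs * w)
  half <- floor(L / 2) + 1L
  P <- (Mod(X[seq_len(half), , drop = FALSE])^2) / (fs * U)
  scale <- rep(2, half)
  scale[1] <- 1
  if (L %% 2 == 0) scale[half] <- 1
  P * scale
}

# split a vector into detrended (mean-removed) overlapping segments
segment_matrix <- function(x, L, step) {
  starts <- seq(1, length(x) - L + 1, by = step)
  segs <- vapply(starts, function(s) x[s:(s + L - 1)], numeric(L))
  segs <- as.matrix(segs)
  sweep(segs, 2, colMeans(segs))
}

new_psd <- function(freqs, density, fs, segment_length_s, overlap, window,
                    source_window) {
  structure(list(freqs_hz = freqs, density = density,
                 sample_rate_hz = fs,
                 segment_length_s = segment_length_s,
                 overlap_fraction = overlap, window_name = window,
                 source_window = source_window),
            class = "psd_estimate")
}

#' @export
print.psd_estimate <- function(x, ...) {
  df <- x$freqs_hz[2] - x$freqs_hz[1]
  cat(sprintf(paste0("<psd_estimate> %d bins, 0-%.1f Hz (df = %.3g Hz), ",
                     "%gs %s segments, overlap %.0f%%\n"),
              length(x$freqs_hz), max(x$freqs_hz), df, x$segment_length_s,
              x$window_name, 100 * x$overlap_fraction))
  invisible(x)
}

#' Welch power spectral density of a recording window
#'
#' Averages one-sided periodograms of Hann-windowed, 50%-overlapped
#' segments; each segment is mean-removed before windowing so no DC
#' leaks into the delta band. Scaling satisfies the Parseval contract:
#' the integral of the density over frequency equals the mean square of
#' the (detrended) input. The 5-s default segment matches the scoring
#' epoch and gives 0.2 Hz resolution; a 30-s analysis window yields 11
#' overlapped segments.
#'
#' @param recording a [signal_recording].
#' @param channel channel name.
#' @param window `c(start_s, duration_s)` within the recording.
#' @param segment_length_s Welch segment length, seconds.
#' @param overlap_fraction fractional segment overlap.
#' @return a `psd_estimate` (density in uV^2/Hz on a 0--Nyquist grid).
#' @export
compute_psd <- function(recording, channel, window = NULL,
                        segment_length_s = 5, overlap_fraction = 0.5) {
  stopifnot(inherits(recording, "signal_recording"))
  if (!channel %in% names(recording$channels)) {
    stop("no channel named '", channel, "' in recording")
  }
  fs <- recording$sample_rate_hz
  x <- recording$channels[[channel]]
  if (is.null(window)) window <- c(0, length(x) / fs)
  start_s <- window[1]; dur_s <- window[2]
  if (start_s < 0 || start_s + dur_s > length(x) / fs + 1e-9) {
    stop("analysis window [", start_s, ", ", start_s + dur_s,
         "] falls outside the recording")
  }
  if (dur_s < segment_length_s) {
    stop("window duration (", dur_s, " s) is shorter than one segment (",
         segment_length_s, " s)")
  }
  i0 <- round(start_s * fs)
  x <- x[(i0 + 1):(i0 + round(dur_s * fs))]
  L <- round(segment_length_s * fs)
  step <- max(1L, round(L * (1 - overlap_fraction)))
  P <- rowMeans(periodogram_matrix(segment_matrix(x, L, step), fs))
  freqs <- seq(0, fs / 2, length.out = floor(L / 2) + 1L)
  new_psd(freqs, P, fs, segment_length_s, overlap_fraction, "hann",
          c(start_s, dur_s))
}

#' Integrated band power of a PSD
#'
#' Sums `density * bin_width` over bins whose center frequency lies in
#' the closed interval `[lo_hz, hi_hz]` (bin-center convention: with the
#' default 0.2 Hz grid the 0.9--3.9 Hz ratio band effectively spans bins
#' 1.0 through 3.8 Hz).
#'
#' @param psd a `psd_estimate`.
#' @param lo_hz,hi_hz band edges, Hz.
#' @return band power in uV^2.
#' @export
band_power <- function(psd, lo_hz, hi_hz) {
  stopifnot(inherits(psd, "psd_estimate"), lo_hz < hi_hz)
  df <- psd$freqs_hz[2] - psd$freqs_hz[1]
  sel <- psd$freqs_hz >= lo_hz - 1e-9 & psd$freqs_hz <= hi_hz + 1e-9
  if (!any(sel)) {
    stop("no frequency bins in [", lo_hz, ", ", hi_hz,
         "] Hz at resolution ", df, " Hz")
  }
  sum(psd$density[sel]) * df
}

#' Delta ratio of a PSD
#'
#' The reported delta statistic: power summed over 0.9--3.9 Hz divided by
#' total power summed over 0.9--99 Hz. Dimensionless, in \[0, 1\] up to
#' spectral leakage.
#'
#' @param psd a `psd_estimate` covering at least 99 Hz.
#' @return the ratio.
#' @export
delta_ratio <- function(psd) {
  if (max(psd$freqs_hz) < SPECTRAL_BANDS$total[2]) {
    stop("PSD must cover ", SPECTRAL_BANDS$total[2], " Hz to form the ",
         "delta ratio (covers ", max(psd$freqs_hz), " Hz)")
  }
  num <- band_power(psd, SPECTRAL_BANDS$delta_ratio_numerator[1],
                    SPECTRAL_BANDS$delta_ratio_numerator[2])
  den <- band_power(psd, SPECTRAL_BANDS$total[1], SPECTRAL_BANDS$total[2])
  if (den == 0) stop("zero total power: delta ratio undefined")
  num / den
}

#' Virtual delta channel
#'
#' Sliding display of delta-band (0.5--4 Hz) power: one Hann-windowed,
#' detrended periodogram per non-overlapping `step_s` window, summed over
#' the display delta band.
#'
#' @param recording a [signal_recording].
#' @param channel channel name.
#' @param step_s window/step size, seconds (>= 1).
#' @param band band limits, Hz.
#' @return data.frame with `time_s` (window start) and `delta_power`
#'   (uV^2); `floor(duration/step_s)` rows.
#' @export
virtual_delta_channel <- function(recording, channel = "ECoG", step_s = 5,
                                  band = SPECTRAL_BANDS$delta_display) {
  stopifnot(step_s >= 1)
  fs <- recording$sample_rate_hz
  x <- recording$channels[[channel]]
  L <- round(step_s * fs)
  n_win <- floor(length(x) / L)
  if (n_win < 1) stop("step_s exceeds the recording duration")
  segs <- matrix(x[seq_len(n_win * L)], nrow = L)
  segs <- sweep(segs, 2, colMeans(segs))
  P <- periodogram_matrix(segs, fs)
  freqs <- seq(0, fs / 2, length.out = floor(L / 2) + 1L)
  df <- freqs[2] - freqs[1]
  sel <- freqs >= band[1] - 1e-9 & freqs <= band[2] + 1e-9
  data.frame(time_s = (seq_len(n_win) - 1) * step_s,
             delta_power = colSums(P[sel, , drop = FALSE]) * df)
}
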