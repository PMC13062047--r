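# FFT-domain signal helpers shared by the generator and the spike detector.

#' Zero-phase FFT band-pass filter
#'
#' Filters by masking FFT bins, with raised-cosine roll-offs of width
#' `transition_hz` on both edges so the mask has no hard discontinuity.
#' Zero phase and exactly deterministic; edge effects are those of the
#' implicit circular extension, negligible for the long records used here.
#'
#' @param x numeric signal.
#' @param fs sampling rate, Hz.
#' @param lo,hi pass-band edges, Hz (`lo = 0` gives a low-pass).
#' @param transition_hz roll-off width, Hz.
#' @return filtered signal, same length.
#' @export
fft_bandpass <- function(x, fs, lo, hi, transition_hz = 0.5) {
  n <- length(x)
  if (n == 0) return(x)
  f <- abs(seq(0, fs, length.out = n + 1)[seq_len(n)])
  f <- pmin(f, fs - f)                      # two-sided frequency axis
  ramp_up <- function(f, edge) {
    ifelse(f <= edge - transition_hz, 0,
           ifelse(f >= edge, 1,
                  0.5 - 0.5 * cos(pi * (f - (edge - transition_hz)) /
                                    transition_hz)))
  }
  mask <- rep(1, n)
  if (lo > 0) mask <- mask * ramp_up(f, lo)
  if (hi < fs / 2) mask <- mask * (1 - ramp_up(f, hi + transition_hz))
  Re(stats::fft(stats::fft(x) * mask, inverse = TRUE)) / n
}

#' Pink (1/f) noise
#'
#' Gaussian noise shaped in the frequency domain to a 1/f power spectrum,
#' flattened below `f_floor` to keep variance finite, then scaled to the
#' requested RMS. Uses the current RNG stream.
#'
#' @param n number of samples.
#' @param fs sampling rate, Hz.
#' @param rms target root-mean-square amplitude.
#' @param f_floor frequency below which the spectrum is flat, Hz.
#' @return numeric vector of length `n`.
#' @export
pink_noise <- function(n, fs, rms = 1, f_floor = 0.5) {
  if (n == 0) return(numeric(0))
  x <- stats::rnorm(n)
  f <- abs(seq(0, fs, length.out = n + 1)[seq_len(n)])
  f <- pmin(f, fs - f)
  shape <- 1 / sqrt(pmax(f, f_floor))
  shape[1] <- 0                              # remove DC
  y <- Re(stats::fft(stats::fft(x) * shape, inverse = TRUE)) / n
  y * rms / stats::sd(y)
}

#' Band-limited Gaussian noise with unit RMS
#'
#' @inheritParams fft_bandpass
#' @param n number of samples.
#' @return numeric vector with RMS 1 (zeros if the band is empty).
#' @export
band_noise <- function(n, fs, lo, hi) {
  if (n == 0) return(numeric(0))
  y <- fft_bandpass(stats::rnorm(n), fs, lo, hi)
  s <- stats::sd(y)
  if (s == 0) return(y)
  y / s
}

# Smooth a per-sample gate/envelope so state-gated amplitudes cross-fade
# instead of stepping: two passes of a centered moving average (via
# cumsum), i.e. a triangular kernel spanning fade_s.
smooth_gate <- function(gate, fs, fade_s = 1) {
  k <- max(1L, round(fade_s * fs / 2))
  if (k <= 1 || length(gate) < 2 * k + 2) return(gate)
  ma <- function(x) {
    n <- length(x)
    xp <- c(rep(x[1], k), x, rep(x[n], k))
    cs <- cumsum(xp)
    (cs[(2 * k + 1):(n + 2 * k)] -
       c(0, cs[seq_len(n - 1)])) / (2 * k + 1)
  }
  ma(ma(gate))
}

# Median/MAD-based robust standard deviation (consistent for a Gaussian).
robust_sd <- function(x) stats::mad(x, constant = 1.4826)
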