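#' Vigilance-state labels used throughout the package
#'
#' Five labels cover every 5-s epoch: the three vigilance states plus the
#' transition label produced by the 20-s alternation rule and an artifact
#' label for excluded epochs.
#'
#' @export
STATE_LEVELS <- c("WAKE", "NREM", "REM", "TRANSITION", "ARTIFACT")

#' Construct a hypnogram
#'
#' A hypnogram is a run of vigilance-state labels on a fixed epoch grid
#' (5 s by default, matching the scoring epoch used for rodent
#' polysomnography).
#'
#' @param labels character vector of labels, one per epoch, drawn from
#'   [STATE_LEVELS].
#' @param epoch_length_s epoch length in seconds.
#' @param provenance `"ground_truth"` for generator output, `"scored"` for
#'   classifier output.
#' @return an object of class `hypnogram`: a list with elements `labels`,
#'   `epoch_length_s`, `provenance`.
#' @export
hypnogram <- function(labels, epoch_length_s = 5,
                      provenance = c("ground_truth", "scored")) {
  provenance <- match.arg(provenance)
  labels <- as.character(labels)
  bad <- which(!labels %in% STATE_LEVELS)
  if (length(bad) > 0) {
    stop("unknown vigilance label '", labels[bad[1]], "' at epoch ", bad[1],
         "; valid labels: ", paste(STATE_LEVELS, collapse = ", "))
  }
  if (!is.numeric(epoch_length_s) || epoch_length_s <= 0) {
    stop("epoch_length_s must be a positive number")
  }
  structure(list(labels = labels, epoch_length_s = epoch_length_s,
                 provenance = provenance),
            class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  tab <- table(factor(x$labels, levels = STATE_LEVELS))
  cat(sprintf("<hypnogram> %d epochs x %g s (%s)\n", length(x$labels),
              x$epoch_length_s, x$provenance))
  print(tab)
  invisible(x)
}

#' Number of epochs in a hypnogram
#' @param h a [hypnogram].
#' @return integer epoch count.
#' @export
n_epochs <- function(h) length(h$labels)

#' Total duration covered by a hypnogram, in seconds
#' @param h a [hypnogram].
#' @export
hypnogram_duration <- function(h) length(h$labels) * h$epoch_length_s

#' Construct a multichannel signal recording
#'
#' Container for sampled electrophysiology (ECoG or depth LFP plus EMG),
#' with amplitudes in microvolts.
#'
#' @param channels named list of numeric sample vectors (all equal length).
#' @param sample_rate_hz sampling rate in Hz.
#' @param subject_id subject identifier.
#' @param metadata list of free-form metadata; conventional entries are
#'   `genotype`, `bandpass_hz` (length-2 numeric) and `notch_hz`.
#' @return an object of class `signal_recording`.
#' @export
signal_recording <- function(channels, sample_rate_hz, subject_id = "",
                             metadata = list()) {
  if (!is.list(channels) || is.null(names(channels)) ||
      any(!nzchar(names(channels)))) {
    stop("channels must be a named list of numeric vectors")
  }
  lens <- vapply(channels, length, integer(1))
  if (length(unique(lens)) > 1) {
    stop("all channels must have the same length; got lengths ",
         paste(lens, collapse = ", "))
  }
  if (!is.numeric(sample_rate_hz) || sample_rate_hz <= 0) {
    stop("sample_rate_hz must be positive")
  }
  bp <- metadata$bandpass_hz
  if (!is.null(bp) && max(bp) > sample_rate_hz / 2) {
    stop("band-pass upper edge exceeds Nyquist frequency")
  }
  structure(list(channels = lapply(channels, as.numeric),
                 sample_rate_hz = sample_rate_hz,
                 subject_id = subject_id, metadata = metadata),
            class = "signal_recording")
}

#' @export
print.signal_recording <- function(x, ...) {
  n <- if (length(x$channels)) length(x$channels[[1]]) else 0L
  cat(sprintf("<signal_recording> %s: %d channel(s) [%s], %g Hz, %.1f s\n",
              x$subject_id, length(x$channels),
              paste(names(x$channels), collapse = ", "),
              x$sample_rate_hz, n / x$sample_rate_hz))
  invisible(x)
}

#' Recording duration in seconds
#' @param recording a [signal_recording].
#' @export
recording_duration <- function(recording) {
  if (length(recording$channels) == 0) return(0)
  length(recording$channels[[1]]) / recording$sample_rate_hz
}

#' Construct a core-temperature trace
#'
#' @param time_s strictly increasing sample times in seconds.
#' @param temp_c temperatures in degrees Celsius; values outside the
#'   physiologically plausible range 25--43 are rejected.
#' @return an object of class `temperature_trace`.
#' @export
temperature_trace <- function(time_s, temp_c) {
  if (length(time_s) != length(temp_c)) {
    stop("time_s and temp_c must have equal length")
  }
  if (length(time_s) > 1 && any(diff(time_s) <= 0)) {
    stop("time_s must be strictly increasing")
  }
  if (length(temp_c) > 0 && (min(temp_c) < 25 || max(temp_c) > 43)) {
    stop("temperature outside plausible range [25, 43] degrees C")
  }
  structure(list(time_s = as.numeric(time_s), temp_c = as.numeric(temp_c)),
            class = "temperature_trace")
}

#' @export
print.temperature_trace <- function(x, ...) {
  cat(sprintf("<temperature_trace> %d samples, %.1f-%.1f s, mean %.2f C\n",
              length(x$time_s),
              if (length(x$time_s)) min(x$time_s) else NA_real_,
              if (length(x$time_s)) max(x$time_s) else NA_real_,
              mean(x$temp_c)))
  invisible(x)
}
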