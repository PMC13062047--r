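# European Data Format (EDF) 16-bit reader/writer, implemented from the
# format definition: fixed-width ASCII header (256 bytes + 256 per signal)
# followed by little-endian int16 data records.

pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

# fit a number into EDF's 8-char ASCII fields
num8 <- function(x) {
  s <- formatC(x, format = "g", digits = 7, width = 0)
  if (nchar(s) > 8) s <- formatC(x, format = "g", digits = 4, width = 0)
  pad(s, 8)
}

#' Write a recording to an EDF file
#'
#' Uses 1-second data records, so the sampling rate must be a positive
#' integer and the duration a whole number of seconds. Samples are scaled
#' to the full 16-bit digital range over each channel's physical
#' min/max, the standard EDF quantization.
#'
#' @param recording a [signal_recording].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  stopifnot(inherits(recording, "signal_recording"))
  fs <- recording$sample_rate_hz
  if (fs != round(fs) || fs <= 0) {
    stop("EDF writer requires an integer sampling rate")
  }
  lens <- vapply(recording$channels, length, integer(1))
  if (length(unique(lens)) > 1) {
    stop("refusing to write EDF: channels have mismatched lengths")
  }
  n <- if (length(lens)) lens[1] else 0L
  if (n %% fs != 0) stop("EDF writer requires a whole number of seconds")
  n_rec <- as.integer(n / fs)
  ns <- length(recording$channels)

  pmin_ <- pmax_ <- numeric(ns)
  dig <- vector("list", ns)
  for (j in seq_len(ns)) {
    x <- recording$channels[[j]]
    lo <- if (n) min(x) else -1
    hi <- if (n) max(x) else 1
    if (hi <= lo) hi <- lo + 1
    # widen so 8-char rounded header values still bracket the data
    lo <- as.numeric(num8(lo - (hi - lo) * 1e-4))
    hi <- as.numeric(num8(hi + (hi - lo) * 1e-4))
    pmin_[j] <- lo; pmax_[j] <- hi
    dig[[j]] <- as.integer(round((x - lo) / (hi - lo) * 65535 - 32768))
  }

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad("0", 8), pad(recording$subject_id, 80), pad("somnotherm", 80),
    pad(format(Sys.Date(), "01.01.00"), 8), pad("00.00.00", 8),
    pad(256 * (ns + 1), 8), pad("", 44), pad(n_rec, 8), pad(1, 8), pad(ns, 4))
  sig_hdr <- paste0(
    paste(vapply(names(recording$channels), pad, "", width = 16),
          collapse = ""),
    paste(rep(pad("", 80), ns), collapse = ""),
    paste(rep(pad("uV", 8), ns), collapse = ""),
    paste(vapply(pmin_, num8, ""), collapse = ""),
    paste(vapply(pmax_, num8, ""), collapse = ""),
    paste(rep(pad(-32768, 8), ns), collapse = ""),
    paste(rep(pad(32767, 8), ns), collapse = ""),
    paste(rep(pad("", 80), ns), collapse = ""),
    paste(rep(pad(fs, 8), ns), collapse = ""),
    paste(rep(pad("", 32), ns), collapse = ""))
  writeChar(paste0(hdr, sig_hdr), con, eos = NULL)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (j in seq_len(ns)) writeBin(dig[[j]][idx], con, size = 2,
                                    endian = "little")
  }
  invisible(path)
}

#' Read an EDF file
#'
#' @param path EDF file path.
#' @return a [signal_recording]; channels in microvolts (or the file's
#'   physical dimension).
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("EDF file does not exist: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  version <- rd(8)
  if (version != "0") stop("malformed EDF header in ", path,
                           ": bad version field '", version, "'")
  subject <- rd(80); rd(80); rd(8); rd(8)
  hdr_bytes <- suppressWarnings(as.integer(rd(8)))
  rd(44)
  n_rec <- suppressWarnings(as.integer(rd(8)))
  rec_dur <- suppressWarnings(as.numeric(rd(8)))
  ns <- suppressWarnings(as.integer(rd(4)))
  if (anyNA(c(hdr_bytes, n_rec, rec_dur, ns)) || ns < 1 || n_rec < 0) {
    stop("malformed EDF header in ", path)
  }
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)                 # transducer
  for (i in seq_len(ns)) rd(8)                  # physical dimension
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)                 # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)
  if (anyNA(spr) || any(spr <= 0)) stop("malformed EDF header in ", path)

  chans <- lapply(seq_len(ns), function(j) numeric(n_rec * spr[j]))
  for (r in seq_len(n_rec)) {
    for (j in seq_len(ns)) {
      d <- readBin(con, "integer", n = spr[j], size = 2, endian = "little",
                   signed = TRUE)
      if (length(d) < spr[j]) stop("EDF file truncated: ", path)
      chans[[j]][((r - 1) * spr[j] + 1):(r * spr[j])] <-
        pmin_[j] + (d - dmin_[j]) * (pmax_[j] - pmin_[j]) /
        (dmax_[j] - dmin_[j])
    }
  }
  names(chans) <- labels
  fs <- spr[1] / rec_dur
  signal_recording(chans, fs, subject_id = subject)
}
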