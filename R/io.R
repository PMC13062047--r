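# CSV readers/writers for hypnograms and temperature traces. Dialect:
# comma-separated, header row required, UTF-8, '.' decimal.

#' Write a hypnogram CSV (`epoch_index,start_s,label`)
#'
#' @param hyp a [hypnogram].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hypnogram_csv <- function(hyp, path) {
  stopifnot(inherits(hyp, "hypnogram"))
  n <- n_epochs(hyp)
  df <- data.frame(epoch_index = seq_len(n) - 1L,
                   start_s = (seq_len(n) - 1L) * hyp$epoch_length_s,
                   label = hyp$labels)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a hypnogram CSV
#'
#' Expects columns `epoch_index,start_s,label`; any label outside the
#' vigilance-state enum is rejected with its row number. An empty file
#' (header only, or zero bytes) yields an empty hypnogram with a warning.
#'
#' @param path CSV path.
#' @param provenance provenance tag for the resulting [hypnogram].
#' @return a [hypnogram].
#' @export
read_hypnogram_csv <- function(path, provenance = "scored") {
  if (!file.exists(path)) stop("hypnogram file does not exist: ", path)
  if (file.size(path) == 0) {
    warning("empty hypnogram file: ", path)
    return(hypnogram(character(0), 5, provenance))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    warning("hypnogram file has no epochs: ", path)
    return(hypnogram(character(0), 5, provenance))
  }
  if (!all(c("epoch_index", "start_s", "label") %in% names(df))) {
    stop("hypnogram CSV must have columns epoch_index,start_s,label")
  }
  bad <- which(!df$label %in% STATE_LEVELS)
  if (length(bad) > 0) {
    stop("unknown vigilance label '", df$label[bad[1]], "' at row ", bad[1],
         " of ", path)
  }
  ep <- if (nrow(df) > 1) df$start_s[2] - df$start_s[1] else 5
  hypnogram(df$label, ep, provenance)
}

#' Write a temperature CSV (`time_s,temp_c`)
#'
#' @param trace a [temperature_trace].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_temperature_csv <- function(trace, path) {
  stopifnot(inherits(trace, "temperature_trace"))
  utils::write.csv(data.frame(time_s = trace$time_s, temp_c = trace$temp_c),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a temperature CSV
#'
#' Validates the trace: two numeric columns, strictly increasing times,
#' temperatures within 25--43 degrees C.
#'
#' @param path CSV path.
#' @return a [temperature_trace].
#' @export
read_temperature_csv <- function(path) {
  if (!file.exists(path)) stop("temperature file does not exist: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "temp_c") %in% names(df))) {
    stop("temperature CSV must have columns time_s,temp_c")
  }
  if (!is.numeric(df$time_s) || !is.numeric(df$temp_c)) {
    stop("temperature CSV columns must be numeric")
  }
  temperature_trace(df$time_s, df$temp_c)
}
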