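#' Find eligible wake-to-NREM transitions
#'
#' An NREM onset is eligible when at least `wake_min_s` of contiguous
#' WAKE precede it (TRANSITION epochs are permitted in the final
#' `transition_tail_s`) and at least `nrem_min_s` of contiguous NREM
#' follow it. The defaults (120 s prior wake, 90 s NREM) are forced by
#' the transition-locked PSD window placement: the wake window starts
#' 2 min before onset and the NREM window ends 90 s after it. Analysis
#' windows `[onset - wake_min_s, onset + nrem_min_s]` of retained onsets
#' never overlap (earlier onsets win).
#'
#' @param hyp a scored [hypnogram] (transition rule applied).
#' @param wake_min_s minimum contiguous wake before onset, seconds.
#' @param nrem_min_s minimum contiguous NREM after onset, seconds.
#' @param transition_tail_s tail of the wake run in which TRANSITION
#'   epochs are tolerated, seconds.
#' @return numeric vector of onset times, seconds (possibly empty).
#' @export
find_wake_to_nrem <- function(hyp, wake_min_s = 120, nrem_min_s = 90,
                              transition_tail_s = 20) {
  ep <- hyp$epoch_length_s
  lab <- hyp$labels
  n <- length(lab)
  k_wake <- ceiling(wake_min_s / ep)
  k_nrem <- ceiling(nrem_min_s / ep)
  k_tail <- floor(transition_tail_s / ep)
  onsets <- numeric(0)
  last_end <- -Inf
  for (i in seq_len(n)) {
    if (lab[i] != "NREM") next
    if (i == 1 || lab[i - 1] == "NREM") next        # not an onset
    if (i - 1 < k_wake || i + k_nrem - 1 > n) next
    if (!all(lab[i:(i + k_nrem - 1)] == "NREM")) next
    pre <- lab[(i - k_wake):(i - 1)]
    tail_ok <- pre[(k_wake - k_tail + 1):k_wake] %in% c("WAKE", "TRANSITION")
    head_ok <- pre[seq_len(k_wake - k_tail)] == "WAKE"
    if (!all(head_ok) || !all(tail_ok)) next
    onset_s <- (i - 1) * ep
    if (onset_s - wake_min_s < last_end) next       # overlapping window
    onsets <- c(onsets, onset_s)
    last_end <- onset_s + nrem_min_s
  }
  onsets
}

#' Transition-locked wake and NREM spectra
#'
#' For one eligible onset, computes the wake PSD from the 30 s starting
#' 2 min before the transition and the NREM PSD from the 30 s starting
#' 1 min into NREM, and attaches both delta ratios. If a hypnogram is
#' supplied and the default wake window overlaps an ARTIFACT epoch, the
#' window slides earlier in 5-s steps by up to `max_slide_s`; if no
#' artifact-free placement exists the event is rejected.
#'
#' @param recording a [signal_recording].
#' @param onset_s onset time from [find_wake_to_nrem].
#' @param channel signal channel.
#' @param hyp optional scored [hypnogram] used for artifact avoidance.
#' @param max_slide_s maximum earlier slide of the wake window, seconds.
#' @return list with `wake_psd`, `nrem_psd`, `wake_delta_ratio`,
#'   `nrem_delta_ratio`, `wake_window`, `nrem_window`.
#' @export
transition_psds <- function(recording, onset_s, channel = "ECoG",
                            hyp = NULL, max_slide_s = 30) {
  if (onset_s < 120) {
    stop("onset at ", onset_s, " s is less than 120 s from record start; ",
         "the wake window would underflow")
  }
  wake_start <- onset_s - 120
  if (!is.null(hyp)) {
    ok <- FALSE
    for (slide in seq(0, max_slide_s, by = 5)) {
      s <- onset_s - 120 - slide
      if (s < 0) break
      ep <- hyp$epoch_length_s
      idx <- (floor(s / ep) + 1):ceiling((s + 30) / ep)
      idx <- idx[idx >= 1 & idx <= n_epochs(hyp)]
      if (!any(hyp$labels[idx] == "ARTIFACT")) {
        wake_start <- s
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("no artifact-free wake window within ", max_slide_s,
                  " s before the default placement; event dropped")
  }
  wake_psd <- compute_psd(recording, channel, c(wake_start, 30))
  nrem_psd <- compute_psd(recording, channel, c(onset_s + 60, 30))
  list(wake_psd = wake_psd, nrem_psd = nrem_psd,
       wake_delta_ratio = delta_ratio(wake_psd),
       nrem_delta_ratio = delta_ratio(nrem_psd),
       wake_window = c(wake_start, 30), nrem_window = c(onset_s + 60, 30))
}

#' Classify the core-temperature change at an NREM onset
#'
#' Baseline is the mean temperature over `baseline_window` (default the
#' 60 s before onset); post is the mean over `post_window` (default 60 to
#' 180 s after onset). The change is classed `negative` below `-epsilon`,
#' `positive` above `+epsilon`, else `unchanged`. The windows and the
#' 0.1 degree C epsilon are this module's definitions of "unchanged" and
#' are configurable.
#'
#' @param trace a [temperature_trace] covering both windows.
#' @param onset_s onset time, seconds.
#' @param epsilon dead-band half-width, degrees C.
#' @param baseline_window,post_window offsets from onset, seconds.
#' @return list with `temp_class` (`"negative"`, `"unchanged"`,
#'   `"positive"`), `temp_delta_c`, `temp_baseline_c`, `temp_post_c`.
#'   Insufficient trace coverage raises an error of class
#'   `somnotherm_coverage_error` (pipelines drop the event and log it).
#' @export
classify_temperature_change <- function(trace, onset_s, epsilon = 0.1,
                                        baseline_window = c(-60, 0),
                                        post_window = c(60, 180)) {
  tt <- trace$time_s
  need <- onset_s + c(baseline_window[1], post_window[2])
  if (length(tt) == 0 || min(tt) > need[1] + 1e-9 ||
      max(tt) < need[2] - 1 - 1e-9) {
    stop(structure(class = c("somnotherm_coverage_error", "error",
                             "condition"),
                   list(message = paste0("temperature trace does not cover [",
                                         need[1], ", ", need[2],
                                         "] s around the onset"),
                        call = NULL)))
  }
  base_sel <- tt >= onset_s + baseline_window[1] & tt < onset_s +
    baseline_window[2]
  post_sel <- tt >= onset_s + post_window[1] & tt < onset_s + post_window[2]
  baseline <- mean(trace$temp_c[base_sel])
  post <- mean(trace$temp_c[post_sel])
  delta <- post - baseline
  cls <- if (delta < -epsilon) "negative" else if (delta > epsilon)
    "positive" else "unchanged"
  list(temp_class = cls, temp_delta_c = delta,
       temp_baseline_c = baseline, temp_post_c = post)
}

#' Extract all transition events from one session
#'
#' Runs [find_wake_to_nrem], [transition_psds] and
#' [classify_temperature_change] over a scored session; events whose
#' temperature coverage or artifact-free window requirements fail are
#' dropped with a message.
#'
#' @param recording a [signal_recording].
#' @param hyp a scored [hypnogram] with the transition rule applied.
#' @param trace a [temperature_trace] (optional; temperature fields NA
#'   when absent).
#' @param subject_id subject identifier for the event rows.
#' @param channel signal channel.
#' @param epsilon temperature dead band, degrees C.
#' @return data.frame of events: `subject_id`, `onset_s`,
#'   `wake_delta_ratio`, `nrem_delta_ratio`, `temp_baseline_c`,
#'   `temp_post_c`, `temp_delta_c`, `temp_class`; attribute `"psds"`
#'   holds the per-event PSD pairs.
#' @export
session_transition_events <- function(recording, hyp, trace = NULL,
                                      subject_id = recording$subject_id,
                                      channel = "ECoG", epsilon = 0.1) {
  onsets <- find_wake_to_nrem(hyp)
  rows <- list()
  psds <- list()
  for (o in onsets) {
    ev <- tryCatch({
      sp <- transition_psds(recording, o, channel = channel, hyp = hyp)
      tc <- if (is.null(trace)) {
        list(temp_class = NA_character_, temp_delta_c = NA_real_,
             temp_baseline_c = NA_real_, temp_post_c = NA_real_)
      } else {
        classify_temperature_change(trace, o, epsilon = epsilon)
      }
      list(sp = sp, tc = tc)
    }, error = function(e) {
      message("dropping transition at ", o, " s (", subject_id, "): ",
              conditionMessage(e))
      NULL
    })
    if (is.null(ev)) next
    rows[[length(rows) + 1]] <- data.frame(
      subject_id = subject_id, onset_s = o,
      wake_delta_ratio = ev$sp$wake_delta_ratio,
      nrem_delta_ratio = ev$sp$nrem_delta_ratio,
      temp_baseline_c = ev$tc$temp_baseline_c,
      temp_post_c = ev$tc$temp_post_c,
      temp_delta_c = ev$tc$temp_delta_c,
      temp_class = ev$tc$temp_class)
    psds[[length(psds) + 1]] <- ev$sp[c("wake_psd", "nrem_psd")]
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subject_id = character(0), onset_s = numeric(0),
               wake_delta_ratio = numeric(0), nrem_delta_ratio = numeric(0),
               temp_baseline_c = numeric(0), temp_post_c = numeric(0),
               temp_delta_c = numeric(0), temp_class = character(0))
  attr(out, "psds") <- psds
  out
}

#' Per-subject transition summaries
#'
#' Averages all of a subject's transition events before any
#' across-subject averaging, so each subject contributes one value to
#' group statistics. PSDs are averaged bin-wise when supplied.
#'
#' @param events event data.frame from [session_transition_events]
#'   (possibly concatenated over sessions).
#' @return data.frame with one row per subject: mean wake/NREM delta
#'   ratios, event count, and per-class counts (`n_negative`,
#'   `n_unchanged`, `n_positive`); attribute `"mean_psds"` holds the
#'   bin-averaged PSD pairs when event PSDs were attached.
#' @export
per_subject_average <- function(events) {
  if (nrow(events) == 0) stop("no transition events to summarize")
  ids <- unique(events$subject_id)
  psds <- attr(events, "psds")
  mean_psds <- list()
  rows <- lapply(ids, function(id) {
    e <- events[events$subject_id == id, ]
    data.frame(subject_id = id,
               n_events = nrow(e),
               wake_delta_ratio = mean(e$wake_delta_ratio),
               nrem_delta_ratio = mean(e$nrem_delta_ratio),
               n_negative = sum(e$temp_class == "negative", na.rm = TRUE),
               n_unchanged = sum(e$temp_class == "unchanged", na.rm = TRUE),
               n_positive = sum(e$temp_class == "positive", na.rm = TRUE))
  })
  if (!is.null(psds) && length(psds) == nrow(events)) {
    for (id in ids) {
      sel <- which(events$subject_id == id)
      avg <- function(which_psd) {
        p <- psds[[sel[1]]][[which_psd]]
        p$density <- rowMeans(vapply(sel, function(i)
          psds[[i]][[which_psd]]$density,
          numeric(length(p$density))))
        p$source_window <- c(NA_real_, NA_real_)
        p
      }
      mean_psds[[id]] <- list(wake_psd = avg("wake_psd"),
                              nrem_psd = avg("nrem_psd"))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "mean_psds") <- mean_psds
  out
}

#' Pooled (per-event) mean delta ratios
#'
#' The pooled mean weights subjects by their event counts and therefore
#' differs from the mean of per-subject means under unequal counts; the
#' per-subject route is what group statistics use.
#'
#' @param events event data.frame.
#' @return named numeric vector `wake`/`nrem`.
#' @export
pooled_event_mean <- function(events) {
  c(wake = mean(events$wake_delta_ratio),
    nrem = mean(events$nrem_delta_ratio))
}

#' Contingency table of temperature classes by group
#'
#' @param group_events named list mapping group label to an event
#'   data.frame (with `temp_class`).
#' @return a `contingency_table`: integer matrix groups x
#'   (negative, unchanged, positive).
#' @export
build_transition_contingency <- function(group_events) {
  if (length(group_events) < 2) stop("need at least 2 groups")
  classes <- c("negative", "unchanged", "positive")
  counts <- t(vapply(group_events, function(e) {
    tab <- table(factor(e$temp_class, levels = classes))
    as.integer(tab)
  }, integer(3)))
  dimnames(counts) <- list(names(group_events), classes)
  structure(counts, class = c("contingency_table", class(counts)))
}
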