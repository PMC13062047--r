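#' Per-epoch spectral and EMG features
#'
#' Segments the recording into fixed epochs (5 s default) and computes,
#' per epoch: delta power (display band 0.5--4 Hz), theta power (4--8 Hz),
#' total power (0.9--99 Hz, capped at Nyquist), the theta/delta ratio, and
#' the RMS of the band-passed (20--100 Hz) EMG. Band powers use the same
#' detrended Hann periodogram as [compute_psd].
#'
#' @param recording a [signal_recording] with a signal channel (`ECoG` or
#'   `LFP`) and an `EMG` channel.
#' @param epoch_length_s epoch length, seconds.
#' @param signal_channel channel to use for spectra; default picks
#'   `ECoG` then `LFP`.
#' @return data.frame with one row per complete epoch: `epoch_index`
#'   (0-based), `start_s`, `delta_power`, `theta_power`, `total_power`,
#'   `theta_delta_ratio` (NA where delta power is 0), `emg_rms`,
#'   `artifact_flag` (initialized FALSE; see [detect_artifacts]).
#' @export
compute_epoch_features <- function(recording, epoch_length_s = 5,
                                   signal_channel = NULL) {
  stopifnot(inherits(recording, "signal_recording"))
  if (!"EMG" %in% names(recording$channels)) {
    stop("recording has no EMG channel; epoch features require one")
  }
  if (is.null(signal_channel)) {
    signal_channel <- intersect(c("ECoG", "LFP"), names(recording$channels))[1]
    if (is.na(signal_channel)) {
      signal_channel <- setdiff(names(recording$channels), "EMG")[1]
    }
  }
  fs <- recording$sample_rate_hz
  x <- recording$channels[[signal_channel]]
  L <- round(epoch_length_s * fs)
  n_ep <- floor(length(x) / L)
  if (n_ep == 0) {
    return(data.frame(epoch_index = integer(0), start_s = numeric(0),
                      delta_power = numeric(0), theta_power = numeric(0),
                      total_power = numeric(0),
                      theta_delta_ratio = numeric(0), emg_rms = numeric(0),
                      artifact_flag = logical(0)))
  }
  segs <- matrix(x[seq_len(n_ep * L)], nrow = L)
  segs <- sweep(segs, 2, colMeans(segs))
  P <- periodogram_matrix(segs, fs)
  freqs <- seq(0, fs / 2, length.out = floor(L / 2) + 1L)
  df <- freqs[2] - freqs[1]
  bsum <- function(band) {
    sel <- freqs >= band[1] - 1e-9 & freqs <= min(band[2], fs / 2) + 1e-9
    colSums(P[sel, , drop = FALSE]) * df
  }
  delta <- bsum(SPECTRAL_BANDS$delta_display)
  theta <- bsum(SPECTRAL_BANDS$theta)
  total <- bsum(SPECTRAL_BANDS$total)

  emg <- fft_bandpass(recording$channels[["EMG"]], fs, 20, min(100, fs / 2))
  em <- matrix(emg[seq_len(n_ep * L)], nrow = L)
  emg_rms <- sqrt(colMeans(em^2))

  data.frame(epoch_index = seq_len(n_ep) - 1L,
             start_s = (seq_len(n_ep) - 1L) * epoch_length_s,
             delta_power = delta, theta_power = theta, total_power = total,
             theta_delta_ratio = ifelse(delta > 0, theta / delta, NA_real_),
             emg_rms = emg_rms, artifact_flag = FALSE)
}

# Exact 1-D Otsu split: threshold maximizing between-class variance over
# midpoints of consecutive sorted values. Returns the threshold and the
# separation score (between-class variance / total variance at the
# optimum), a bimodality measure in [0, 1].
otsu_split <- function(x) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n < 2 || stats::var(x) == 0) {
    stop("degenerate (constant) feature distribution; supply manual ",
         "thresholds instead")
  }
  cs <- cumsum(x)
  k <- seq_len(n - 1)
  m1 <- cs[k] / k
  m2 <- (cs[n] - cs[k]) / (n - k)
  bcv <- (k / n) * (1 - k / n) * (m1 - m2)^2
  # exclude splits between tied values (zero-width thresholds)
  valid <- diff(x) > 0
  bcv[!valid] <- -Inf
  i <- which.max(bcv)
  list(threshold = (x[i] + x[i + 1]) / 2,
       separation = bcv[i] / (stats::var(x) * (n - 1) / n))
}

#' Fit scoring thresholds from epoch features
#'
#' EMG wake threshold: exact Otsu split of log EMG RMS. NREM delta
#' threshold: Otsu split of log delta power restricted to low-EMG epochs.
#' When the low-EMG delta distribution shows no real bimodality
#' (separation score below `min_separation`; the score of an optimal
#' split of a unimodal Gaussian is about 0.64, while two modes at least
#' 3.5 SD apart score above 0.75) — the situation in recordings without
#' a NREM delta surge, where EMG must carry the classification — the
#' delta threshold is placed below the observed range so every low-EMG,
#' non-REM epoch scores as NREM.
#'
#' Both splits act on logs, so thresholds are equivariant under rescaling
#' of the raw features.
#'
#' @param features data.frame from [compute_epoch_features] (>= 100 rows).
#' @param rem_theta_delta_threshold REM ratio criterion (default 2.5).
#' @param artifact_amplitude_sd artifact peak-amplitude criterion, in
#'   robust SDs.
#' @param min_separation Otsu separation score under which the delta
#'   split is considered unimodal.
#' @return a `scoring_thresholds` list.
#' @export
fit_thresholds <- function(features, rem_theta_delta_threshold = 2.5,
                           artifact_amplitude_sd = 8, min_separation = 0.75) {
  if (nrow(features) < 100) {
    stop("need at least 100 epochs to fit thresholds (got ",
         nrow(features), ")")
  }
  emg_split <- otsu_split(log(features$emg_rms))
  emg_thr <- exp(emg_split$threshold)
  low <- features$emg_rms <= emg_thr & features$delta_power > 0
  ld <- log(features$delta_power[low])
  delta_split <- tryCatch(otsu_split(ld), error = function(e) NULL)
  if (is.null(delta_split) || delta_split$separation < min_separation) {
    delta_thr <- exp(min(ld)) / 2          # EMG-led scoring: no delta gate
  } else {
    delta_thr <- exp(delta_split$threshold)
  }
  structure(list(emg_wake_threshold = emg_thr,
                 delta_nrem_threshold = delta_thr,
                 rem_theta_delta_threshold = rem_theta_delta_threshold,
                 artifact_amplitude_sd = artifact_amplitude_sd),
            class = "scoring_thresholds")
}

#' Classify epochs into vigilance states
#'
#' Deterministic decision cascade, ordered by discriminative priority:
#' ARTIFACT if flagged; WAKE if EMG RMS exceeds the wake threshold
#' (high muscle tone is the primary wake discriminator); REM if the
#' theta/delta ratio exceeds 2.5 (with EMG already low at this point in
#' the cascade); NREM if delta power exceeds the NREM threshold; else
#' WAKE (quiet wake).
#'
#' @param features data.frame from [compute_epoch_features].
#' @param thresholds a `scoring_thresholds` list from [fit_thresholds].
#' @param epoch_length_s epoch length for the resulting hypnogram.
#' @return a scored [hypnogram].
#' @export
classify_epochs <- function(features, thresholds, epoch_length_s = 5) {
  ratio <- features$theta_delta_ratio
  lab <- ifelse(features$artifact_flag, "ARTIFACT",
         ifelse(features$emg_rms > thresholds$emg_wake_threshold, "WAKE",
         ifelse(!is.na(ratio) & ratio > thresholds$rem_theta_delta_threshold,
                "REM",
         ifelse(features$delta_power > thresholds$delta_nrem_threshold,
                "NREM", "WAKE"))))
  hypnogram(lab, epoch_length_s, "scored")
}

#' Relabel brief wake/NREM alternations as transition states
#'
#' Implements the 20-s alternation rule: within any maximal block of
#' consecutive short runs (runs of WAKE or NREM no longer than
#' `max_run_s`), the states genuinely alternate when the block holds at
#' least three runs — some state then recurs within 20 s — and all its
#' epochs are relabeled TRANSITION. A single clean switch (two runs) is
#' not alternation and is left alone, as are stable runs (longer than
#' `max_run_s`) and non-wake/NREM labels, which bound the blocks.
#' Idempotent.
#'
#' @param hyp a scored [hypnogram].
#' @param max_run_s maximum run length counted as alternation (default
#'   20 s = 4 epochs, inclusive).
#' @return the relabeled [hypnogram].
#' @export
apply_transition_rule <- function(hyp, max_run_s = 20) {
  lab <- hyp$labels
  if (length(lab) == 0) return(hyp)
  max_ep <- floor(max_run_s / hyp$epoch_length_s)
  r <- rle(lab)
  short <- r$values %in% c("WAKE", "NREM") & r$lengths <= max_ep
  grp <- cumsum(!short)                     # block id between stable runs
  run_start <- cumsum(c(1, r$lengths[-length(r$lengths)]))
  for (g in unique(grp[short])) {
    members <- which(short & grp == g)
    if (length(members) >= 3) {
      for (m in members) {
        lab[run_start[m]:(run_start[m] + r$lengths[m] - 1)] <- "TRANSITION"
      }
    }
  }
  hypnogram(lab, hyp$epoch_length_s, hyp$provenance)
}

#' Flag artifact epochs
#'
#' An epoch is flagged when its peak absolute signal amplitude exceeds
#' `amplitude_sd` robust SDs of the whole channel, or when its total
#' power strictly exceeds the `power_quantile` quantile of all epochs.
#'
#' @param recording a [signal_recording].
#' @param features data.frame from [compute_epoch_features].
#' @param amplitude_sd robust-SD multiplier (default 8).
#' @param power_quantile total-power quantile cutoff (default 0.999).
#' @param signal_channel channel to inspect; default as in
#'   [compute_epoch_features].
#' @return logical vector of flags, one per feature row.
#' @export
detect_artifacts <- function(recording, features, amplitude_sd = 8,
                             power_quantile = 0.999, signal_channel = NULL) {
  if (is.null(signal_channel)) {
    signal_channel <- intersect(c("ECoG", "LFP"), names(recording$channels))[1]
  }
  fs <- recording$sample_rate_hz
  x <- recording$channels[[signal_channel]]
  ep_s <- if (nrow(features) >= 2) features$start_s[2] - features$start_s[1]
          else 5
  L <- round(ep_s * fs)
  n_ep <- nrow(features)
  if (n_ep == 0) return(logical(0))
  peaks <- vapply(seq_len(n_ep), function(i) {
    max(abs(x[((i - 1) * L + 1):min(i * L, length(x))]))
  }, numeric(1))
  sd_r <- robust_sd(x)
  amp_flag <- peaks > amplitude_sd * sd_r
  pow_flag <- features$total_power >
    stats::quantile(features$total_power, power_quantile)
  amp_flag | pow_flag
}

#' Agreement between two hypnograms
#'
#' Emulates the dual-scorer consensus: percent of epochs with identical
#' labels (epochs labeled ARTIFACT by either scorer are excluded from the
#' denominator) and the boolean mask of mutually agreed epochs for
#' downstream filtering.
#'
#' @param h1,h2 [hypnogram]s on the same epoch grid.
#' @return list with `percent_agreement` and `agreed_mask`.
#' @export
score_agreement <- function(h1, h2) {
  if (n_epochs(h1) != n_epochs(h2) ||
      h1$epoch_length_s != h2$epoch_length_s) {
    stop("hypnograms are on different epoch grids")
  }
  art <- h1$labels == "ARTIFACT" | h2$labels == "ARTIFACT"
  agree <- h1$labels == h2$labels
  denom <- sum(!art)
  list(percent_agreement = if (denom == 0) NA_real_ else
         100 * sum(agree & !art) / denom,
       agreed_mask = agree & !art)
}

#' Percent of time spent in a state over an interval
#'
#' 100 x (epochs of `state`) / (non-ARTIFACT epochs), over epochs fully
#' contained in `[start_s, end_s)`.
#'
#' @param hyp a [hypnogram].
#' @param state a label from [STATE_LEVELS].
#' @param interval `c(start_s, end_s)`; default the whole hypnogram.
#' @return percent (0--100).
#' @export
percent_time_in_state <- function(hyp, state, interval = NULL) {
  stopifnot(state %in% STATE_LEVELS)
  ep <- hyp$epoch_length_s
  if (is.null(interval)) interval <- c(0, hypnogram_duration(hyp))
  starts <- (seq_len(n_epochs(hyp)) - 1) * ep
  sel <- starts >= interval[1] - 1e-9 & starts + ep <= interval[2] + 1e-9
  lab <- hyp$labels[sel]
  lab <- lab[lab != "ARTIFACT"]
  if (length(lab) == 0) stop("interval [", interval[1], ", ", interval[2],
                             ") contains no scoreable epochs")
  100 * sum(lab == state) / length(lab)
}

#' Score a session end-to-end
#'
#' Convenience wrapper: epoch features, artifact flags, automatic
#' thresholds, the decision cascade and the 20-s transition rule.
#'
#' @param recording a [signal_recording].
#' @param epoch_length_s epoch length, seconds.
#' @return list with `hypnogram` (scored, transition rule applied),
#'   `features`, `thresholds`.
#' @export
score_session <- function(recording, epoch_length_s = 5) {
  feats <- compute_epoch_features(recording, epoch_length_s)
  feats$artifact_flag <- detect_artifacts(recording, feats)
  thr <- fit_thresholds(feats)
  hyp <- apply_transition_rule(classify_epochs(feats, thr, epoch_length_s))
  list(hypnogram = hyp, features = feats, thresholds = thr)
}
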