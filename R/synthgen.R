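#' Session specification for the synthetic generator
#'
#' @param subject_id subject identifier.
#' @param preset a [make_preset] result.
#' @param ambient_blocks data.frame with columns `label` (`"RT"` or
#'   `"WARM"`) and `duration_s`; session duration is their sum.
#' @param sample_rate_hz sampling rate; must exceed twice the 99 Hz
#'   analysis ceiling. Default 250 Hz keeps desk-scale runtimes; the
#'   acquisition-matched 1 kHz is accepted.
#' @param epoch_length_s scoring epoch, seconds.
#' @param seed integer RNG seed; all session randomness derives from it.
#' @return an object of class `session_spec`.
#' @export
session_spec <- function(subject_id, preset,
                         ambient_blocks = data.frame(
                           label = "RT", duration_s = 7200),
                         sample_rate_hz = 250, epoch_length_s = 5,
                         seed = 1L) {
  stopifnot(inherits(preset, "genotype_preset"))
  if (!all(ambient_blocks$label %in% c("RT", "WARM"))) {
    stop("ambient block labels must be RT or WARM")
  }
  if (sample_rate_hz <= 2 * 100) {
    stop("sample_rate_hz must exceed 200 Hz (Nyquist above the 99 Hz ceiling)")
  }
  duration_s <- sum(ambient_blocks$duration_s)
  if (duration_s %% epoch_length_s != 0) {
    stop("session duration must be a multiple of the epoch length")
  }
  structure(list(subject_id = subject_id, preset = preset,
                 duration_s = duration_s, ambient_blocks = ambient_blocks,
                 sample_rate_hz = sample_rate_hz,
                 epoch_length_s = epoch_length_s, seed = as.integer(seed)),
            class = "session_spec")
}

# Deterministic sub-seed per generator stage, kept below 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647)
}

# Ambient label at a given time, from the ordered block list.
ambient_at <- function(blocks, t) {
  ends <- cumsum(blocks$duration_s)
  blocks$label[min(which(t < ends + 1e-9), length(ends))]
}

#' Simulate a ground-truth hypnogram
#'
#' Draws an alternating-bout (semi-Markov) state sequence on the 5-s epoch
#' grid: bout lengths are exponential with per-state means, truncated at
#' one epoch; the next state follows the preset's entry chain, switched to
#' the warmth-adjusted chain ([warm_entry_probs]) inside WARM blocks so
#' the expected NREM fraction rises by `warm_nrem_boost`.
#'
#' @param spec a [session_spec].
#' @return a ground-truth [hypnogram].
#' @export
simulate_hypnogram <- function(spec) {
  stopifnot(inherits(spec, "session_spec"))
  preset <- spec$preset
  ep <- spec$epoch_length_s
  n_ep <- as.integer(spec$duration_s / ep)
  set.seed(derive_seed(spec$seed, 1))
  P_rt <- preset$state_entry_probs
  P_warm <- warm_entry_probs(preset)
  labels <- character(n_ep)
  i <- 0L
  # stationary start: avoids a wake-biased transient in the first block
  occ0 <- stationary_occupancy(preset,
                               ambient_at(spec$ambient_blocks, 0))
  state <- sample(names(occ0), 1, prob = occ0)
  while (i < n_ep) {
    m <- preset$bout_mean_s[[state]]
    len <- max(1L, as.integer(round(stats::rexp(1, 1 / m) / ep)))
    len <- min(len, n_ep - i)
    labels[(i + 1):(i + len)] <- state
    i <- i + len
    P <- if (ambient_at(spec$ambient_blocks, i * ep) == "WARM") P_warm else P_rt
    state <- sample(colnames(P), 1, prob = P[state, ])
  }
  hypnogram(labels, ep, "ground_truth")
}

#' Synthesize ECoG/LFP and EMG signals from a hypnogram
#'
#' The ECoG/LFP channel is pink-noise background plus state-gated
#' narrowband components: a 0.5--4 Hz delta oscillation in NREM whose
#' band power is `nrem_delta_gain^2` times the background (wake) delta
#' power, and a 4--8 Hz theta oscillation in REM strong enough that the
#' per-epoch theta/delta ratio clears the 2.5 REM criterion. The EMG
#' channel is 20--100 Hz noise with per-state RMS from the preset.
#' State gates are cross-faded over 1 s.
#'
#' @param hyp a [hypnogram] on the session's epoch grid.
#' @param preset a `genotype_preset`.
#' @param spec the [session_spec] (rate, subject, metadata).
#' @return a [signal_recording] with channels `ECoG` and `EMG` (microvolts).
#' @export
synthesize_signals <- function(hyp, preset, spec) {
  fs <- spec$sample_rate_hz
  n <- as.integer(round(hypnogram_duration(hyp) * fs))
  if (n != as.integer(round(spec$duration_s * fs))) {
    stop("hypnogram duration does not match the session spec")
  }
  meta <- list(genotype = preset$name, bandpass_hz = c(0.5, 100),
               notch_hz = 50, epoch_length_s = hyp$epoch_length_s)
  if (n == 0) {
    return(signal_recording(list(ECoG = numeric(0), EMG = numeric(0)),
                            fs, spec$subject_id, meta))
  }
  set.seed(derive_seed(spec$seed, 2))
  per_sample <- rep(hyp$labels, each = round(hyp$epoch_length_s * fs))[1:n]

  bg <- pink_noise(n, fs, rms = 25)
  delta_bg_power <- mean(fft_bandpass(bg, fs, 0.5, 4)^2)

  delta_amp <- sqrt(max(preset$nrem_delta_gain^2 - 1, 0) * delta_bg_power)
  theta_amp <- sqrt(6 * delta_bg_power)
  ecog <- bg
  if (delta_amp > 0 && any(per_sample == "NREM")) {
    gate_n <- smooth_gate(as.numeric(per_sample == "NREM"), fs)
    ecog <- ecog + delta_amp * gate_n * band_noise(n, fs, 0.5, 4)
  }
  if (any(per_sample == "REM")) {
    gate_r <- smooth_gate(as.numeric(per_sample == "REM"), fs)
    ecog <- ecog + theta_amp * gate_r * band_noise(n, fs, 4, 8)
  }

  env <- preset$emg_rms_by_state[per_sample]
  env[is.na(env)] <- preset$emg_rms_by_state[["WAKE"]]  # transition/artifact
  emg <- smooth_gate(env, fs) * band_noise(n, fs, 20, min(100, fs / 2 - 5))

  signal_recording(list(ECoG = ecog, EMG = emg), fs, spec$subject_id, meta)
}

#' Synthesize a core-temperature trace coupled to NREM onsets
#'
#' Produces a 1 Hz trace: baseline + slow sinusoidal drift + measurement
#' noise, minus a drop component that relaxes toward
#' `temp_drop_magnitude_c` with time constant `temp_drop_tau_s` during
#' NREM bouts selected (independently, with probability `temp_drop_prob`)
#' to carry a drop, and back toward zero otherwise.
#'
#' @param hyp ground-truth [hypnogram].
#' @param preset a `genotype_preset`.
#' @param spec the [session_spec].
#' @param noise_sd measurement noise SD, degrees C (0 disables).
#' @param drift_amp amplitude of the slow drift, degrees C (0 disables).
#' @param drift_period_s drift period, seconds.
#' @return list with `trace` (a [temperature_trace]), `nrem_onsets_s`,
#'   `temp_drop_onsets_s` (the subset of onsets carrying an injected drop).
#' @export
synthesize_temperature <- function(hyp, preset, spec, noise_sd = 0.02,
                                   drift_amp = 0.05, drift_period_s = 1800) {
  set.seed(derive_seed(spec$seed, 3))
  ep <- hyp$epoch_length_s
  dur <- hypnogram_duration(hyp)
  tt <- seq(0, max(dur - 1, 0))
  lab <- hyp$labels
  r <- rle(lab)
  run_start <- cumsum(c(0, r$lengths[-length(r$lengths)])) * ep
  run_end <- cumsum(r$lengths) * ep
  is_nrem_run <- r$values == "NREM"
  nrem_onsets <- run_start[is_nrem_run]
  has_drop <- stats::runif(length(nrem_onsets)) < preset$temp_drop_prob
  drop_onsets <- nrem_onsets[has_drop]

  # per-second drop target: magnitude while inside a drop-carrying NREM bout
  target <- numeric(length(tt))
  ends <- run_end[is_nrem_run][has_drop]
  for (k in seq_along(drop_onsets)) {
    idx <- tt >= drop_onsets[k] & tt < ends[k]
    target[idx] <- preset$temp_drop_magnitude_c
  }
  depth <- numeric(length(tt))
  if (length(tt) > 1) {
    a <- 1 / preset$temp_drop_tau_s
    for (i in 2:length(tt)) {
      depth[i] <- depth[i - 1] + a * (target[i - 1] - depth[i - 1])
    }
  }
  phase <- stats::runif(1, 0, 2 * pi)
  drift <- drift_amp * sin(2 * pi * tt / drift_period_s + phase)
  noise <- if (noise_sd > 0) stats::rnorm(length(tt), 0, noise_sd) else 0
  temp <- preset$baseline_temp_c + drift + noise - depth
  list(trace = temperature_trace(tt, temp),
       nrem_onsets_s = nrem_onsets,
       temp_drop_onsets_s = drop_onsets)
}

#' Inject interictal spikes into an ECoG/LFP channel
#'
#' Adds brief biphasic (Gaussian-derivative, ~60 ms) transients at
#' homogeneous-Poisson times, with peak amplitude `amplitude_sd` times
#' the robust SD of the clean channel. A zero rate returns the input
#' unchanged.
#'
#' @param recording a [signal_recording].
#' @param preset a `genotype_preset` (uses `spike_rate_per_min`).
#' @param seed integer seed.
#' @param channel channel to spike (default `"ECoG"`).
#' @param amplitude_sd peak amplitude in robust-SD units of the clean signal.
#' @return list with `recording` (spiked) and `spike_times_s` (sorted).
#' @export
inject_interictal_spikes <- function(recording, preset, seed,
                                     channel = "ECoG", amplitude_sd = 6) {
  rate <- preset$spike_rate_per_min
  if (rate == 0 || recording_duration(recording) == 0) {
    return(list(recording = recording, spike_times_s = numeric(0)))
  }
  set.seed(derive_seed(seed, 4))
  fs <- recording$sample_rate_hz
  x <- recording$channels[[channel]]
  dur <- length(x) / fs
  n_spk <- stats::rpois(1, rate * dur / 60)
  times <- sort(stats::runif(n_spk, 0.1, dur - 0.1))
  amp <- amplitude_sd * robust_sd(x)
  s <- 0.008                                   # Gaussian-derivative width, s
  tk <- seq(-0.03, 0.03, by = 1 / fs)          # 60 ms support
  w <- -tk / s * exp(-tk^2 / (2 * s^2))
  w <- w / max(abs(w)) * amp
  for (t0 in times) {
    i0 <- round(t0 * fs)
    idx <- i0 + seq_along(w) - round(length(w) / 2)
    keep <- idx >= 1 & idx <= length(x)
    x[idx[keep]] <- x[idx[keep]] + w[keep]
  }
  recording$channels[[channel]] <- x
  list(recording = recording, spike_times_s = times)
}

#' Simulate one complete labeled session
#'
#' Convenience wrapper running the full generator chain: hypnogram,
#' signals, temperature and interictal spikes, returning the session with
#' its ground truth.
#'
#' @param spec a [session_spec].
#' @param noise_sd,drift_amp forwarded to [synthesize_temperature].
#' @return list with `spec`, `recording`, `trace`, `ground_truth` (fields
#'   `hypnogram`, `nrem_onsets_s`, `temp_drop_onsets_s`, `spike_times_s`).
#' @export
simulate_session <- function(spec, noise_sd = 0.02, drift_amp = 0.05) {
  hyp <- simulate_hypnogram(spec)
  rec <- synthesize_signals(hyp, spec$preset, spec)
  tmp <- synthesize_temperature(hyp, spec$preset, spec,
                                noise_sd = noise_sd, drift_amp = drift_amp)
  spk <- inject_interictal_spikes(rec, spec$preset, spec$seed)
  list(spec = spec, recording = spk$recording, trace = tmp$trace,
       ground_truth = list(hypnogram = hyp,
                           nrem_onsets_s = tmp$nrem_onsets_s,
                           temp_drop_onsets_s = tmp$temp_drop_onsets_s,
                           spike_times_s = spk$spike_times_s))
}

#' Generate a cohort of labeled synthetic sessions
#'
#' Per-subject seeds are derived deterministically from the master seed,
#' so the same master seed reproduces the cohort byte-for-byte. When
#' `out_dir` is given, each session's EDF, hypnogram CSV, temperature CSV
#' and spike-times CSV are written and listed in a manifest JSON.
#'
#' @param group_specs list of lists with fields `preset`
#'   (a `genotype_preset`), `n_subjects`, `ambient_blocks` and optionally
#'   `sample_rate_hz`.
#' @param seed master integer seed.
#' @param out_dir optional output directory.
#' @param ... forwarded to [simulate_session].
#' @return list of sessions (as from [simulate_session]); if `out_dir`
#'   is given, attribute `"manifest"` holds the manifest path.
#' @export
generate_cohort <- function(group_specs, seed, out_dir = NULL, ...) {
  sessions <- list()
  manifest <- list()
  g_i <- 0L
  for (g in group_specs) {
    g_i <- g_i + 1L
    stopifnot(g$n_subjects >= 1)
    for (i in seq_len(g$n_subjects)) {
      sid <- sprintf("%s_%02d", g$preset$name, i)
      sp <- session_spec(
        subject_id = sid, preset = g$preset,
        ambient_blocks = g$ambient_blocks,
        sample_rate_hz = if (is.null(g$sample_rate_hz)) 250 else
          g$sample_rate_hz,
        seed = derive_seed(seed, g_i * 1000 + i))
      ses <- simulate_session(sp, ...)
      sessions[[sid]] <- ses
      if (!is.null(out_dir)) {
        dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
        paths <- list(
          edf = file.path(out_dir, paste0(sid, ".edf")),
          hypnogram = file.path(out_dir, paste0(sid, "_hypnogram.csv")),
          temperature = file.path(out_dir, paste0(sid, "_temp.csv")),
          spikes = file.path(out_dir, paste0(sid, "_spikes.csv")))
        write_edf(ses$recording, paths$edf)
        write_hypnogram_csv(ses$ground_truth$hypnogram, paths$hypnogram)
        utils::write.csv(data.frame(time_s = ses$trace$time_s,
                                    temp_c = round(ses$trace$temp_c, 4)),
                         paths$temperature, row.names = FALSE, quote = FALSE)
        utils::write.csv(
          data.frame(spike_time_s = ses$ground_truth$spike_times_s),
          paths$spikes, row.names = FALSE, quote = FALSE)
        manifest[[sid]] <- c(list(subject_id = sid, preset = g$preset$name,
                                  duration_s = sp$duration_s,
                                  sample_rate_hz = sp$sample_rate_hz,
                                  seed = sp$seed), lapply(paths, basename))
      }
    }
  }
  if (!is.null(out_dir)) {
    mpath <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    attr(sessions, "manifest") <- mpath
  }
  sessions
}
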