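test_that("hypnogram simulation fills the epoch grid deterministically", {
  sp <- session_spec("s1", make_preset("WT"),
                     data.frame(label = "RT", duration_s = 3600), seed = 3L)
  h1 <- simulate_hypnogram(sp)
  h2 <- simulate_hypnogram(sp)
  expect_length(h1$labels, 720)
  expect_identical(h1$labels, h2$labels)

  expect_error(session_spec("s", make_preset("WT"),
                            data.frame(label = "RT", duration_s = 3601)),
               "multiple of the epoch length")
})

test_that("simulated NREM occupancy matches the analytic stationary value", {
  wt <- make_preset("WT")
  occ <- stationary_occupancy(wt, "RT")[["NREM"]]
  fracs <- vapply(1:10, function(i) {
    sp <- session_spec("s", wt, data.frame(label = "RT", duration_s = 7200),
                       seed = 400L + i)
    h <- simulate_hypnogram(sp)
    mean(h$labels == "NREM")
  }, numeric(1))
  expect_lt(abs(mean(fracs) - occ), 0.05)
})

test_that("warm blocks gain the configured NREM boost, per preset", {
  # hypnogram-only Monte Carlo: the mean warm-minus-RT NREM difference
  # matches the configured boost within its own Monte-Carlo error
  for (nm in c("WT", "DS")) {
    p <- make_preset(nm)
    blocks <- data.frame(label = c("RT", "WARM"),
                         duration_s = c(3600, 3600))
    diffs <- vapply(1:100, function(i) {
      sp <- session_spec("s", p, blocks, seed = 900L + i)
      h <- simulate_hypnogram(sp)
      (percent_time_in_state(h, "NREM", c(3600, 7200)) -
         percent_time_in_state(h, "NREM", c(0, 3600))) / 100
    }, numeric(1))
    mc_err <- 2.5 * sd(diffs) / sqrt(length(diffs))
    expect_lt(abs(mean(diffs) - p$warm_nrem_boost), mc_err)
  }
})

test_that("synthesized signals express the per-state spectral criteria", {
  wt <- make_preset("WT")
  sp <- session_spec("s", wt, data.frame(label = "RT", duration_s = 600),
                     seed = 7L)
  # all-NREM: delta power dominates theta in nearly every epoch
  rec_n <- synthesize_signals(uniform_hypnogram("NREM", 120), wt, sp)
  f_n <- compute_epoch_features(rec_n)
  expect_gte(mean(f_n$delta_power > f_n$theta_power), 0.95)
  # all-REM: theta/delta ratio clears the 2.5 REM criterion
  rec_r <- synthesize_signals(uniform_hypnogram("REM", 120), wt, sp)
  f_r <- compute_epoch_features(rec_r)
  expect_gte(mean(f_r$theta_delta_ratio > 2.5, na.rm = TRUE), 0.95)
  # determinism
  rec_n2 <- synthesize_signals(uniform_hypnogram("NREM", 120), wt, sp)
  expect_identical(rec_n$channels$ECoG, rec_n2$channels$ECoG)
})

test_that("a zero-duration session yields an empty recording", {
  wt <- make_preset("WT")
  sp0 <- session_spec("s", wt, data.frame(label = "RT", duration_s = 0),
                      seed = 1L)
  rec <- synthesize_signals(uniform_hypnogram("WAKE", 0), wt, sp0)
  expect_length(rec$channels$ECoG, 0)
  expect_equal(recording_duration(rec), 0)
})

test_that("signal synthesis rejects a hypnogram of the wrong length", {
  wt <- make_preset("WT")
  sp <- session_spec("s", wt, data.frame(label = "RT", duration_s = 600),
                     seed = 7L)
  expect_error(synthesize_signals(uniform_hypnogram("WAKE", 60), wt, sp),
               "does not match")
})

test_that("temperature drops obey the forced limits", {
  p <- make_preset("WT")
  p$temp_drop_prob <- 1
  # long alternating bouts: 300 s wake, 300 s NREM, 6 cycles
  lab <- rep(rep(c("WAKE", "NREM"), each = 60), 6)
  hyp <- hypnogram(lab, 5, "ground_truth")
  sp <- session_spec("s", p, data.frame(label = "RT",
                                        duration_s = length(lab) * 5),
                     seed = 5L)
  res <- synthesize_temperature(hyp, p, sp, noise_sd = 0, drift_amp = 0)
  expect_identical(res$temp_drop_onsets_s, res$nrem_onsets_s)
  for (o in res$nrem_onsets_s) {
    sel_base <- res$trace$time_s >= o - 30 & res$trace$time_s < o
    sel_low <- res$trace$time_s >= o + 240 & res$trace$time_s < o + 300
    drop <- mean(res$trace$temp_c[sel_base]) - mean(res$trace$temp_c[sel_low])
    expect_equal(drop, p$temp_drop_magnitude_c, tolerance = 0.05)
  }

  p0 <- make_preset("WT")
  p0$temp_drop_prob <- 0
  res0 <- synthesize_temperature(hyp, p0, sp, noise_sd = 0, drift_amp = 0)
  expect_lt(max(abs(res0$trace$temp_c - p0$baseline_temp_c)), 0.05)
  expect_length(res0$temp_drop_onsets_s, 0)
})

test_that("injected drop fraction converges to temp_drop_prob", {
  p <- make_preset("WT")
  # 220 wake/NREM cycles -> 220 onsets
  lab <- rep(rep(c("WAKE", "NREM"), each = 30), 220)
  hyp <- hypnogram(lab, 5, "ground_truth")
  sp <- session_spec("s", p,
                     data.frame(label = "RT", duration_s = length(lab) * 5),
                     seed = 9L)
  res <- synthesize_temperature(hyp, p, sp)
  n <- length(res$nrem_onsets_s)
  expect_gte(n, 200)
  frac <- length(res$temp_drop_onsets_s) / n
  se <- sqrt(0.65 * 0.35 / n)
  expect_lt(abs(frac - 0.65), 2 * se)
})

test_that("interictal spike injection matches its rate and amplitude contract", {
  ds <- make_preset("DS")
  sp <- session_spec("s", ds, data.frame(label = "RT", duration_s = 600),
                     seed = 21L)
  rec <- synthesize_signals(uniform_hypnogram("WAKE", 120), ds, sp)

  # rate 0: identity
  wt <- make_preset("WT")
  out0 <- inject_interictal_spikes(rec, wt, seed = 21L)
  expect_identical(out0$recording$channels$ECoG, rec$channels$ECoG)

  # rate 6/min over 10 min: count within 2 SE of Poisson(60)
  ds6 <- ds
  ds6$spike_rate_per_min <- 6
  out <- inject_interictal_spikes(rec, ds6, seed = 22L)
  n <- length(out$spike_times_s)
  expect_lt(abs(n - 60), 2 * sqrt(60))

  # every spike peak exceeds 5x the robust SD of the spike-free signal
  clean_sd <- mad(rec$channels$ECoG)
  fs <- rec$sample_rate_hz
  peaks <- vapply(out$spike_times_s, function(t0) {
    idx <- round(t0 * fs) + seq(-10, 10)
    max(abs(out$recording$channels$ECoG[idx]))
  }, numeric(1))
  expect_true(all(peaks > 5 * clean_sd))
})

test_that("cohort generation is deterministic and writes matching manifests", {
  g <- list(list(preset = make_preset("WT"), n_subjects = 6,
                 ambient_blocks = data.frame(label = "RT",
                                             duration_s = 300)))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  c1 <- generate_cohort(g, seed = 33L, out_dir = d1)
  c2 <- generate_cohort(g, seed = 33L, out_dir = d2)
  expect_length(c1, 6)
  expect_length(unique(names(c1)), 6)
  expect_identical(readLines(file.path(d1, "manifest.json")),
                   readLines(file.path(d2, "manifest.json")))
  expect_identical(c1$WT_01$recording$channels$ECoG,
                   c2$WT_01$recording$channels$ECoG)
  # written ground truth round-trips
  h <- read_hypnogram_csv(file.path(d1, "WT_01_hypnogram.csv"),
                          provenance = "ground_truth")
  expect_identical(h$labels, c1$WT_01$ground_truth$hypnogram$labels)
})
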