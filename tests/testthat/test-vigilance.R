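test_that("epoch features have the right count and degenerate behavior", {
  rec <- raw_recording(ECoG = rnorm(600 * 250), EMG = rnorm(600 * 250),
                       fs = 250)
  f <- compute_epoch_features(rec)
  expect_equal(nrow(f), 120)

  zeros <- raw_recording(ECoG = numeric(250 * 50), EMG = numeric(250 * 50),
                         fs = 250)
  fz <- compute_epoch_features(zeros)
  expect_true(all(fz$delta_power == 0))
  expect_true(all(is.na(fz$theta_delta_ratio)))

  no_emg <- raw_recording(ECoG = rnorm(2500), LFP = rnorm(2500), fs = 250)
  names(no_emg$channels) <- c("ECoG", "LFP")
  expect_error(compute_epoch_features(no_emg), "EMG")
})

test_that("Otsu threshold separates a bimodal log-normal EMG mixture", {
  set.seed(11)
  n <- 400
  truth <- rep(c(FALSE, TRUE), each = n)       # FALSE = sleep, TRUE = wake
  emg <- exp(c(rnorm(n, log(8), 0.15), rnorm(n, log(30), 0.15)))
  feats <- data.frame(emg_rms = emg,
                      delta_power = exp(rnorm(2 * n, 5, 0.3)),
                      theta_power = 1, total_power = 1,
                      theta_delta_ratio = 0.3, artifact_flag = FALSE)
  thr <- fit_thresholds(feats)
  misassigned <- mean((emg > thr$emg_wake_threshold) != truth)
  expect_lt(misassigned, 0.05)

  # rescaling all features 10x scales the thresholds by the same factor
  feats10 <- feats
  feats10$emg_rms <- feats$emg_rms * 10
  feats10$delta_power <- feats$delta_power * 10
  thr10 <- fit_thresholds(feats10)
  expect_equal(thr10$emg_wake_threshold, 10 * thr$emg_wake_threshold)
  expect_equal(thr10$delta_nrem_threshold, 10 * thr$delta_nrem_threshold)

  const <- feats
  const$emg_rms <- 5
  expect_error(fit_thresholds(const), "constant")
  expect_error(fit_thresholds(feats[1:50, ]), "100 epochs")
})

test_that("the decision cascade applies the stated state criteria", {
  thr <- structure(list(emg_wake_threshold = 15, delta_nrem_threshold = 100,
                        rem_theta_delta_threshold = 2.5,
                        artifact_amplitude_sd = 8),
                   class = "scoring_thresholds")
  f <- data.frame(
    emg_rms = c(30, 5, 5, 5, 5),
    theta_delta_ratio = c(3.0, 3.0, 1.0, 1.0, NA),
    delta_power = c(500, 50, 500, 50, 0),
    theta_power = 1, total_power = 1,
    artifact_flag = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  h <- classify_epochs(f, thr)
  # high EMG wins regardless of spectra; then REM ratio; then delta; then
  # quiet wake; artifact flag dominates everything
  expect_identical(h$labels, c("WAKE", "REM", "NREM", "WAKE", "ARTIFACT"))
  # determinism
  expect_identical(classify_epochs(f, thr)$labels, h$labels)
})

test_that("rule-based scoring recovers clean synthetic ground truth", {
  ses <- fixture_wt_session()
  sc <- score_session(ses$recording)
  agr <- score_agreement(sc$hypnogram, ses$ground_truth$hypnogram)
  expect_gte(agr$percent_agreement, 90)

  # wake/NREM confusion specifically is small
  truth <- ses$ground_truth$hypnogram$labels
  scored <- sc$hypnogram$labels
  wn <- truth %in% c("WAKE", "NREM") & scored %in% c("WAKE", "NREM")
  expect_lte(mean(truth[wn] != scored[wn]), 0.05)

  # every generator-planted eligible transition is recovered unless its
  # analysis window was hit by an artifact flag
  truth_onsets <- find_wake_to_nrem(ses$ground_truth$hypnogram)
  scored_onsets <- find_wake_to_nrem(sc$hypnogram)
  art_epochs <- which(scored == "ARTIFACT") - 1
  for (o in truth_onsets) {
    window_epochs <- seq(o / 5 - 24, o / 5 + 17)
    if (!any(window_epochs %in% art_epochs)) {
      expect_true(o %in% scored_onsets)
    }
  }
})

test_that("the 20-s alternation rule matches its spec'd examples", {
  h <- function(x) hypnogram(x, 5, "scored")
  W <- "WAKE"; N <- "NREM"; Tr <- "TRANSITION"
  expect_identical(apply_transition_rule(h(c(W, N, W, N)))$labels,
                   rep(Tr, 4))
  expect_identical(apply_transition_rule(h(c(W, W, W, N, N, N)))$labels,
                   c(W, W, W, N, N, N))
  # alternation followed by a stable (25 s) NREM run: the run keeps NREM
  x <- c(W, N, W, N, N, N, N, N)
  out <- apply_transition_rule(h(x))$labels
  expect_identical(out, c(Tr, Tr, Tr, rep(N, 5)))
})

test_that("the alternation rule matches an independent oracle exhaustively", {
  # all wake/NREM label strings of length <= 8
  for (len in 1:8) {
    grid <- expand.grid(rep(list(c("WAKE", "NREM")), len),
                        stringsAsFactors = FALSE)
    for (i in seq_len(nrow(grid))) {
      lab <- unlist(grid[i, ], use.names = FALSE)
      got <- apply_transition_rule(hypnogram(lab, 5, "scored"))$labels
      expect_identical(got, transition_rule_oracle(lab),
                       info = paste(lab, collapse = ","))
      # idempotence
      expect_identical(
        apply_transition_rule(hypnogram(got, 5, "scored"))$labels, got)
    }
  }
})

test_that("artifact detection flags forced exceedances and little else", {
  ses <- fixture_wt_session()
  f <- compute_epoch_features(ses$recording)
  flags <- detect_artifacts(ses$recording, f)
  expect_lt(mean(flags), 0.01)

  # inject a 10x robust-SD square pulse into one epoch
  rec <- ses$recording
  fs <- rec$sample_rate_hz
  sd_r <- mad(rec$channels$ECoG)
  idx <- (100 * 5 * fs):(100 * 5 * fs + fs)     # inside epoch 100
  rec$channels$ECoG[idx] <- 10 * sd_r
  f2 <- compute_epoch_features(rec)
  flags2 <- detect_artifacts(rec, f2)
  expect_true(flags2[101])

  zeros <- raw_recording(ECoG = numeric(250 * 600), EMG = numeric(250 * 600),
                         fs = 250)
  fz <- compute_epoch_features(zeros)
  expect_false(any(detect_artifacts(zeros, fz)))
})

test_that("scorer agreement counts identical non-artifact epochs", {
  h1 <- hypnogram(rep(c("WAKE", "NREM"), 50), 5, "scored")
  expect_equal(score_agreement(h1, h1)$percent_agreement, 100)

  flipped <- hypnogram(rep(c("NREM", "WAKE"), 50), 5, "scored")
  expect_equal(score_agreement(h1, flipped)$percent_agreement, 0)

  set.seed(3)
  lab <- h1$labels
  corrupt <- sample(100, 10)
  lab[corrupt] <- ifelse(lab[corrupt] == "WAKE", "NREM", "WAKE")
  h2 <- hypnogram(lab, 5, "scored")
  agr <- score_agreement(h1, h2)
  expect_equal(agr$percent_agreement, 90)
  expect_equal(sum(agr$agreed_mask), 90)

  expect_error(score_agreement(h1, hypnogram("WAKE", 5, "scored")),
               "different epoch grids")
})

test_that("percent_time_in_state handles the basic intervals", {
  all_n <- hypnogram(rep("NREM", 100), 5, "scored")
  expect_equal(percent_time_in_state(all_n, "NREM"), 100)

  half <- hypnogram(rep(c("NREM", "WAKE"), 50), 5, "scored")
  expect_equal(percent_time_in_state(half, "NREM"), 50)

  # artifacts leave the denominator
  mixed <- hypnogram(c(rep("NREM", 50), rep("ARTIFACT", 50)), 5, "scored")
  expect_equal(percent_time_in_state(mixed, "NREM"), 100)

  expect_error(percent_time_in_state(all_n, "NREM", c(600, 600)),
               "no scoreable epochs")
})
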