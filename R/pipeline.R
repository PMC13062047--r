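#' Run the transition pipeline over a cohort of sessions
#'
#' For each simulated (or loaded) session: score the vigilance states,
#' apply the 20-s transition rule, detect eligible wake-to-NREM
#' transitions, compute transition-locked spectra and classify the
#' coincident temperature change. Scoring is blind to the generator's
#' ground truth.
#'
#' @param sessions list of sessions as produced by [simulate_session] /
#'   [generate_cohort] (each with `recording` and `trace`), or lists with
#'   a pre-scored `hypnogram` plus `recording`/`trace`.
#' @param epsilon temperature dead band, degrees C.
#' @return list with `events` (all transition events, one data.frame),
#'   `per_subject` (from [per_subject_average]) and `hypnograms` (the
#'   scored hypnograms).
#' @export
run_transition_pipeline <- function(sessions, epsilon = 0.1) {
  all_events <- list()
  hyps <- list()
  for (sid in names(sessions)) {
    s <- sessions[[sid]]
    hyp <- s$hypnogram
    if (is.null(hyp)) hyp <- score_session(s$recording)$hypnogram
    hyps[[sid]] <- hyp
    ev <- session_transition_events(s$recording, hyp, s$trace,
                                    subject_id = sid, epsilon = epsilon)
    all_events[[sid]] <- ev
  }
  psds <- do.call(c, lapply(all_events, attr, "psds"))
  events <- do.call(rbind, all_events)
  rownames(events) <- NULL
  attr(events, "psds") <- psds
  list(events = events,
       per_subject = if (nrow(events)) per_subject_average(events) else NULL,
       hypnograms = hyps)
}

#' Transition-temperature coupling experiment over genotype groups
#'
#' End-to-end replication harness for the transition analysis: simulates
#' one cohort per group, runs the full scoring + transition pipeline,
#' builds the group x temperature-class contingency table and applies
#' the two-sided exact r x c test.
#'
#' @param groups named list; each element has `preset`
#'   (a `genotype_preset`), `n_subjects`, and `duration_s` (RT-only
#'   sessions of that length).
#' @param seed master seed.
#' @param epsilon temperature dead band.
#' @param sample_rate_hz generator sampling rate.
#' @return list with `events_by_group`, `per_subject_by_group`,
#'   `contingency`, `fisher`, `pct_negative` (named per group).
#' @export
transition_experiment <- function(groups, seed, epsilon = 0.1,
                                  sample_rate_hz = 250) {
  events_by_group <- list()
  per_subject <- list()
  g_i <- 0L
  for (g in names(groups)) {
    g_i <- g_i + 1L
    sp <- groups[[g]]
    sessions <- generate_cohort(
      list(list(preset = sp$preset, n_subjects = sp$n_subjects,
                ambient_blocks = data.frame(label = "RT",
                                            duration_s = sp$duration_s),
                sample_rate_hz = sample_rate_hz)),
      seed = derive_seed(seed, 7000 + g_i))
    res <- run_transition_pipeline(sessions, epsilon = epsilon)
    events_by_group[[g]] <- res$events
    per_subject[[g]] <- res$per_subject
  }
  ct <- build_transition_contingency(events_by_group)
  # temperature classes observed in neither group carry no information
  # and would violate the exact test's no-empty-column contract
  fish <- fisher_exact_rxc(ct[, colSums(ct) > 0, drop = FALSE])
  pct_neg <- vapply(events_by_group, function(e) {
    100 * sum(e$temp_class == "negative", na.rm = TRUE) /
      sum(!is.na(e$temp_class))
  }, numeric(1))
  list(events_by_group = events_by_group,
       per_subject_by_group = per_subject,
       contingency = ct, fisher = fish, pct_negative = pct_neg)
}

#' Warmth-somnogenesis experiment over genotype groups
#'
#' Simulates cohorts with one RT hour followed by one WARM hour, scores
#' them, and quantifies %NREM per block per subject.
#'
#' @param presets named list of `genotype_preset`s (names are group
#'   labels).
#' @param n_per_group subjects per group.
#' @param block_s duration of each of the two blocks, seconds.
#' @param seed master seed.
#' @param sample_rate_hz generator sampling rate.
#' @return the [warmth_experiment] result, with the session table
#'   carrying group labels.
#' @export
warmth_experiment_synthetic <- function(presets, n_per_group = 7,
                                        block_s = 3600, seed = 1L,
                                        sample_rate_hz = 250) {
  blocks <- data.frame(label = c("RT", "WARM"),
                       duration_s = c(block_s, block_s))
  sessions <- list()
  g_i <- 0L
  for (g in names(presets)) {
    g_i <- g_i + 1L
    cohort <- generate_cohort(
      list(list(preset = presets[[g]], n_subjects = n_per_group,
                ambient_blocks = blocks, sample_rate_hz = sample_rate_hz)),
      seed = derive_seed(seed, 8000 + g_i))
    for (sid in names(cohort)) {
      sessions[[sid]] <- list(
        hypnogram = score_session(cohort[[sid]]$recording)$hypnogram,
        ambient_blocks = blocks, group = g)
    }
  }
  warmth_experiment(sessions)
}
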