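#' Genotype presets for the synthetic polysomnography generator
#'
#' Each preset bundles the generator parameters that distinguish the three
#' study groups: wild-type (`WT`), the Dravet-syndrome model (`DS`) and the
#' hypothalamically rescued model (`DS_RESCUED`).
#'
#' The two parameters with published anchors are the probability that a
#' wake-to-NREM transition is accompanied by a core-temperature drop
#' (0.65 for WT, 0.21 for DS) and the absent warmth response of the DS
#' group (`warm_nrem_boost = 0`). The DS preset has no NREM delta surge
#' (`nrem_delta_gain = 1`), reflecting the attenuated contribution of
#' delta power at NREM onset in the model. Remaining values (bout
#' dynamics, drop kinetics, EMG amplitudes, baseline temperature offset)
#' are modeling choices documented in the methods vignette.
#'
#' @param name one of `"WT"`, `"DS"`, `"DS_RESCUED"`.
#' @return an object of class `genotype_preset`: a list with fields
#'   `name`, `bout_mean_s`, `state_entry_probs`, `nrem_delta_gain`,
#'   `temp_drop_prob`, `temp_drop_magnitude_c`, `temp_drop_tau_s`,
#'   `baseline_temp_c`, `warm_nrem_boost`, `spike_rate_per_min`,
#'   `emg_rms_by_state`.
#' @examples
#' p <- make_preset("WT")
#' p$temp_drop_prob   # 0.65
#' @export
make_preset <- function(name) {
  valid <- c("WT", "DS", "DS_RESCUED")
  if (length(name) != 1 || !toupper(name) %in% valid) {
    stop("unknown preset '", name, "'; valid presets: ",
         paste(valid, collapse = ", "))
  }
  name <- toupper(name)
  # Embedded chain over WAKE/NREM/REM at room temperature: wake always
  # yields to NREM; REM is entered only from NREM and rarely (short-term
  # daytime recordings in this model essentially never reach REM).
  entry <- matrix(c(0, 1, 0,
                    0.98, 0, 0.02,
                    1, 0, 0),
                  nrow = 3, byrow = TRUE,
                  dimnames = list(c("WAKE", "NREM", "REM"),
                                  c("WAKE", "NREM", "REM")))
  p <- list(
    name = name,
    bout_mean_s = c(WAKE = 150, NREM = 120, REM = 60),
    state_entry_probs = entry,
    nrem_delta_gain = 3,
    temp_drop_prob = 0.65,
    temp_drop_magnitude_c = 0.4,
    temp_drop_tau_s = 60,
    baseline_temp_c = 37,
    warm_nrem_boost = 0.15,
    spike_rate_per_min = 0,
    emg_rms_by_state = c(WAKE = 30, NREM = 8, REM = 5)
  )
  if (name == "DS") {
    p$temp_drop_prob <- 0.21
    p$nrem_delta_gain <- 1
    p$baseline_temp_c <- 36.2     # reduced baseline; magnitude a free choice
    p$warm_nrem_boost <- 0
    p$spike_rate_per_min <- 2
  } else if (name == "DS_RESCUED") {
    # hypothalamic rescue: warmth response and delta surge restored,
    # epileptiform activity unchanged
    p$nrem_delta_gain <- 2.5
    p$baseline_temp_c <- 36.2
    p$spike_rate_per_min <- 2
  }
  class(p) <- "genotype_preset"
  validate_preset(p)
  p
}

#' Validate a genotype preset
#'
#' Checks the structural invariants: probabilities in \[0, 1\], entry-prob
#' rows summing to 1, bout means longer than one epoch, baseline
#' temperature in \[34, 39\] degrees C, non-negative spike rate (zero for WT).
#'
#' @param preset a `genotype_preset`.
#' @param epoch_length_s epoch length used by the hypnogram grid.
#' @return the preset, invisibly; errors on violation.
#' @export
validate_preset <- function(preset, epoch_length_s = 5) {
  stopifnot(inherits(preset, "genotype_preset"))
  P <- preset$state_entry_probs
  if (any(P < 0) || any(P > 1) || any(abs(rowSums(P) - 1) > 1e-8)) {
    stop("state_entry_probs rows must be probabilities summing to 1")
  }
  if (preset$temp_drop_prob < 0 || preset$temp_drop_prob > 1) {
    stop("temp_drop_prob must lie in [0, 1]")
  }
  if (preset$warm_nrem_boost < 0 || preset$warm_nrem_boost > 1) {
    stop("warm_nrem_boost must lie in [0, 1]")
  }
  if (any(preset$bout_mean_s <= epoch_length_s)) {
    stop("bout means must exceed the epoch length")
  }
  if (preset$baseline_temp_c < 34 || preset$baseline_temp_c > 39) {
    stop("baseline_temp_c must lie in [34, 39]")
  }
  if (preset$spike_rate_per_min < 0) stop("spike_rate_per_min must be >= 0")
  if (preset$name == "WT" && preset$spike_rate_per_min != 0) {
    stop("WT preset must have zero interictal spike rate")
  }
  if (preset$nrem_delta_gain < 1) stop("nrem_delta_gain must be >= 1")
  invisible(preset)
}

#' @export
print.genotype_preset <- function(x, ...) {
  cat(sprintf(paste0("<genotype_preset> %s: drop prob %.2f (%.2f C, tau %g s), ",
                     "delta gain %.1f, warm boost %.2f, spikes %.1f/min\n"),
              x$name, x$temp_drop_prob, x$temp_drop_magnitude_c,
              x$temp_drop_tau_s, x$nrem_delta_gain, x$warm_nrem_boost,
              x$spike_rate_per_min))
  invisible(x)
}

#' Stationary state occupancy of the bout model
#'
#' For the alternating-renewal (semi-Markov) bout model, the long-run
#' fraction of time in each state is `nu_i * m_i / sum_j nu_j * m_j`,
#' where `nu` is the stationary distribution of the embedded entry chain
#' and `m` the mean bout length per visit. This closed form is what the
#' warm-block adjustment solves against and what the Monte-Carlo
#' occupancy tests compare to.
#'
#' @param preset a `genotype_preset`.
#' @param ambient `"RT"` or `"WARM"`; the warm block uses the
#'   warmth-adjusted entry chain (see [warm_entry_probs]).
#' @return named numeric vector of occupancies over WAKE/NREM/REM.
#' @export
stationary_occupancy <- function(preset, ambient = c("RT", "WARM")) {
  ambient <- match.arg(ambient)
  P <- if (ambient == "WARM") warm_entry_probs(preset) else
    preset$state_entry_probs
  nu <- embedded_stationary(P)
  w <- nu * preset$bout_mean_s[rownames(P)]
  w / sum(w)
}

embedded_stationary <- function(P) {
  # stationary distribution of the embedded (entry) chain: nu P = nu
  k <- nrow(P)
  A <- rbind(t(P) - diag(k), rep(1, k))
  b <- c(rep(0, k), 1)
  nu <- qr.solve(A, b)
  names(nu) <- rownames(P)
  pmax(nu, 0) / sum(pmax(nu, 0))
}

#' Warm-block entry probabilities
#'
#' Warmth-induced somnogenesis is encoded as a change in the entry chain,
#' not in bout lengths: a NREM self-re-entry probability `q` is introduced
#' (at bout end the subject starts a fresh NREM bout with probability `q`),
#' and `q` is solved numerically so that stationary NREM occupancy rises
#' by exactly `warm_nrem_boost` over the room-temperature value. With
#' `warm_nrem_boost = 0` (the DS preset) the chain is unchanged.
#'
#' @param preset a `genotype_preset`.
#' @return a 3x3 entry-probability matrix for the warm block.
#' @export
warm_entry_probs <- function(preset) {
  P0 <- preset$state_entry_probs
  b <- preset$warm_nrem_boost
  if (b == 0) return(P0)
  m <- preset$bout_mean_s[rownames(P0)]
  occ0 <- stationary_occupancy(preset, "RT")[["NREM"]]
  target <- occ0 + b
  if (target >= 0.98) stop("warm_nrem_boost pushes NREM occupancy above 0.98")
  occ_at <- function(q) {
    P <- P0
    P["NREM", ] <- c((1 - q) * P0["NREM", "WAKE"], q,
                     (1 - q) * P0["NREM", "REM"])
    nu <- embedded_stationary(P)
    w <- nu * m
    (w / sum(w))[["NREM"]]
  }
  q <- stats::uniroot(function(q) occ_at(q) - target,
                      interval = c(0, 0.995), tol = 1e-10)$root
  P <- P0
  P["NREM", ] <- c((1 - q) * P0["NREM", "WAKE"], q,
                   (1 - q) * P0["NREM", "REM"])
  P
}
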