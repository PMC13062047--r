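#' Two-sided exact test for an r x c contingency table
#'
#' Freeman--Halton extension of Fisher's exact test: under fixed margins
#' the table probability is multivariate hypergeometric, and the
#' two-sided p-value is the total probability of all tables whose
#' probability does not exceed the observed table's (probability-ordering
#' criterion). Small tables are enumerated exhaustively; tables whose
#' enumeration would exceed `max_tables` fall back (or are forced with
#' `method = "mc"`) to seeded Monte-Carlo sampling of fixed-margin tables
#' via Patefield's algorithm.
#'
#' @param table integer matrix of counts (>= 2x2, no empty row/column).
#' @param method `"auto"`, `"exact"` or `"mc"`.
#' @param max_tables enumeration budget.
#' @param mc_reps Monte-Carlo replicates.
#' @param seed seed for the Monte-Carlo fallback.
#' @return list (class `somno_test`) with `method`, `p_value`,
#'   `table_dims`, and for MC mode `mc_se`.
#' @examples
#' fisher_exact_rxc(matrix(c(3, 1, 1, 3), 2))$p_value  # 34/70
#' @export
fisher_exact_rxc <- function(table, method = c("auto", "exact", "mc"),
                             max_tables = 2e6, mc_reps = 1e5, seed = 1L) {
  method <- match.arg(method)
  tab <- as.matrix(table)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("table must contain non-negative integer counts")
  }
  if (nrow(tab) < 2 || ncol(tab) < 2) stop("table must be at least 2x2")
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) {
    stop("table has an empty row or column")
  }
  n <- sum(tab)
  const <- sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(n + 1)
  logp_obs <- const - sum(lgamma(tab + 1))
  tol <- 1e-7

  if (method != "mc") {
    res <- enumerate_tables(rs, cs, logp_obs + tol, const, max_tables)
    if (!is.null(res)) {
      return(structure(list(method = "fisher_exact_rxc (enumeration)",
                            p_value = min(1, res), table_dims = dim(tab)),
                       class = "somno_test"))
    }
    if (method == "exact") {
      stop("enumeration budget (", max_tables, " tables) exceeded; use ",
           "method = 'mc' (seeded Monte-Carlo)")
    }
  }
  set.seed(seed)
  sims <- stats::r2dtable(mc_reps, rs, cs)
  logp <- vapply(sims, function(s) const - sum(lgamma(s + 1)), numeric(1))
  hits <- logp <= logp_obs + tol
  p <- (sum(hits) + 1) / (mc_reps + 1)
  structure(list(method = "fisher_exact_rxc (Monte-Carlo)",
                 p_value = p, table_dims = dim(tab),
                 mc_se = stats::sd(hits) / sqrt(mc_reps)),
            class = "somno_test")
}

# DFS over all tables with the given margins; returns the summed
# probability of tables with log-probability <= cutoff, or NULL if more
# than max_tables tables were visited.
enumerate_tables <- function(rs, cs, cutoff, const, max_tables) {
  r <- length(rs); cc <- length(cs)
  count <- 0L
  total <- 0
  cell <- matrix(0L, r, cc)
  rec <- function(i, j, row_left, col_left, lg_acc) {
    if (count > max_tables) return(invisible(NULL))
    if (i == r) {
      # last row forced by column margins
      lg <- lg_acc + sum(lgamma(col_left + 1))
      count <<- count + 1L
      if (count > max_tables) return(invisible(NULL))
      lp <- const - lg
      if (lp <= cutoff) total <<- total + exp(lp)
      return(invisible(NULL))
    }
    if (j == cc) {
      # last cell of row forced by row margin
      if (row_left > col_left[cc]) return(invisible(NULL))
      col_left2 <- col_left
      col_left2[cc] <- col_left2[cc] - row_left
      rec(i + 1L, 1L, rs[i + 1L], col_left2, lg_acc + lgamma(row_left + 1))
      return(invisible(NULL))
    }
    hi <- min(row_left, col_left[j])
    for (v in 0:hi) {
      col_left2 <- col_left
      col_left2[j] <- col_left2[j] - v
      rec(i, j + 1L, row_left - v, col_left2, lg_acc + lgamma(v + 1))
      if (count > max_tables) return(invisible(NULL))
    }
    invisible(NULL)
  }
  rec(1L, 1L, rs[1], cs, 0)
  if (count > max_tables) NULL else total
}

#' @export
print.somno_test <- function(x, ...) {
  cat("<", x$method, "> p = ", format.pval(x$p_value, digits = 4), "\n",
      sep = "")
  invisible(x)
}

#' Holm--Sidak step-down adjusted p-values
#'
#' Sort p-values ascending; the i-th smallest is adjusted to
#' `max_{j <= i} (1 - (1 - p_(j))^(m - j + 1))`, clipped at 1, and the
#' adjusted values are returned in the input order. Adjusted values are
#' never below the raw ones and are monotone in the sorted order.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same order as the input.
#' @examples
#' holm_sidak(c(0.01, 0.04, 0.03))
#' @export
holm_sidak <- function(p_values) {
  p <- as.numeric(p_values)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  ps <- p[o]
  adj <- cummax(1 - (1 - ps)^(m - seq_len(m) + 1))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Two-way ANOVA (between-subjects or repeated on one factor)
#'
#' The package's one delegated statistic: fits via [stats::aov]. For the
#' between-subjects design, unbalanced data use Type II sums of squares
#' ([car::Anova]); balanced data give the classical decomposition. The
#' repeated-measures variant (for within-subject temperature blocks)
#' uses an `Error(subject)` stratum on `factor_b`.
#'
#' @param values numeric response.
#' @param factor_a,factor_b factors (coerced).
#' @param subject subject identifiers; required when `repeated = TRUE`.
#' @param repeated treat `factor_b` as within-subject.
#' @return data.frame with columns `term`, `df`, `F`, `p_value` covering
#'   both main effects and the interaction.
#' @export
two_way_anova <- function(values, factor_a, factor_b, subject = NULL,
                          repeated = FALSE) {
  a <- factor(factor_a); b <- factor(factor_b)
  if (nlevels(a) < 2 || nlevels(b) < 2) {
    stop("both factors need at least 2 levels")
  }
  d <- data.frame(y = values, A = a, B = b)
  if (repeated) {
    if (is.null(subject)) stop("repeated = TRUE requires subject ids")
    d$S <- factor(subject)
    fit <- stats::aov(y ~ A * B + Error(S), data = d)
    sm <- summary(fit)
    rows <- do.call(rbind, lapply(sm, function(stratum) {
      tt <- stratum[[1]]
      nr <- nrow(tt)
      data.frame(term = trimws(rownames(tt)), df = tt$Df,
                 F = if (is.null(tt$`F value`)) rep(NA_real_, nr) else
                   tt$`F value`,
                 p_value = if (is.null(tt$`Pr(>F)`)) rep(NA_real_, nr) else
                   tt$`Pr(>F)`)
    }))
    rows <- rows[rows$term %in% c("A", "B", "A:B"), ]
  } else {
    counts <- table(a, b)
    if (length(unique(as.vector(counts))) == 1) {
      tt <- summary(stats::aov(y ~ A * B, data = d))[[1]]
      rows <- data.frame(term = trimws(rownames(tt)), df = tt$Df,
                         F = tt$`F value`, p_value = tt$`Pr(>F)`)
      rows <- rows[rows$term != "Residuals", ]
    } else {
      tt <- car::Anova(stats::lm(y ~ A * B, data = d), type = 2)
      rows <- data.frame(term = rownames(tt), df = tt$Df,
                         F = tt$`F value`, p_value = tt$`Pr(>F)`)
      rows <- rows[rows$term != "Residuals", ]
    }
  }
  lev <- c(A = "factor_a", B = "factor_b", `A:B` = "interaction")
  rows$term <- unname(lev[rows$term])
  rownames(rows) <- NULL
  rows
}

#' Count interictal spikes
#'
#' Threshold-crossing detector on the 20--80 Hz-emphasized signal:
#' samples whose absolute filtered amplitude exceeds `k` robust SDs mark
#' candidate events; candidates within `refractory_s` of a previous
#' event merge into it. Deterministic.
#'
#' @param recording a [signal_recording].
#' @param channel signal channel.
#' @param k threshold in robust SDs of the filtered signal.
#' @param refractory_s merge window, seconds.
#' @param band emphasis band, Hz.
#' @return list with `count` and `spike_times_s` (event onset times).
#' @export
count_interictal_spikes <- function(recording, channel = "ECoG", k = 5,
                                    refractory_s = 0.2, band = c(20, 80)) {
  if (!channel %in% names(recording$channels)) {
    stop("no channel named '", channel, "'")
  }
  fs <- recording$sample_rate_hz
  x <- recording$channels[[channel]]
  if (length(x) == 0) return(list(count = 0L, spike_times_s = numeric(0)))
  y <- fft_bandpass(x, fs, band[1], min(band[2], fs / 2 - 1))
  thr <- k * robust_sd(y)
  if (!is.finite(thr) || thr <= 0) {
    return(list(count = 0L, spike_times_s = numeric(0)))
  }
  idx <- which(abs(y) > thr)
  if (length(idx) == 0) return(list(count = 0L, spike_times_s = numeric(0)))
  gap <- round(refractory_s * fs)
  keep <- c(TRUE, diff(idx) > gap)
  times <- (idx[keep] - 1) / fs
  list(count = length(times), spike_times_s = times)
}

#' Warmth-induced somnogenesis analysis
#'
#' For each session with labeled RT and WARM blocks, computes the percent
#' of time in NREM per block from the scored hypnogram (an optional
#' exclusion window at block start mirrors drug-absorption exclusions),
#' then fits a two-way ANOVA of %NREM on group x block with block as the
#' within-subject factor.
#'
#' @param sessions named list; each element has `hypnogram` (scored),
#'   `ambient_blocks` (data.frame `label`, `duration_s`), and `group`.
#' @param exclude_start_s seconds excluded at the start of each block.
#' @return list with `table` (subject, group, block, pct_nrem),
#'   `paired` (per-subject WARM - RT differences) and `anova`.
#' @export
warmth_experiment <- function(sessions, exclude_start_s = 0) {
  rows <- list()
  for (sid in names(sessions)) {
    s <- sessions[[sid]]
    blocks <- s$ambient_blocks
    if (!all(c("RT", "WARM") %in% blocks$label)) {
      stop("session ", sid, " is missing an RT or WARM block label")
    }
    ends <- cumsum(blocks$duration_s)
    starts <- c(0, ends[-length(ends)])
    for (bi in seq_len(nrow(blocks))) {
      pct <- percent_time_in_state(
        s$hypnogram, "NREM",
        c(starts[bi] + exclude_start_s, ends[bi]))
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = sid, group = s$group, block = blocks$label[bi],
        pct_nrem = pct)
    }
  }
  tab <- do.call(rbind, rows)
  wide <- merge(tab[tab$block == "RT", c("subject_id", "group", "pct_nrem")],
                tab[tab$block == "WARM", c("subject_id", "pct_nrem")],
                by = "subject_id", suffixes = c("_rt", "_warm"))
  wide$diff <- wide$pct_nrem_warm - wide$pct_nrem_rt
  an <- if (length(unique(tab$group)) >= 2) {
    two_way_anova(tab$pct_nrem, tab$group, tab$block,
                  subject = tab$subject_id, repeated = TRUE)
  } else NULL
  list(table = tab, paired = wide, anova = an)
}

#' Write the analysis report
#'
#' Writes tidy CSV tables (per-subject delta ratios, the transition
#' contingency table, %NREM by block) and a JSON summary holding every
#' test result plus the configuration snapshot. Deterministic given its
#' inputs; an empty cohort yields empty tables, valid JSON and a warning.
#'
#' @param out_dir output directory (created if needed).
#' @param subject_summaries data.frame from [per_subject_average]
#'   (or NULL).
#' @param contingency a `contingency_table` (or NULL).
#' @param warmth result of [warmth_experiment] (or NULL).
#' @param tests named list of test results (`somno_test` or numeric).
#' @param config named list snapshot of analysis parameters.
#' @return named character vector of written paths, invisibly.
#' @export
build_report <- function(out_dir, subject_summaries = NULL,
                         contingency = NULL, warmth = NULL,
                         tests = list(), config = list()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  empty <- is.null(subject_summaries) || nrow(subject_summaries) == 0
  if (empty) warning("empty cohort: writing empty report tables")

  p <- file.path(out_dir, "subject_delta_ratios.csv")
  ss <- if (is.null(subject_summaries)) {
    data.frame(subject_id = character(0), n_events = integer(0),
               wake_delta_ratio = numeric(0), nrem_delta_ratio = numeric(0))
  } else subject_summaries
  utils::write.csv(ss, p, row.names = FALSE, quote = FALSE)
  paths["subject_delta_ratios"] <- p

  p <- file.path(out_dir, "transition_contingency.csv")
  ct <- if (is.null(contingency)) {
    data.frame(group = character(0), negative = integer(0),
               unchanged = integer(0), positive = integer(0))
  } else {
    cbind(data.frame(group = rownames(contingency)),
          as.data.frame(unclass(contingency)))
  }
  utils::write.csv(ct, p, row.names = FALSE, quote = FALSE)
  paths["transition_contingency"] <- p

  p <- file.path(out_dir, "pct_nrem_by_block.csv")
  wt <- if (is.null(warmth)) {
    data.frame(subject_id = character(0), group = character(0),
               block = character(0), pct_nrem = numeric(0))
  } else warmth$table
  utils::write.csv(wt, p, row.names = FALSE, quote = FALSE)
  paths["pct_nrem_by_block"] <- p

  p <- file.path(out_dir, "summary.json")
  summary <- list(
    tests = lapply(tests, function(t) if (inherits(t, "somno_test"))
      unclass(t) else t),
    config = config,
    n_subjects = if (empty) 0L else nrow(ss))
  jsonlite::write_json(summary, p, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  paths["summary"] <- p
  invisible(paths)
}
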