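test_that("the exact r x c test reproduces hand-enumerable cases", {
  # margins (4,4)/(4,4): full enumeration gives p = 34/70
  res <- fisher_exact_rxc(matrix(c(3, 1, 1, 3), 2, byrow = TRUE))
  expect_equal(res$p_value, 34 / 70, tolerance = 1e-12)

  # identical rows: the observed table is modal, p = 1
  res1 <- fisher_exact_rxc(matrix(c(5, 2, 1, 5, 2, 1), 2, byrow = TRUE))
  expect_equal(res1$p_value, 1, tolerance = 1e-12)

  expect_error(fisher_exact_rxc(matrix(c(1, 0, 2, 0), 2)), "empty")
  expect_error(fisher_exact_rxc(matrix(c(1.5, 1, 1, 1), 2)), "integer")
})

test_that("enumeration agrees with the reference implementation on random tables", {
  set.seed(14)
  for (i in 1:250) {
    repeat {
      dims <- if (i %% 2 == 0) c(2, 2) else c(2, 3)
      n <- sample(8:40, 1)
      tab <- matrix(rmultinom(1, n, rep(1, prod(dims))), dims[1])
      if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) break
    }
    ours <- fisher_exact_rxc(tab, method = "exact")$p_value
    ref <- stats::fisher.test(tab)$p.value
    expect_equal(ours, ref, tolerance = 1e-7,
                 info = paste(tab, collapse = ","))
  }
})

test_that("the Monte-Carlo fallback approximates the exact p-value", {
  tab <- matrix(c(12, 7, 3, 4, 9, 10), 2, byrow = TRUE)
  exact <- fisher_exact_rxc(tab, method = "exact")$p_value
  mc <- fisher_exact_rxc(tab, method = "mc", mc_reps = 2e4, seed = 5)
  expect_lt(abs(mc$p_value - exact), 5 * mc$mc_se + 1e-3)
  # seeded: reproducible
  mc2 <- fisher_exact_rxc(tab, method = "mc", mc_reps = 2e4, seed = 5)
  expect_identical(mc$p_value, mc2$p_value)
})

test_that("the exact test rejects at or below the nominal rate under the null", {
  set.seed(99)
  n_rep <- 5000
  rej <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    repeat {
      # independent margins: multinomial with product cell probabilities
      pr <- c(0.3, 0.2) %o% c(0.4, 0.35, 0.25)
      tab <- matrix(rmultinom(1, 30, as.vector(pr / sum(pr))), 2)
      if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) break
    }
    rej[i] <- fisher_exact_rxc(tab)$p_value <= 0.05
  }
  expect_lte(mean(rej), 0.06)
})

test_that("Holm-Sidak adjustment follows the step-down formula", {
  expect_equal(holm_sidak(0.04), 0.04)
  # hand evaluation: sorted (0.01, 0.03, 0.04), m = 3:
  #   1 - 0.99^3 = 0.029701; max(., 1 - 0.97^2) = 0.059100; max(., 1 - 0.96)
  #   = 0.059100 -> back in input order
  expect_equal(holm_sidak(c(0.01, 0.04, 0.03)),
               c(0.029701, 0.0591, 0.0591), tolerance = 1e-6)
  expect_equal(holm_sidak(c(1, 1, 1)), c(1, 1, 1))
  expect_error(holm_sidak(c(0.5, 1.2)), "\\[0, 1\\]")

  # properties: adjusted >= raw, monotone in sorted order, clipped at 1
  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(2:10, 1))
    adj <- holm_sidak(p)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
})

test_that("two-way ANOVA matches a hand-computed balanced decomposition", {
  # balanced 2x2, n = 3 per cell
  d <- expand.grid(a = c("lo", "hi"), b = c("L", "R"), rep = 1:3)
  set.seed(2)
  d$y <- with(d, 10 + 3 * (a == "hi") + 5 * (b == "R") +
                2 * (a == "hi" & b == "R") + rnorm(nrow(d)))
  res <- two_way_anova(d$y, d$a, d$b)

  # independent oracle: classical sums of squares computed from means
  gm <- mean(d$y)
  ssa <- sum(tapply(d$y, d$a, function(v) length(v) * (mean(v) - gm)^2))
  ssb <- sum(tapply(d$y, d$b, function(v) length(v) * (mean(v) - gm)^2))
  cellm <- tapply(d$y, list(d$a, d$b), mean)
  am <- tapply(d$y, d$a, mean); bm <- tapply(d$y, d$b, mean)
  ssab <- 3 * sum((cellm - outer(am, rep(1, 2)) -
                     outer(rep(1, 2), bm) + gm)^2)
  sse <- sum((d$y - ave(d$y, d$a, d$b))^2)
  dfe <- nrow(d) - 4
  f_oracle <- c(ssa / (sse / dfe), ssb / (sse / dfe), ssab / (sse / dfe))
  expect_equal(res$F, unname(f_oracle), tolerance = 1e-8)

  expect_error(two_way_anova(d$y, rep("x", nrow(d)), d$b), "2 levels")
})

test_that("two-way ANOVA is calibrated under the null and powered under effects", {
  set.seed(6)
  ps <- replicate(100, {
    a <- rep(c("g1", "g2"), each = 20)
    b <- rep(rep(c("L", "R"), each = 10), 2)
    y <- rnorm(40)
    min(two_way_anova(y, a, b)$p_value)
  })
  expect_gt(median(ps), 0.1)                 # no effect: ps roughly uniform

  set.seed(12)
  a <- rep(c("g1", "g2"), each = 10)
  b <- rep(rep(c("L", "R"), each = 5), 2)
  y <- rnorm(20) + 5 * (a == "g2")           # 5 sigma main effect
  res <- two_way_anova(y, a, b)
  expect_lt(res$p_value[res$term == "factor_a"], 0.001)

  # repeated-measures variant runs and returns all three terms
  subj <- rep(1:10, each = 2)
  g <- rep(rep(c("WT", "DS"), each = 2), 5)
  blk <- rep(c("RT", "WARM"), 10)
  yy <- rnorm(20) + 3 * (blk == "WARM" & g == "WT")
  rm_res <- two_way_anova(yy, g, blk, subject = subj, repeated = TRUE)
  expect_setequal(rm_res$term, c("factor_a", "factor_b", "interaction"))
})

test_that("spike counting reaches the recall/false-positive contract", {
  wt <- make_preset("WT")
  sp <- session_spec("s", wt, data.frame(label = "RT", duration_s = 600),
                     seed = 31L)
  rec <- synthesize_signals(uniform_hypnogram("WAKE", 120), wt, sp)
  expect_equal(count_interictal_spikes(rec)$count, 0)

  spiky <- wt
  spiky$spike_rate_per_min <- 2
  class(spiky) <- "genotype_preset"
  out <- inject_interictal_spikes(rec, spiky, seed = 32L)
  det <- count_interictal_spikes(out$recording)
  n_true <- length(out$spike_times_s)
  matched <- vapply(out$spike_times_s, function(t0)
    any(abs(det$spike_times_s - t0) < 0.1), logical(1))
  expect_gte(mean(matched), 0.9)
  # no duplicate detections within the refractory window
  if (det$count > 1) expect_true(all(diff(det$spike_times_s) >= 0.2))

  # threshold to infinity: nothing detected
  expect_equal(count_interictal_spikes(out$recording, k = 1e9)$count, 0)
})
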