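test_that("baseline units obey their closed forms on a power step", {
  ## power exactly doubles after t = 0 relative to a [-1, 0) baseline
  tt <- stepTensor(pre = 1, post = 2)
  post <- which(timeAxis(tt) >= 0)

  db <- baselineTransform(tt, c(-1, 0), "decibel")
  expect_equal(unique(as.vector(powerArray(db)[, , post])),
               10 * log10(2), tolerance = 1e-12)
  expect_equal(round(10 * log10(2), 4), 3.0103)

  pp <- baselineTransform(tt, c(-1, 0), "percent_power")
  expect_equal(unique(as.vector(powerArray(pp)[, , post])), 100,
               tolerance = 1e-12)

  pa <- baselineTransform(tt, c(-1, 0), "percent_amplitude")
  expect_equal(unique(as.vector(powerArray(pa)[, , post])),
               100 * (sqrt(2) - 1), tolerance = 1e-12)

  ## stationary signal: every unit reads ~0 across the whole epoch
  flat <- stepTensor(pre = 3, post = 3)
  for (u in c("percent_power", "percent_amplitude", "decibel"))
    expect_equal(max(abs(powerArray(baselineTransform(flat, c(-1, 0), u)))),
                 0, tolerance = 1e-12)
})

test_that("dB and percent power agree cell-wise through the log identity", {
  set.seed(21)
  p <- array(rexp(5 * 3 * 40) + 0.1, c(5, 3, 40))
  tt <- toyTensor(p, seq(-1, 0.95, by = 0.05), c(10, 20, 40))
  db <- powerArray(baselineTransform(tt, c(-1, 0), "decibel"))
  pct <- powerArray(baselineTransform(tt, c(-1, 0), "percent_power"))
  expect_equal(db, 10 * log10(1 + pct / 100), tolerance = 1e-10)
})

test_that("ratio units are scale invariant; z-score is affine invariant", {
  set.seed(22)
  p <- array(rexp(4 * 2 * 30) + 0.1, c(4, 2, 30))
  ta <- toyTensor(p, seq(-1, 0.45, by = 0.05), c(10, 20))
  tb <- toyTensor(3.7 * p, seq(-1, 0.45, by = 0.05), c(10, 20))
  expect_equal(powerArray(baselineTransform(ta, c(-1, 0), "percent_power")),
               powerArray(baselineTransform(tb, c(-1, 0), "percent_power")),
               tolerance = 1e-10)
  expect_equal(powerArray(baselineTransform(ta, c(-1, 0), "zscore_power")),
               powerArray(baselineTransform(tb, c(-1, 0), "zscore_power")),
               tolerance = 1e-10)
})

test_that("degenerate baselines raise named errors", {
  z <- toyTensor(array(0, c(2, 1, 20)), seq(-1, 0.9, by = 0.1), 10)
  expect_error(baselineTransform(z, c(-1, 0), "percent_power"), "all-zero")
  const <- stepTensor(pre = 1, post = 2)
  expect_error(baselineTransform(const, c(-1, 0), "zscore_power"),
               "zero baseline SD")
  expect_error(baselineTransform(stepTensor(), c(5, 6), "decibel"),
               "no timepoints")
  db <- baselineTransform(stepTensor(), c(-1, 0), "decibel")
  expect_error(baselineTransform(db, c(-1, 0), "decibel"), "already in unit")
})

test_that("window collapse averages exactly the selected cells", {
  tt <- stepTensor(pre = 1, post = 2, nTrials = 4)
  post <- collapseWindow(tt, c(0, 1))
  expect_equal(post$value, rep(2, 4))
  half <- collapseWindow(tt, c(-0.5, 0.5))      # half baseline, half step
  expect_equal(half$value, rep(1.5, 4))
  expect_error(collapseWindow(tt, c(5, 6)), "empty intersection")
  ## frequency sub-band
  expect_equal(collapseWindow(tt, c(0, 1), c(10, 10))$value, rep(2, 4))
})

test_that("power-over-time traces match a hand computation", {
  p <- array(0, c(3, 1, 4))
  p[1, 1, ] <- c(1, 2, 3, 4)
  p[2, 1, ] <- c(3, 4, 5, 6)
  p[3, 1, ] <- c(8, 8, 8, 8)
  tt <- toyTensor(p, c(0, 0.1, 0.2, 0.3), 10,
                  conditions = c("A", "A", "B"))
  gr <- conditionGrouping(list(A = "A", B = "B"))
  tr <- powerOverTime(tt, grouping = gr)
  expect_equal(tr$mean[tr$group == "A"], c(2, 3, 4, 5))
  expect_equal(tr$sem[tr$group == "A"],
               rep(sd(c(1, 3)) / sqrt(2), 4))
  ## single-trial group: trace equals the trial, SEM missing
  expect_equal(tr$mean[tr$group == "B"], rep(8, 4))
  expect_true(all(is.na(tr$sem[tr$group == "B"])))

  ## two groups defined on identical trials give identical traces
  p2 <- array(rep(c(1, 2, 3, 4), each = 2), c(2, 1, 4))
  t2 <- toyTensor(p2, c(0, 0.1, 0.2, 0.3), 10, conditions = c("X", "Y"))
  g2 <- conditionGrouping(list(G1 = "X", G2 = "Y"))
  tr2 <- powerOverTime(t2, grouping = g2)
  expect_equal(tr2$mean[tr2$group == "G1"], tr2$mean[tr2$group == "G2"])
})

test_that("condition contrasts cover the one/two/many-group cases", {
  mk <- function(v, cond) data.frame(trial_number = seq_along(v),
                                     block = "001", condition = cond,
                                     is_outlier = FALSE, value = v)
  ## identical values in both groups: t = 0, p = 1
  same <- conditionContrast(mk(rep(5, 8), rep(c("A", "B"), 4)),
                            conditionGrouping(list(A = "A", B = "B")))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  ## clear separation: p << 0.001 and positive effect
  set.seed(31)
  sep <- conditionContrast(
    mk(c(10 + rnorm(10, 0, 0.01), rnorm(10, 0, 0.01)),
       rep(c("A", "B"), each = 10)),
    conditionGrouping(list(A = "A", B = "B")))
  expect_lt(sep$p_value, 1e-6)
  expect_gt(sep$beta, 9.5)

  ## one group: one-sample t against zero, beta = mean
  one <- conditionContrast(mk(rnorm(20) + 2, rep("A", 20)))
  expect_equal(one$test, "one-sample t")
  expect_equal(one$beta, mean(one$groups$mean))

  ## three groups: ANOVA omnibus + per-group tests vs zero
  thr <- conditionContrast(mk(rnorm(30), rep(c("A", "B", "C"), 10)),
                           conditionGrouping(list(A = "A", B = "B", C = "C")))
  expect_equal(thr$test, "anova F")
  expect_equal(nrow(thr$groups), 3L)
  ## oracle: same F as stats::oneway.test on the same data
  expect_error(conditionContrast(mk(rnorm(4), rep("A", 4)),
                                 conditionGrouping(list(A = "A", B = "B"))),
               "without usable trials")
})

test_that("null two-group contrasts keep their type-I rate", {
  set.seed(32)
  reps <- 400
  pvals <- replicate(reps, {
    v <- rnorm(24)
    d <- data.frame(trial_number = 1:24, block = "001",
                    condition = rep(c("A", "B"), 12),
                    is_outlier = FALSE, value = v)
    conditionContrast(d, conditionGrouping(list(A = "A", B = "B")))$p_value
  })
  rate <- mean(pvals < 0.05)
  ci <- qbinom(c(0.005, 0.995), reps, 0.05) / reps
  expect_gte(rate, ci[1])
  expect_lte(rate, ci[2])
  ## p-values approximately uniform
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.001)
})

test_that("electrode statistics table carries BH-corrected p-values", {
  set.seed(33)
  mkT <- function(e, shift) {
    p <- array(rexp(20 * 1 * 30) + 0.5, c(20, 1, 30))
    p[1:10, , 16:30] <- p[1:10, , 16:30] + shift
    tt <- toyTensor(p, seq(-1.5, 1.4, by = 0.1), 10,
                    conditions = rep(c("A", "B"), each = 10))
    tt@electrode <- as.integer(e)
    tt
  }
  tensors <- list(`1` = mkT(1, 4), `2` = mkT(2, 0), `3` = mkT(3, 0.2))
  gr <- conditionGrouping(list(A = "A", B = "B"))
  st <- electrodeStatistics(tensors, gr, timeWindow = c(0, 1.4),
                            baselineWindow = c(-1.5, 0),
                            baselineUnit = "percent_power",
                            electrodeTable = toyElectrodeTable(3))
  expect_equal(st$Electrode, 1:3)
  expect_true(all(st$p_fdr >= st$p))
  expect_equal(st$p_fdr, p.adjust(st$p, "BH"))
  expect_true("AnatomicalLabel" %in% names(st))
  expect_equal(st$n_trials, rep(20L, 3))

  ## single electrode: FDR with m = 1 leaves p unchanged
  st1 <- electrodeStatistics(tensors[1], gr, timeWindow = c(0, 1.4),
                             baselineWindow = c(-1.5, 0))
  expect_equal(st1$p_fdr, st1$p)
})

test_that("BH matches the hand example and a brute-force reference", {
  ## hand-computed: (0.01, 0.02, 0.03, 0.04) -> all 0.04
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
  ## brute-force step-up on random vectors up to length 1000
  set.seed(34)
  for (m in c(1, 7, 100, 1000)) {
    p <- runif(m)
    expect_equal(p.adjust(p, "BH"), bruteForceBH(p), tolerance = 1e-12)
  }
})

test_that("outlier flags are reversible and propagate to statistics", {
  set.seed(35)
  p <- array(rexp(10 * 1 * 20) + 0.5, c(10, 1, 20))
  tt <- toyTensor(p, seq(-1, 0.9, by = 0.1), 10)
  flagged <- setTrialOutliers(tt, c(2, 5))
  expect_equal(sum(trialMeta(flagged)$is_outlier), 2L)
  restored <- setTrialOutliers(flagged, c(2, 5), flag = FALSE)
  expect_identical(trialMeta(restored), trialMeta(tt))
  expect_error(setTrialOutliers(tt, 99), "unknown trial")

  ## flagging one of 10 trials drops n_trials to 9
  st <- electrodeStatistics(list(`1` = setTrialOutliers(tt, 3)),
                            timeWindow = c(0, 0.9),
                            baselineWindow = c(-1, 0))
  expect_equal(st$n_trials, 9L)

  ## flagging an injected artifact trial restores the known effect
  art <- tt
  art@power[4, , ] <- art@power[4, , ] * 50
  stBad <- electrodeStatistics(list(`1` = art), timeWindow = c(0, 0.9),
                               baselineWindow = c(-1, 0))
  stFix <- electrodeStatistics(list(`1` = setTrialOutliers(art, 4)),
                               timeWindow = c(0, 0.9),
                               baselineWindow = c(-1, 0))
  stRef <- electrodeStatistics(list(`1` = setTrialOutliers(tt, 4)),
                               timeWindow = c(0, 0.9),
                               baselineWindow = c(-1, 0))
  expect_equal(stFix$beta, stRef$beta, tolerance = 1e-10)
  expect_false(isTRUE(all.equal(stBad$beta, stRef$beta)))
})

test_that("groupings serialize to YAML and back", {
  gr <- conditionGrouping(list(Aud = c("a1", "a2"), Vis = "v1"))
  path <- withr::local_tempfile(fileext = ".yaml")
  writeConditionGrouping(gr, path)
  expect_equal(readConditionGrouping(path), gr)
  expect_error(conditionGrouping(list(A = "x", B = "x")), "more than one")
})

test_that("aggregation order does not matter for equal-weight means", {
  set.seed(36)
  p <- array(rexp(6 * 2 * 40), c(6, 2, 40))
  tt <- toyTensor(p, seq(-1, 0.95, by = 0.05), c(10, 20),
                  conditions = rep(c("A", "B"), 3))
  gr <- conditionGrouping(list(A = "A", B = "B"))
  win <- c(0, 0.5)
  ## collapse-then-mean equals trace-mean-then-window-mean
  coll <- conditionContrast(collapseWindow(tt, win), gr)$groups
  tr <- powerOverTime(tt, grouping = gr)
  sel <- tr$time >= win[1] & tr$time < win[2]
  for (g in c("A", "B"))
    expect_equal(coll$mean[coll$group == g],
                 mean(tr$mean[tr$group == g & sel]), tolerance = 1e-12)
})
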