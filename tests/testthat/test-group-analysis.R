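test_that("the default model formula is rendered in standard notation", {
  g <- simulateGroupData(nSubjects = 3, electrodesPerSubject = 3,
                         trialsPerElectrode = 8, seed = 41)
  res <- fitLME(g$data)
  expect_identical(res$formula, "Power ~ 1 + (1|Subject/Electrode)")
  ## intercept-only: omnibus is the intercept test, pairwise empty
  expect_equal(res$omnibus$term, "(Intercept)")
  expect_equal(nrow(res$pairwise), 0L)
})

test_that("a degenerate hierarchy collapses to the grand mean", {
  g <- simulateGroupData(nSubjects = 3, electrodesPerSubject = 3,
                         trialsPerElectrode = 10,
                         conditionEffects = c(A = 0), subjectSd = 0,
                         electrodeSd = 0, residualSd = 1, intercept = 7,
                         seed = 42)
  res <- fitLME(g$data)
  expect_equal(res$fixedEffects$estimate[1], mean(g$data$Power),
               tolerance = 1e-6)
  reVar <- res$randomEffects$variance[res$randomEffects$grouping != "Residual"]
  expect_lt(max(reVar), 0.05)
})

test_that("nested simulation parameters are recovered", {
  ## one full-size draw: fixed effect within 2 SE
  g <- simulateGroupData(seed = 43)   # 8 subjects x 10 electrodes x 50 trials
  res <- suppressMessages(fitLME(g$data, fixed = "Condition"))
  i <- grep("ConditionB", res$fixedEffects$term)
  expect_lt(abs(res$fixedEffects$estimate[i] - 20),
            2 * res$fixedEffects$se[i])
  ## variance components recovered in expectation over replicates
  est <- t(sapply(1:6, function(r) {
    gi <- simulateGroupData(seed = 430 + r)
    ri <- suppressMessages(fitLME(gi$data, fixed = "Condition"))
    v <- ri$randomEffects
    c(elec = v$variance[v$grouping == "Electrode:Subject"],
      subj = v$variance[v$grouping == "Subject"],
      resid = v$variance[v$grouping == "Residual"])
  }))
  expect_equal(mean(est[, "elec"]), 9, tolerance = 0.5)
  expect_equal(mean(est[, "subj"]), 25, tolerance = 0.6)
  expect_equal(mean(est[, "resid"]), 100, tolerance = 0.1)
})

test_that("singular designs error instead of degenerating", {
  g <- simulateGroupData(nSubjects = 1, electrodesPerSubject = 1,
                         trialsPerElectrode = 30, seed = 44)
  expect_error(fitLME(g$data), "single level")
  expect_error(fitLME(g$data[0, ]), "empty")
})

test_that("pairwise contrast counts follow C(levels, 2)", {
  for (k in 2:6) {
    eff <- stats::setNames(seq_len(k), paste0("C", seq_len(k)))
    g <- simulateGroupData(nSubjects = 3, electrodesPerSubject = 2,
                           trialsPerElectrode = 2 * k,
                           conditionEffects = eff, subjectSd = 1,
                           electrodeSd = 1, residualSd = 2, seed = 40 + k)
    res <- suppressMessages(fitLME(g$data, fixed = "Condition"))
    expect_equal(nrow(res$pairwise), choose(k, 2))
  }
})

test_that("pairwise adjustment is configurable and conservative", {
  g <- simulateGroupData(nSubjects = 3, electrodesPerSubject = 3,
                         trialsPerElectrode = 12,
                         conditionEffects = c(A = 0, B = 1, C = 2),
                         seed = 47)
  res <- suppressMessages(fitLME(g$data, fixed = "Condition"))
  un <- omnibusAndPairwise(res, adjust = "none")
  bf <- omnibusAndPairwise(res, adjust = "bonferroni")
  expect_true(all(bf$pairwise$p >= un$pairwise$p - 1e-12))
  expect_equal(nrow(un$levels), 3L)
})

test_that("per-electrode univariate table matches the single-subject contrast", {
  g <- simulateGroupData(nSubjects = 2, electrodesPerSubject = 2,
                         trialsPerElectrode = 20, seed = 45)
  uni <- univariateByElectrode(g$data)
  expect_equal(nrow(uni), 4L)
  ## independent route: conditionContrast on one electrode's rows
  sub <- g$data[g$data$Subject == "S01" & g$data$Electrode == 1, ]
  ct <- conditionContrast(
    data.frame(trial_number = sub$Trial, block = "001",
               condition = sub$Condition, is_outlier = FALSE,
               value = sub$Power),
    conditionGrouping(list(A = "A", B = "B")))
  row <- uni[uni$Subject == "S01" & uni$Electrode == "1", ]
  expect_equal(row$statistic, ct$statistic)
  expect_equal(row$p, ct$p_value)
  expect_equal(row$beta, ct$beta)

  ## sortable (stable on electrode for ties) and searchable
  uni$AnatomicalLabel <- c("superior temporal gyrus", "precentral gyrus",
                           "superior temporal gyrus", "precentral gyrus")
  srt <- sortTable(uni, "statistic", decreasing = TRUE)
  expect_equal(order(srt$statistic, decreasing = TRUE), seq_len(nrow(srt)))
  hits <- searchTable(uni, "AnatomicalLabel", "superior temporal")
  expect_equal(nrow(hits), 2L)
})

test_that("post-hoc tests and partial regression behave", {
  set.seed(46)
  n <- 120
  tbl <- data.frame(x = rnorm(n))
  tbl$z <- tbl$x + rnorm(n, 0, 0.5)
  tbl$y <- 2 * tbl$z + rnorm(n, 0, 0.5)
  tbl$mean_A <- tbl$x + 1
  tbl$mean_B <- 1 - tbl$x

  ## y = x exactly: r = 1
  ident <- posthocAnalysis(data.frame(x = 1:10, y = 1:10), "x", "y",
                           test = "pearson")
  expect_equal(ident$estimate, 1)

  ## partial correlation equals the closed-form identity
  part <- posthocAnalysis(tbl, "x", "y", z = "z", test = "pearson")
  rxy <- cor(tbl$x, tbl$y); rxz <- cor(tbl$x, tbl$z); ryz <- cor(tbl$y, tbl$z)
  closed <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  expect_equal(part$estimate, closed, tolerance = 1e-10)

  ## derived variables: "mean_A - mean_B" equals hand computation
  drv <- posthocAnalysis(tbl, "d", "z", test = "spearman",
                         derived = list(d = "mean_A - mean_B"))
  hand <- cor(2 * tbl$x, tbl$z, method = "spearman")
  expect_equal(drv$estimate, hand, tolerance = 1e-10)

  ## paired difference tests run
  tt <- posthocAnalysis(tbl, "x", "y", test = "t_test")
  expect_true(is.finite(tt$statistic))
  wt <- posthocAnalysis(tbl, "x", "y", test = "wilcoxon")
  expect_true(is.finite(wt$p_value))

  ## safety rails of the expression language
  expect_error(posthocAnalysis(tbl, "d", "z",
                               derived = list(d = "nope + 1")),
               "unknown column")
  expect_error(posthocAnalysis(tbl, "d", "z",
                               derived = list(d = "system('ls')")),
               "not allowed")
})

test_that("group traces use across-electrode variance", {
  mk <- function(e, trace) {
    data.frame(Subject = "S01", Electrode = e, Condition = "A",
               Trial = rep(1:2, each = length(trace)),
               Time = rep(seq_along(trace) / 10, 2),
               Power = rep(trace, 2))
  }
  ## identical traces: SEM exactly 0
  same <- groupPowerOverTime(rbind(mk(1, c(1, 2, 3)), mk(2, c(1, 2, 3))))
  expect_equal(same$sem, rep(0, 3))

  ## traces c and -c: mean 0; with the sample-SD convention the
  ## across-electrode SEM is sd({c,-c})/sqrt(2) = |c|
  cc <- c(2, -4, 6)
  anti <- groupPowerOverTime(rbind(mk(1, cc), mk(2, -cc)))
  expect_equal(anti$mean, rep(0, 3))
  expect_equal(anti$sem, abs(cc))

  ## three-electrode fixture vs manual aggregation
  tr <- list(c(1, 1, 1), c(2, 3, 4), c(6, 5, 4))
  long <- do.call(rbind, lapply(1:3, function(i) mk(i, tr[[i]])))
  out <- groupPowerOverTime(long)
  mat <- do.call(rbind, tr)
  expect_equal(out$mean, colMeans(mat))
  expect_equal(out$sem, apply(mat, 2, sd) / sqrt(3))
  expect_equal(out$n_electrodes, rep(3, 3))

  ## single electrode: SEM missing
  one <- groupPowerOverTime(mk(1, cc))
  expect_true(all(is.na(one$sem)))
})
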