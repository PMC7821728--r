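test_that("simulation is bit-reproducible given (spec, seed)", {
  spec <- simulationSpec(nSubjects = 1, electrodesPerSubject = 2,
                         trialsPerBlock = 4, sampleRate = 400, seed = 9)
  a <- simulateDataset(spec)
  b <- simulateDataset(spec)
  expect_identical(voltageData(a$subjects$S01$blocks[["001"]]),
                   voltageData(b$subjects$S01$blocks[["001"]]))
  expect_identical(a$groundTruth, b$groundTruth)
  ## a different seed changes the data
  c <- simulateDataset(simulationSpec(nSubjects = 1, electrodesPerSubject = 2,
                                      trialsPerBlock = 4, sampleRate = 400,
                                      seed = 10))
  expect_false(identical(voltageData(a$subjects$S01$blocks[["001"]]),
                         voltageData(c$subjects$S01$blocks[["001"]])))
})

test_that("background spectral slope matches the requested 1/f exponent", {
  for (expo in c(1, 2)) {
    spec <- simulationSpec(nSubjects = 1, electrodesPerSubject = 1,
                           trialsPerBlock = 8, sampleRate = 500,
                           conditions = c(A = 0), noiseExponent = expo,
                           lineAmplitude = 0, seed = 13)
    sim <- simulateDataset(spec)
    x <- voltageData(sim$subjects$S01$blocks[["001"]])[1, ]
    psd <- ieegpipe:::welchPsd(x, 500)
    sel <- psd$freq > 2 & psd$freq < 200
    fit <- lm(log10(psd$psd[sel]) ~ log10(psd$freq[sel]))
    expect_equal(unname(coef(fit)[2]), -expo, tolerance = 0.15)
  }
})

test_that("a null simulation measures ~0 percent change (direct band oracle)", {
  spec <- simulationSpec(nSubjects = 1, electrodesPerSubject = 4,
                         trialsPerBlock = 24, sampleRate = 500,
                         conditions = c(A = 0, B = 0), seed = 14)
  sim <- simulateDataset(spec)
  rate <- 500
  ## brute-force oracle: FFT band power in effect windows vs baselines,
  ## no wavelets involved
  bandPower <- function(x) {
    n <- length(x)
    f <- (0:(n - 1)) * rate / n
    sel <- (f >= 70 & f <= 150) | (f >= rate - 150 & f <= rate - 70)
    sum(Mod(fft(x)[sel])^2) / n^2
  }
  pct <- NULL
  for (e in 1:4) {
    x <- voltageData(sim$subjects$S01$blocks[["001"]])[e, ]
    ep <- sim$subjects$S01$epochTable
    for (i in seq_len(nrow(ep))) {
      t0 <- ep$Time[i]
      w <- x[(round(t0 * rate) + 1):(round((t0 + 0.5) * rate))]
      b <- x[(round((t0 - 1) * rate) + 1):(round((t0 - 0.5) * rate))]
      pct <- c(pct, 100 * (bandPower(w) / bandPower(b) - 1))
    }
  }
  expect_lt(abs(mean(pct)), 3 * sd(pct) / sqrt(length(pct)))
})

test_that("the injected effect scales band power by the stated percent", {
  ## one electrode, large effect, measured with the same direct FFT oracle
  spec <- simulationSpec(nSubjects = 1, electrodesPerSubject = 2,
                         trialsPerBlock = 36, sampleRate = 500,
                         conditions = c(A = 100), seed = 15)
  sim <- simulateDataset(spec)
  rate <- 500
  bandPower <- function(x) {
    n <- length(x)
    f <- (0:(n - 1)) * rate / n
    sel <- (f >= 70 & f <= 150) | (f >= rate - 150 & f <= rate - 70)
    sum(Mod(fft(x)[sel])^2) / n^2
  }
  pct <- NULL
  for (e in 1:2) {
    x <- voltageData(sim$subjects$S01$blocks[["001"]])[e, ]
    ep <- sim$subjects$S01$epochTable
    for (i in seq_len(nrow(ep))) {
      t0 <- ep$Time[i]
      w <- x[(round(t0 * rate) + 1):(round((t0 + 0.5) * rate))]
      b <- x[(round((t0 - 1) * rate) + 1):(round((t0 - 0.5) * rate))]
      pct <- c(pct, 100 * (bandPower(w) / bandPower(b) - 1))
    }
  }
  expect_lt(abs(mean(pct) - 100), 3 * sd(pct) / sqrt(length(pct)) + 5)
})

test_that("ground-truth summary reflects the random-effect structure", {
  ## no random effects: every electrode carries the nominal effect
  flat <- simulateDataset(simulationSpec(
    nSubjects = 2, electrodesPerSubject = 3, trialsPerBlock = 2,
    sampleRate = 400, seed = 16))
  gs <- groundTruthSummary(flat)
  a <- gs$perElectrode[gs$perElectrode$Condition == "A", ]
  expect_equal(a$true_pct, rep(25, 6))
  expect_equal(unname(gs$varianceComponents), c(0, 0))

  ## subject offsets only: effects identical within subject, not across
  subjOnly <- simulateDataset(simulationSpec(
    nSubjects = 2, electrodesPerSubject = 3, trialsPerBlock = 2,
    sampleRate = 400, subjectSd = 0.4, seed = 17))
  gA <- groundTruthSummary(subjOnly)$perElectrode
  gA <- gA[gA$Condition == "A", ]
  for (s in unique(gA$Subject))
    expect_equal(diff(range(gA$true_pct[gA$Subject == s])), 0)
  expect_gt(diff(range(tapply(gA$true_pct, gA$Subject, mean))), 0)

  ## law of large numbers: drawn offsets reproduce the requested SD
  big <- simulateDataset(simulationSpec(
    nSubjects = 1, electrodesPerSubject = 400, trialsPerBlock = 1,
    sampleRate = 200, band = c(20, 60), electrodeSd = 0.3, seed = 18))
  off <- big$groundTruth$electrodeOffsets$S01
  expect_equal(sd(off), 0.3, tolerance = 0.15)
})

test_that("notch filtering removes the injected line component", {
  sim <- sharedSim()
  blk <- sim$subjects$S01$blocks[["001"]]
  rate <- sampleRate(blk)
  psdAt <- function(x, f0) {
    psd <- ieegpipe:::welchPsd(x, rate)
    psd$psd[which.min(abs(psd$freq - f0))]
  }
  before <- psdAt(voltageData(blk)[1, ], 60)
  after <- psdAt(voltageData(notchFilter(blk))[1, ], 60)
  expect_gt(before / after, 100)   # >= 20 dB suppression at the line
})

test_that("group-level generator matches its declared moments", {
  g <- simulateGroupData(nSubjects = 40, electrodesPerSubject = 2,
                         trialsPerElectrode = 20,
                         conditionEffects = c(A = 0, B = 12),
                         subjectSd = 2, electrodeSd = 1, residualSd = 3,
                         seed = 19)
  d <- g$data
  expect_equal(mean(d$Power[d$Condition == "B"]) -
                 mean(d$Power[d$Condition == "A"]), 12, tolerance = 0.15)
  within <- tapply(d$Power, interaction(d$Subject, d$Electrode, d$Condition),
                   sd)
  expect_equal(mean(within), 3, tolerance = 0.1)
})

test_that("simulated datasets round-trip through the subject store", {
  root <- withr::local_tempdir()
  sim <- simulateDataset(simulationSpec(
    nSubjects = 1, electrodesPerSubject = 2, trialsPerBlock = 3,
    sampleRate = 400, seed = 20))
  stores <- writeSimulatedDataset(sim, root, "proj")
  store <- stores$S01
  back <- readVoltage(store, "001")
  expect_identical(voltageData(back),
                   voltageData(sim$subjects$S01$blocks[["001"]]))
  et <- readElectrodeTable(storePath(store, "meta", "electrodes.csv"))
  expect_equal(nrow(et), 2L)
  ep <- readEpochTable(storePath(store, "meta", "epochs.csv"))
  expect_equal(nrow(ep), 3L)
  trig <- readTrigger(store, "001")
  expect_identical(trig$data, sim$subjects$S01$triggers[["001"]])
})
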