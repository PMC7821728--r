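#' @include AllClasses.R
NULL

#' Specification for a synthetic iEEG dataset
#'
#' Defines the generative conditions: multi-subject, multi-electrode,
#' multi-block recordings of 1/f-shaped Gaussian background plus
#' sinusoidal line noise, with condition-locked band-limited power
#' changes and a pulse trigger channel. The effect is injected by scaling
#' the in-band component of the background inside each trial's effect
#' window by `sqrt(1 + pct/100)`, so the true per-frequency percent power
#' change inside the band is exactly `pct`, uniformly across the band.
#' Random effects are multiplicative on effect size (log-normal):
#' `pct_e = pct_condition * exp(eta_subject + eta_electrode)` with the
#' etas drawn at the given SDs (log scale), keeping power changes
#' positive.
#'
#' @param nSubjects,electrodesPerSubject,blocks,trialsPerBlock design size.
#' @param sampleRate acquisition rate in Hz.
#' @param conditions named numeric vector: per-condition true percent
#'   power change in the band/effect window.
#' @param band `c(low, high)` Hz of the modulated band.
#' @param effectWindow `c(start, end)` seconds post-onset.
#' @param subjectSd,electrodeSd SDs (log scale) of the multiplicative
#'   random effect offsets.
#' @param noiseExponent 1/f exponent of the background PSD.
#' @param noiseSd background SD in microvolts.
#' @param lineFreq,lineAmplitude line-noise frequency (Hz) and amplitude.
#' @param triggerAmplitude,triggerWidth trigger pulse height and width (s).
#' @param itiSeconds onset-to-onset interval; `preSeconds`/`tailSeconds`
#'   pad the block ends.
#' @param seed RNG seed; given (spec, seed) the output is bit-reproducible.
#' @return A validated list of class `SimulationSpec`.
#' @export
simulationSpec <- function(nSubjects = 1, electrodesPerSubject = 8,
                           blocks = 1, trialsPerBlock = 48,
                           sampleRate = 1000,
                           conditions = c(A = 25, B = 0),
                           band = c(70, 150), effectWindow = c(0, 0.5),
                           subjectSd = 0, electrodeSd = 0,
                           noiseExponent = 1, noiseSd = 10,
                           lineFreq = 60, lineAmplitude = 5,
                           triggerAmplitude = 5, triggerWidth = 0.05,
                           itiSeconds = 2.5, preSeconds = 2.5,
                           tailSeconds = 1.5, seed = 1) {
  spec <- list(nSubjects = nSubjects,
               electrodesPerSubject = electrodesPerSubject,
               blocks = blocks, trialsPerBlock = trialsPerBlock,
               sampleRate = sampleRate, conditions = conditions,
               band = band, effectWindow = effectWindow,
               subjectSd = subjectSd, electrodeSd = electrodeSd,
               noiseExponent = noiseExponent, noiseSd = noiseSd,
               lineFreq = lineFreq, lineAmplitude = lineAmplitude,
               triggerAmplitude = triggerAmplitude,
               triggerWidth = triggerWidth, itiSeconds = itiSeconds,
               preSeconds = preSeconds, tailSeconds = tailSeconds,
               seed = seed)
  if (spec$trialsPerBlock < 1) stop("trials must be >= 1")
  if (spec$subjectSd < 0 || spec$electrodeSd < 0) stop("SDs must be >= 0")
  if (spec$band[2] >= spec$sampleRate / 2)
    stop(sprintf("band (%g-%g Hz) must lie below Nyquist (%g Hz)",
                 spec$band[1], spec$band[2], spec$sampleRate / 2))
  if (is.null(names(spec$conditions)) || any(!nzchar(names(spec$conditions))))
    stop("conditions must be a named numeric vector of percent changes")
  if (any(spec$conditions <= -100)) stop("percent changes must exceed -100")
  structure(spec, class = "SimulationSpec")
}

## shaped spectrum amplitude for an n-sample real signal: |f|^(-exponent/2)
shapedAmplitude <- function(n, rate, exponent) {
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * rate / n
  a <- numeric(n)
  a[f > 0] <- f[f > 0]^(-exponent / 2)
  a
}

bandMask <- function(n, rate, band) {
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * rate / n
  as.numeric(f >= band[1] & f <= band[2])
}

#' Generate a synthetic multi-subject iEEG dataset
#'
#' Each channel is 1/f-shaped Gaussian noise plus line noise plus the
#' condition-locked band-limited amplitude modulation described in
#' [simulationSpec()]. The trigger channel carries one rectangular pulse
#' at every trial onset (onsets lie exactly on the sample grid). The
#' ground-truth record stores every drawn random offset, the true percent
#' change per electrode and condition, and all onset times.
#'
#' @param spec a `SimulationSpec`.
#' @return An object of class `SimulatedDataset`: list with `spec`,
#'   `subjects` (per subject: `blocks` of [VoltageBlock-class], `triggers`,
#'   `electrodeTable`, `epochTable`) and `groundTruth`.
#' @export
simulateDataset <- function(spec) {
  stopifnot(inherits(spec, "SimulationSpec"))
  set.seed(spec$seed)
  rate <- spec$sampleRate
  nTr <- spec$trialsPerBlock
  blockDur <- spec$preSeconds + nTr * spec$itiSeconds + spec$tailSeconds
  n <- round(blockDur * rate)
  amp <- shapedAmplitude(n, rate, spec$noiseExponent)
  bmask <- bandMask(n, rate, spec$band)
  condNames <- names(spec$conditions)
  subjects <- list()
  effects <- list()
  onsetRows <- list()
  subjOff <- stats::rnorm(spec$nSubjects, 0, spec$subjectSd)
  names(subjOff) <- sprintf("S%02d", seq_len(spec$nSubjects))
  elecOff <- list()

  for (s in seq_len(spec$nSubjects)) {
    sid <- names(subjOff)[s]
    eOff <- stats::rnorm(spec$electrodesPerSubject, 0, spec$electrodeSd)
    elecOff[[sid]] <- eOff
    ## per-electrode/condition true percent change
    truePct <- outer(exp(subjOff[s] + eOff), spec$conditions)
    effects[[sid]] <- data.frame(
      Subject = sid,
      Electrode = rep(seq_len(spec$electrodesPerSubject),
                      times = length(condNames)),
      Condition = rep(condNames, each = spec$electrodesPerSubject),
      true_pct = as.vector(truePct),
      stringsAsFactors = FALSE)

    blocks <- list(); triggers <- list(); epochRows <- list()
    for (b in seq_len(spec$blocks)) {
      bid <- sprintf("%03d", b)
      onsets <- round((spec$preSeconds +
                         (seq_len(nTr) - 1L) * spec$itiSeconds) * rate) / rate
      conds <- rep_len(condNames, nTr)
      ## gain timecourse per condition-effect is electrode specific; build
      ## per-trial sample windows once
      winIdx <- lapply(onsets, function(t0) {
        i0 <- round((t0 + spec$effectWindow[1]) * rate) + 1L
        i1 <- round((t0 + spec$effectWindow[2]) * rate)
        seq.int(max(1L, i0), min(n, i1))
      })
      dat <- matrix(0, spec$electrodesPerSubject, n)
      for (e in seq_len(spec$electrodesPerSubject)) {
        W <- stats::fft(stats::rnorm(n))
        pinkRaw <- Re(stats::fft(W * amp, inverse = TRUE)) / n
        sc <- spec$noiseSd / stats::sd(pinkRaw)
        pink <- pinkRaw * sc
        xb <- Re(stats::fft(W * amp * bmask, inverse = TRUE)) / n * sc
        g <- numeric(n)
        for (i in seq_len(nTr)) {
          pct <- spec$conditions[conds[i]] * exp(subjOff[s] + eOff[e])
          if (spec$conditions[conds[i]] == 0) pct <- 0
          gi <- sqrt(1 + pct / 100) - 1
          if (gi != 0) g[winIdx[[i]]] <- gi
        }
        phase <- stats::runif(1, 0, 2 * pi)
        tsec <- (seq_len(n) - 1L) / rate
        dat[e, ] <- pink + g * xb +
          spec$lineAmplitude * sin(2 * pi * spec$lineFreq * tsec + phase)
      }
      trig <- numeric(n)
      wSamp <- max(1L, round(spec$triggerWidth * rate))
      for (t0 in onsets) {
        i0 <- round(t0 * rate) + 1L
        trig[i0:min(n, i0 + wSamp - 1L)] <- spec$triggerAmplitude
      }
      blocks[[bid]] <- VoltageBlock(bid, dat, rate,
                                    seq_len(spec$electrodesPerSubject))
      triggers[[bid]] <- trig
      epochRows[[bid]] <- data.frame(
        Block = bid, Trial = seq_len(nTr), Condition = conds,
        Time = onsets, stringsAsFactors = FALSE)
      onsetRows[[paste(sid, bid)]] <- data.frame(
        Subject = sid, Block = bid, Trial = seq_len(nTr), Time = onsets,
        stringsAsFactors = FALSE)
    }
    nE <- spec$electrodesPerSubject
    electrodeTable <- data.frame(
      Electrode = seq_len(nE),
      Label = paste0("LA", seq_len(nE)),
      x = round(stats::runif(nE, -60, -30), 1),
      y = round(stats::runif(nE, -40, 10), 1),
      z = round(stats::runif(nE, -10, 20), 1),
      AnatomicalLabel = rep_len(c("superior temporal gyrus",
                                  "middle temporal gyrus"), nE),
      Group = "LA", Excluded = FALSE, stringsAsFactors = FALSE)
    subjects[[sid]] <- list(
      blocks = blocks, triggers = triggers,
      electrodeTable = electrodeTable,
      epochTable = validateEpochTable(do.call(rbind, epochRows)))
  }
  groundTruth <- list(
    subjectOffsets = subjOff,
    electrodeOffsets = elecOff,
    effects = do.call(rbind, c(effects, list(make.row.names = FALSE))),
    onsets = do.call(rbind, c(onsetRows, list(make.row.names = FALSE))),
    conditions = spec$conditions,
    band = spec$band, effectWindow = spec$effectWindow)
  structure(list(spec = spec, subjects = subjects,
                 groundTruth = groundTruth),
            class = "SimulatedDataset")
}

#' @export
print.SimulatedDataset <- function(x, ...) {
  cat(sprintf("SimulatedDataset: %d subject(s) x %d electrode(s) x %d block(s) x %d trial(s) @ %g Hz\n",
              x$spec$nSubjects, x$spec$electrodesPerSubject, x$spec$blocks,
              x$spec$trialsPerBlock, x$spec$sampleRate))
  cat(sprintf("  conditions: %s (%% power change in %g-%g Hz, %g-%g s)\n",
              paste(names(x$spec$conditions), x$spec$conditions,
                    sep = "=", collapse = ", "),
              x$spec$band[1], x$spec$band[2],
              x$spec$effectWindow[1], x$spec$effectWindow[2]))
  invisible(x)
}

#' Closed-form expectations for a simulated dataset
#'
#' Returns the expected per-electrode, per-condition percent power change
#' (the values the electrode statistics should recover) and the
#' log-scale variance components of the multiplicative random effects
#' (what a hierarchical model of log effect sizes should recover).
#'
#' @param sim a `SimulatedDataset` (or its `groundTruth`).
#' @return list with `perElectrode` (data.frame) and
#'   `varianceComponents`.
#' @export
groundTruthSummary <- function(sim) {
  gt <- if (inherits(sim, "SimulatedDataset")) sim$groundTruth else sim
  spec <- if (inherits(sim, "SimulatedDataset")) sim$spec else NULL
  list(perElectrode = gt$effects,
       varianceComponents = c(
         subject = if (is.null(spec)) NA_real_ else spec$subjectSd^2,
         electrode = if (is.null(spec)) NA_real_ else spec$electrodeSd^2))
}

#' Write a simulated dataset into subject stores
#'
#' Persists raw voltage blocks and trigger channels as HDF5, electrode
#' and epoch tables as CSV under `meta/`, and the ground truth as JSON —
#' the exact dialects the storage readers consume.
#'
#' @param sim a `SimulatedDataset`.
#' @param root project root directory.
#' @param project project name.
#' @return Named list of [SubjectStore-class] handles.
#' @export
writeSimulatedDataset <- function(sim, root, project = "sim") {
  stopifnot(inherits(sim, "SimulatedDataset"))
  stores <- list()
  for (sid in names(sim$subjects)) {
    sub <- sim$subjects[[sid]]
    store <- initSubject(root, project, sid)
    for (bid in names(sub$blocks)) {
      bl <- sub$blocks[[bid]]
      importVoltage(store, bid, voltageData(bl), sampleRate(bl),
                    channelNumbers(bl))
      writeTrigger(store, bid, sub$triggers[[bid]], sampleRate(bl))
    }
    writeElectrodeTable(sub$electrodeTable,
                        storePath(store, "meta", "electrodes.csv"))
    writeEpochTable(sub$epochTable, storePath(store, "meta", "epochs.csv"))
    gt <- sim$groundTruth
    jsonlite::write_json(
      list(subjectOffsets = as.list(gt$subjectOffsets),
           effects = gt$effects[gt$effects$Subject == sid, ],
           conditions = as.list(gt$conditions)),
      storePath(store, "meta", "ground_truth.json"), auto_unbox = TRUE,
      digits = NA)
    stores[[sid]] <- store
  }
  stores
}

#' Simulate a nested group dataset of per-trial power values
#'
#' Draws collapsed per-trial power values directly from the nested
#' generative model the group LME assumes:
#' `Power = intercept + effect[condition] + b_subject + b_electrode(subject)
#' + residual`, with independent Gaussian components. Used to validate
#' fixed-effect recovery and interval coverage of [fitLME()].
#'
#' @param nSubjects,electrodesPerSubject,trialsPerElectrode design size;
#'   trials are split evenly across conditions.
#' @param conditionEffects named numeric vector of additive condition
#'   effects (first level is the reference).
#' @param subjectSd,electrodeSd,residualSd Gaussian SDs of the random
#'   components.
#' @param intercept grand intercept.
#' @param seed optional RNG seed.
#' @return list with `data` (Subject, Electrode, Trial, Condition, Power)
#'   and `truth` (the generating values).
#' @export
simulateGroupData <- function(nSubjects = 8, electrodesPerSubject = 10,
                              trialsPerElectrode = 50,
                              conditionEffects = c(A = 0, B = 20),
                              subjectSd = 5, electrodeSd = 3,
                              residualSd = 10, intercept = 0,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  conds <- names(conditionEffects)
  rows <- list()
  for (s in seq_len(nSubjects)) {
    bs <- stats::rnorm(1, 0, subjectSd)
    for (e in seq_len(electrodesPerSubject)) {
      be <- stats::rnorm(1, 0, electrodeSd)
      cond <- rep_len(conds, trialsPerElectrode)
      pow <- intercept + conditionEffects[cond] + bs + be +
        stats::rnorm(trialsPerElectrode, 0, residualSd)
      rows[[length(rows) + 1L]] <- data.frame(
        Subject = sprintf("S%02d", s), Electrode = e,
        Trial = seq_len(trialsPerElectrode), Condition = cond,
        Power = unname(pow), stringsAsFactors = FALSE)
    }
  }
  list(data = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       truth = list(conditionEffects = conditionEffects,
                    subjectSd = subjectSd, electrodeSd = electrodeSd,
                    residualSd = residualSd, intercept = intercept))
}
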