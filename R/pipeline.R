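#' @include AllClasses.R
NULL

knownConfigKeys <- list(
  "." = c("project", "simulate", "preprocess", "reference", "epoch",
          "analysis", "select", "group", "seed", "log_level"),
  project = c("root", "name", "subjects"),
  simulate = c("nSubjects", "electrodesPerSubject", "blocks",
               "trialsPerBlock", "sampleRate", "conditions", "band",
               "effectWindow", "subjectSd", "electrodeSd", "noiseExponent",
               "noiseSd", "lineFreq", "lineAmplitude", "triggerAmplitude",
               "triggerWidth", "itiSeconds", "preSeconds", "tailSeconds",
               "seed"),
  preprocess = c("notch", "wavelet"),
  notch = c("freqs", "half_bandwidths"),
  wavelet = c("frequencies", "cycles", "downsample_to"),
  reference = c("scheme", "electrodes", "pairs_csv"),
  epoch = c("window", "locking_event", "detect"),
  detect = c("threshold", "min_separation"),
  analysis = c("baseline_window", "unit", "baseline_mode", "time_window",
               "frequency_range", "groups"),
  select = c("functional", "anatomical"),
  group = c("fixed", "random", "adjust")
)

checkKeys <- function(x, section) {
  allowed <- knownConfigKeys[[section]]
  unknown <- setdiff(names(x), allowed)
  if (length(unknown))
    stop(sprintf("unknown config key(s) in '%s': %s (allowed: %s)",
                 section, paste(unknown, collapse = ", "),
                 paste(allowed, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}

#' Read and validate a pipeline run configuration
#'
#' A single YAML file with per-stage sections; unknown keys are rejected
#' outright so typos fail fast rather than silently falling back to
#' defaults.
#'
#' @param path YAML file path (or an already-parsed list).
#' @return The validated config list, class `RunConfig`.
#' @export
readRunConfig <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  checkKeys(cfg, ".")
  for (sec in intersect(names(cfg), c("project", "simulate", "preprocess",
                                      "reference", "epoch", "analysis",
                                      "select", "group"))) {
    checkKeys(cfg[[sec]], sec)
  }
  if (!is.null(cfg$preprocess$notch)) checkKeys(cfg$preprocess$notch, "notch")
  if (!is.null(cfg$preprocess$wavelet))
    checkKeys(cfg$preprocess$wavelet, "wavelet")
  if (!is.null(cfg$epoch$detect)) checkKeys(cfg$epoch$detect, "detect")
  if (is.null(cfg$project$root) || is.null(cfg$project$name))
    stop("config must define project.root and project.name")
  structure(cfg, class = c("RunConfig", "list"))
}

projectDir <- function(cfg) file.path(cfg$project$root, cfg$project$name)

cfgSubjects <- function(cfg, subject = NULL) {
  subs <- subject %||% cfg$project$subjects
  if (is.null(subs)) {
    subs <- list.dirs(projectDir(cfg), recursive = FALSE, full.names = FALSE)
  }
  if (!length(subs)) stop("no subjects configured or present on disk")
  as.character(subs)
}

writeProvenance <- function(dir, command, cfg, extra = list()) {
  rec <- c(list(command = command,
                package = "ieegpipe",
                version = as.character(utils::packageVersion("ieegpipe")),
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                config = unclass(cfg)),
           extra)
  jsonlite::write_json(rec, file.path(dir, paste0("provenance-", command,
                                                  ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(NULL)
}

logMsg <- function(cfg, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible(NULL))
  message(format(Sys.time(), "[%H:%M:%S] "), ...)
}

#' Run one pipeline stage
#'
#' Commands wire the modules into the processing flow: `simulate` |
#' `preprocess` | `reference` | `epoch` | `analyze` | `select` | `group`.
#' Each stage reads the run config, executes the corresponding module
#' pipeline on each configured subject, writes its outputs under the
#' project tree and drops a JSON provenance record (config snapshot,
#' package version, timestamp) next to them. A missing upstream stage
#' produces an error naming the command to run first.
#'
#' @param command stage name.
#' @param config path to a YAML run config, or a parsed `RunConfig`.
#' @param subject optional subject id(s) overriding the config.
#' @param seed optional seed overriding the config.
#' @return Invisibly, a stage-specific result summary.
#' @export
runStage <- function(command, config, subject = NULL, seed = NULL) {
  cfg <- readRunConfig(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  switch(command,
         simulate = runSimulate(cfg),
         preprocess = runPreprocess(cfg, subject),
         reference = runReference(cfg, subject),
         epoch = runEpoch(cfg, subject),
         analyze = runAnalyze(cfg, subject),
         select = runSelect(cfg, subject),
         group = runGroup(cfg),
         stop("unknown command '", command, "'; available: simulate, ",
              "preprocess, reference, epoch, analyze, select, group"))
}

#' @rdname runStage
#' @param cfg a `RunConfig`.
#' @export
runSimulate <- function(cfg) {
  sc <- cfg$simulate %||% list()
  if (!is.null(sc$conditions)) sc$conditions <- unlist(sc$conditions)
  for (k in c("band", "effectWindow")) if (!is.null(sc[[k]]))
    sc[[k]] <- as.numeric(unlist(sc[[k]]))
  if (!is.null(cfg$seed)) sc$seed <- cfg$seed
  spec <- do.call(simulationSpec, sc)
  sim <- simulateDataset(spec)
  stores <- writeSimulatedDataset(sim, cfg$project$root, cfg$project$name)
  writeProvenance(projectDir(cfg), "simulate", cfg,
                  list(subjects = names(stores)))
  logMsg(cfg, "simulated ", length(stores), " subject(s) under ",
         projectDir(cfg))
  invisible(stores)
}

openStore <- function(cfg, sid) initSubject(cfg$project$root,
                                            cfg$project$name, sid)

#' @rdname runStage
#' @export
runPreprocess <- function(cfg, subject = NULL) {
  for (sid in cfgSubjects(cfg, subject)) {
    store <- openStore(cfg, sid)
    blocks <- listBlocks(store)
    if (!length(blocks))
      stop("no raw voltage blocks for subject ", sid,
           ": run 'simulate' (or import raw data) first")
    pp <- cfg$preprocess %||% list()
    nf <- pp$notch$freqs %||% c(60, 120, 180)
    nh <- pp$notch$half_bandwidths %||% c(1, 2, 2)
    for (bid in blocks) {
      block <- readVoltage(store, bid)
      clean <- notchFilter(block, as.numeric(unlist(nf)),
                           as.numeric(unlist(nh)))
      wfreq <- pp$wavelet$frequencies
      bank <- designWaveletBank(
        frequencies = if (is.null(wfreq)) waveletDefaultFrequencies() else
          as.numeric(unlist(wfreq)),
        cycleRange = as.numeric(unlist(pp$wavelet$cycles %||% c(3, 16))),
        designRate = sampleRate(block))
      spectra <- waveletTransform(clean, bank)
      target <- pp$wavelet$downsample_to %||% 100
      for (sa in spectra)
        writeSpectral(store, downsampleSpectral(sa, target), bid)
      qc <- qualityReport(block, as.numeric(unlist(nf)),
                          as.numeric(unlist(nh)))
      qcTbl <- do.call(rbind, lapply(qc$electrodes, function(e)
        data.frame(Electrode = e$electrode, t(e$voltage))))
      utils::write.csv(qcTbl, storePath(store, "meta",
                                        paste0("qc-", bid, ".csv")),
                       row.names = FALSE)
    }
    writeProvenance(storePath(store, "meta"), "preprocess", cfg)
    logMsg(cfg, sid, ": preprocessed ", length(blocks), " block(s)")
  }
  invisible(NULL)
}

buildScheme <- function(cfg, store) {
  rf <- cfg$reference %||% list(scheme = "common_average")
  etabPath <- storePath(store, "meta", "electrodes.csv")
  if (!file.exists(etabPath))
    stop("no electrode table (meta/electrodes.csv): run 'simulate' or ",
         "provide one first")
  etab <- readElectrodeTable(etabPath)
  switch(rf$scheme %||% "common_average",
         none = new("ReferenceScheme", kind = "none"),
         common_average = buildCAR(etab),
         white_matter = buildWhiteMatter(as.integer(unlist(rf$electrodes))),
         bipolar = buildBipolar(etab, rf$pairs_csv),
         stop("unknown reference scheme: ", rf$scheme))
}

#' @rdname runStage
#' @export
runReference <- function(cfg, subject = NULL) {
  for (sid in cfgSubjects(cfg, subject)) {
    store <- openStore(cfg, sid)
    scheme <- buildScheme(cfg, store)
    blocks <- listBlocks(store)
    for (bid in blocks) {
      els <- listSpectralElectrodes(store, bid)
      if (!length(els))
        stop("no spectral data for subject ", sid, " block ", bid,
             ": run 'preprocess' first")
      spectra <- lapply(els, function(e) readSpectral(store, e, bid))
      names(spectra) <- as.character(els)
      refd <- applyReference(spectra, scheme)
      for (sa in refd) writeSpectral(store, sa, bid, kind = "referenced")
    }
    writeProvenance(storePath(store, "meta"), "reference", cfg,
                    list(scheme = scheme@kind))
    logMsg(cfg, sid, ": referenced (", scheme@kind, ")")
  }
  invisible(NULL)
}

#' @rdname runStage
#' @export
runEpoch <- function(cfg, subject = NULL) {
  det <- cfg$epoch$detect %||% list()
  for (sid in cfgSubjects(cfg, subject)) {
    store <- openStore(cfg, sid)
    blocks <- listBlocks(store)
    if (!length(blocks))
      stop("no raw data for subject ", sid, ": run 'simulate' first")
    rows <- list()
    for (bid in blocks) {
      trig <- tryCatch(readTrigger(store, bid), error = function(e) NULL)
      if (is.null(trig)) next
      onsets <- detectEvents(trig$data, trig$sampleRate,
                             threshold = det$threshold %||%
                               (max(trig$data) / 2),
                             minSeparation = det$min_separation %||% 0.5)
      rows[[bid]] <- proposeEpochs(onsets, bid)
    }
    if (!length(rows))
      stop("no trigger channels for subject ", sid,
           ": run 'simulate' (or supply an epoch CSV) first")
    proposed <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    writeEpochTable(proposed, storePath(store, "meta",
                                        "epochs_detected.csv"))
    if (!file.exists(storePath(store, "meta", "epochs.csv")))
      writeEpochTable(proposed, storePath(store, "meta", "epochs.csv"))
    writeProvenance(storePath(store, "meta"), "epoch", cfg)
    logMsg(cfg, sid, ": detected ", nrow(proposed), " onset(s)")
  }
  invisible(NULL)
}

analysisGrouping <- function(cfg, epochs) {
  gr <- cfg$analysis$groups
  if (is.null(gr)) {
    conds <- unique(epochs$Condition)
    gr <- stats::setNames(as.list(conds), conds)
  }
  conditionGrouping(lapply(gr, function(v) unlist(v, use.names = FALSE)))
}

loadTensors <- function(cfg, store, epochs) {
  blocks <- unique(epochs$Block)
  kind <- "referenced"
  els <- listSpectralElectrodes(store, blocks[1], kind = kind)
  if (!length(els))
    stop("no referenced spectral data for subject ", store@subject,
         ": run 'reference' first")
  win <- as.numeric(unlist(cfg$epoch$window %||% c(-1, 1)))
  lockEvent <- cfg$epoch$locking_event %||% "Trial"
  lapply(stats::setNames(els, as.character(els)), function(e) {
    spectra <- lapply(stats::setNames(blocks, blocks), function(b)
      readSpectral(store, e, b, kind = kind))
    buildTrialTensor(spectra, epochs, lockEvent, win)
  })
}

#' @rdname runStage
#' @export
runAnalyze <- function(cfg, subject = NULL) {
  an <- cfg$analysis %||% list()
  out <- list()
  for (sid in cfgSubjects(cfg, subject)) {
    store <- openStore(cfg, sid)
    epochPath <- storePath(store, "meta", "epochs.csv")
    if (!file.exists(epochPath))
      stop("no epoch table for subject ", sid, ": run 'epoch' first")
    epochs <- readEpochTable(epochPath)
    tensors <- loadTensors(cfg, store, epochs)
    grouping <- analysisGrouping(cfg, epochs)
    bw <- as.numeric(unlist(an$baseline_window %||% c(-1, -0.2)))
    tw <- as.numeric(unlist(an$time_window %||% c(0.1, 0.4)))
    fr <- if (!is.null(an$frequency_range))
      as.numeric(unlist(an$frequency_range))
    etab <- readElectrodeTable(storePath(store, "meta", "electrodes.csv"))
    stats <- electrodeStatistics(
      tensors, grouping, timeWindow = tw, freqRange = fr,
      baselineWindow = bw, baselineUnit = an$unit %||% "percent_power",
      baselineMode = an$baseline_mode %||% "per_trial",
      electrodeTable = etab)
    utils::write.csv(stats, storePath(store, "meta", "electrode_stats.csv"),
                     row.names = FALSE)
    baselined <- lapply(tensors, function(tt)
      baselineTransform(tt, bw, an$unit %||% "percent_power",
                        mode = an$baseline_mode %||% "per_trial"))
    exportLongTable(baselined, sid, freqRange = fr,
                    file = storePath(store, "meta", "long_table.csv"))
    writeProvenance(storePath(store, "meta"), "analyze", cfg)
    logMsg(cfg, sid, ": analyzed ", length(tensors), " electrode(s)")
    out[[sid]] <- stats
  }
  invisible(out)
}

#' @rdname runStage
#' @export
runSelect <- function(cfg, subject = NULL) {
  sel <- cfg$select %||% list()
  crit <- selectionCriteria(
    functional = lapply(sel$functional %||% list(), function(f)
      list(stat = f$stat, op = f$op, threshold = as.numeric(f$threshold))),
    anatomical = lapply(sel$anatomical %||% list(), function(a)
      list(column = a$column, labels = unlist(a$labels))))
  out <- list()
  for (sid in cfgSubjects(cfg, subject)) {
    store <- openStore(cfg, sid)
    statsPath <- storePath(store, "meta", "electrode_stats.csv")
    if (!file.exists(statsPath))
      stop("no electrode statistics for subject ", sid,
           ": run 'analyze' first")
    stats <- utils::read.csv(statsPath)
    res <- applySelection(stats, crit)
    utils::write.csv(
      data.frame(Electrode = stats$Electrode, selected = unname(res$mask)),
      storePath(store, "meta", "selection.csv"), row.names = FALSE)
    writeProvenance(storePath(store, "meta"), "select", cfg,
                    list(n_selected = sum(res$mask)))
    logMsg(cfg, sid, ": selected ", sum(res$mask), " electrode(s)")
    out[[sid]] <- res
  }
  invisible(out)
}

#' @rdname runStage
#' @export
runGroup <- function(cfg) {
  subs <- cfgSubjects(cfg)
  longs <- list()
  for (sid in subs) {
    store <- openStore(cfg, sid)
    p <- storePath(store, "meta", "long_table.csv")
    if (!file.exists(p))
      stop("no exported long table for subject ", sid,
           ": run 'analyze' first")
    long <- utils::read.csv(p)
    selPath <- storePath(store, "meta", "selection.csv")
    if (file.exists(selPath)) {
      sel <- utils::read.csv(selPath)
      long <- long[long$Electrode %in% sel$Electrode[sel$selected], ,
                   drop = FALSE]
    }
    longs[[sid]] <- long
  }
  long <- do.call(rbind, c(longs, list(make.row.names = FALSE)))
  if (!nrow(long)) stop("group dataset is empty after selection")
  tw <- as.numeric(unlist(cfg$analysis$time_window %||% c(0.1, 0.4)))
  collapsed <- collapseLongTable(long, tw)
  gc <- cfg$group %||% list()
  fixed <- if (!is.null(gc$fixed)) unlist(gc$fixed)
  res <- fitLME(collapsed, fixed = fixed,
                random = gc$random %||% "(1|Subject/Electrode)")
  dir <- file.path(projectDir(cfg), "group")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(res$fixedEffects, file.path(dir, "fixed_effects.csv"),
                   row.names = FALSE)
  utils::write.csv(res$randomEffects, file.path(dir, "random_effects.csv"),
                   row.names = FALSE)
  ct <- omnibusAndPairwise(res, adjust = gc$adjust %||% "none")
  utils::write.csv(ct$omnibus, file.path(dir, "omnibus.csv"),
                   row.names = FALSE)
  utils::write.csv(ct$pairwise, file.path(dir, "pairwise.csv"),
                   row.names = FALSE)
  uni <- univariateByElectrode(collapsed)
  utils::write.csv(uni, file.path(dir, "per_electrode.csv"),
                   row.names = FALSE)
  writeProvenance(dir, "group", cfg, list(formula = res$formula))
  logMsg(cfg, "group analysis: ", res$formula)
  invisible(res)
}
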