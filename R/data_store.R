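#' @include AllClasses.R
NULL

## On-disk layout: <root>/<project>/<subject>/{raw,spectral,meta}
## raw/block-<id>.h5            voltage (channels x samples) + rate + channels
## raw/trigger-<id>.h5          analog trigger channel + rate
## spectral/<block>/e<NNN>.h5   complex coefficients, one file per electrode
## referenced/<block>/e<NNN>.h5 same layout after re-referencing
## meta/*.csv                   electrode / epoch / stats tables

#' Initialize a subject's directory tree
#'
#' Creates (idempotently) the project -> subject -> data-files tree with
#' `raw/`, `spectral/` and `meta/` subfolders, and returns a handle used by
#' all storage operations.
#'
#' @param root writable project root directory.
#' @param project project name (e.g. `"speech"`).
#' @param subject subject identifier; letters, digits, `_` and `-` only.
#' @return A [SubjectStore-class] handle.
#' @examples
#' store <- initSubject(tempdir(), "demo_project", "YAB")
#' @export
initSubject <- function(root, project, subject) {
  for (nm in c(project = project, subject = subject)) {
    if (!is.character(nm) || length(nm) != 1L || !nzchar(nm))
      stop("project and subject ids must be non-empty strings")
  }
  if (!grepl("^[A-Za-z0-9_-]+$", subject) || !grepl("^[A-Za-z0-9_-]+$", project))
    stop(sprintf("illegal characters in id '%s': use letters, digits, '_', '-'",
                 if (grepl("^[A-Za-z0-9_-]+$", project)) subject else project))
  base <- file.path(root, project, subject)
  for (sub in c("raw", "spectral", "referenced", "meta")) {
    d <- file.path(base, sub)
    if (!dir.exists(d) && !dir.create(d, recursive = TRUE, showWarnings = FALSE))
      stop("cannot create directory (root unwritable?): ", d)
  }
  new("SubjectStore", root = normalizePath(root), project = project,
      subject = subject)
}

#' Path inside a subject store
#'
#' @param store a [SubjectStore-class].
#' @param ... path components below the subject directory.
#' @return A file path.
#' @export
storePath <- function(store, ...) {
  file.path(store@root, store@project, store@subject, ...)
}

## ---- HDF5 helpers -------------------------------------------------------

h5WriteAttr <- function(file, obj, name, value) {
  fid <- rhdf5::H5Fopen(file)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  oid <- rhdf5::H5Dopen(fid, obj)
  on.exit(rhdf5::H5Dclose(oid), add = TRUE, after = FALSE)
  rhdf5::h5writeAttribute(value, oid, name)
  invisible(NULL)
}

## ---- raw voltage --------------------------------------------------------

#' Import a raw voltage block
#'
#' Accepts an in-memory matrix, a whitespace/comma-delimited text matrix
#' file (rows = channels), or an HDF5 file holding `/voltage/data`.
#' The block is persisted under `raw/` in HDF5 so that a re-read returns
#' bit-identical values.
#'
#' @param store a [SubjectStore-class].
#' @param blockId block identifier.
#' @param source matrix or path to a matrix file.
#' @param sampleRate sampling rate in Hz.
#' @param channelNumbers electrode number of each matrix row.
#' @return The imported [VoltageBlock-class].
#' @export
importVoltage <- function(store, blockId, source, sampleRate, channelNumbers) {
  mat <- readVoltageSource(source)
  channelNumbers <- as.integer(channelNumbers)
  if (nrow(mat) != length(channelNumbers))
    stop(sprintf("source has %d channel rows but %d channel numbers given",
                 nrow(mat), length(channelNumbers)))
  bad <- which(apply(mat, 1L, function(r) any(!is.finite(r))))
  if (length(bad))
    stop("non-finite samples in channel(s): ",
         paste(channelNumbers[bad], collapse = ", "))
  block <- VoltageBlock(blockId, mat, sampleRate, channelNumbers)
  path <- storePath(store, "raw", paste0("block-", blockId, ".h5"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "voltage")
  rhdf5::h5write(mat, path, "voltage/data")
  rhdf5::h5write(as.numeric(sampleRate), path, "voltage/sample_rate")
  rhdf5::h5write(channelNumbers, path, "voltage/channel_numbers")
  rhdf5::h5closeAll()
  block
}

readVoltageSource <- function(source) {
  if (is.matrix(source)) return(source)
  if (is.character(source) && length(source) == 1L) {
    if (!file.exists(source)) stop("source file not found: ", source)
    if (grepl("\\.(h5|hdf5)$", source, ignore.case = TRUE)) {
      mat <- rhdf5::h5read(source, "voltage/data")
      rhdf5::h5closeAll()
      return(mat)
    }
    sep <- if (grepl("\\.csv$", source, ignore.case = TRUE)) "," else ""
    mat <- as.matrix(utils::read.table(source, header = FALSE, sep = sep))
    dimnames(mat) <- NULL
    if (!is.numeric(mat)) stop("source does not parse to a numeric matrix")
    return(mat)
  }
  stop("source must be a numeric matrix or a file path")
}

#' Read a stored voltage block
#'
#' @param store a [SubjectStore-class].
#' @param blockId block identifier.
#' @return A [VoltageBlock-class].
#' @export
readVoltage <- function(store, blockId) {
  path <- storePath(store, "raw", paste0("block-", blockId, ".h5"))
  if (!file.exists(path)) stop("no stored voltage block '", blockId, "'")
  mat <- rhdf5::h5read(path, "voltage/data")
  rate <- as.numeric(rhdf5::h5read(path, "voltage/sample_rate"))
  ch <- as.integer(rhdf5::h5read(path, "voltage/channel_numbers"))
  rhdf5::h5closeAll()
  VoltageBlock(blockId, mat, rate, ch)
}

#' List stored raw block ids
#' @param store a [SubjectStore-class].
#' @return Character vector of block ids.
#' @export
listBlocks <- function(store) {
  f <- list.files(storePath(store, "raw"), pattern = "^block-.*\\.h5$")
  sub("^block-(.*)\\.h5$", "\\1", f)
}

#' Store / read an analog trigger channel
#'
#' @param store a [SubjectStore-class].
#' @param blockId block identifier.
#' @param x numeric vector (analog input samples).
#' @param sampleRate Hz.
#' @return `readTrigger` returns `list(data, sampleRate)`.
#' @export
writeTrigger <- function(store, blockId, x, sampleRate) {
  path <- storePath(store, "raw", paste0("trigger-", blockId, ".h5"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(as.numeric(x), path, "data")
  rhdf5::h5write(as.numeric(sampleRate), path, "sample_rate")
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname writeTrigger
#' @export
readTrigger <- function(store, blockId) {
  path <- storePath(store, "raw", paste0("trigger-", blockId, ".h5"))
  if (!file.exists(path)) stop("no stored trigger channel for block '", blockId, "'")
  out <- list(data = as.numeric(rhdf5::h5read(path, "data")),
              sampleRate = as.numeric(rhdf5::h5read(path, "sample_rate")))
  rhdf5::h5closeAll()
  out
}

## ---- spectral storage ---------------------------------------------------

#' Write / read complex spectral coefficients
#'
#' One HDF5 file per electrode per data kind, so a single electrode loads
#' without touching the rest of the subject. Real and imaginary parts are
#' stored as separate datasets under `/spectral/coefficients`; frequencies,
#' spectral rate and the applied reference travel as HDF5 attributes.
#' The complex round trip is bit-exact.
#'
#' @param store a [SubjectStore-class].
#' @param spectral a [SpectralArray-class].
#' @param blockId block the coefficients belong to.
#' @param kind `"spectral"` (unreferenced) or `"referenced"`.
#' @return `readSpectral` returns a [SpectralArray-class].
#' @export
writeSpectral <- function(store, spectral, blockId,
                          kind = c("spectral", "referenced")) {
  kind <- match.arg(kind)
  stopifnot(is(spectral, "SpectralArray"))
  methods::validObject(spectral)
  dir <- storePath(store, kind, blockId)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, sprintf("e%03d.h5", spectral@electrode))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "spectral")
  rhdf5::h5createGroup(path, "spectral/coefficients")
  rhdf5::h5write(Re(spectral@coefficients), path, "spectral/coefficients/real")
  rhdf5::h5write(Im(spectral@coefficients), path, "spectral/coefficients/imag")
  mask <- spectral@validMask
  if (!is.null(mask))
    rhdf5::h5write(mask + 0L, path, "spectral/valid_mask")
  rhdf5::h5closeAll()
  h5WriteAttr(path, "spectral/coefficients/real", "frequencies",
              spectral@frequencies)
  h5WriteAttr(path, "spectral/coefficients/real", "spectral_rate",
              spectral@spectralRate)
  h5WriteAttr(path, "spectral/coefficients/real", "reference",
              spectral@reference)
  h5WriteAttr(path, "spectral/coefficients/real", "electrode",
              spectral@electrode)
  invisible(path)
}

#' @rdname writeSpectral
#' @param electrodeNumber electrode to load.
#' @export
readSpectral <- function(store, electrodeNumber, blockId,
                         kind = c("spectral", "referenced")) {
  kind <- match.arg(kind)
  path <- file.path(storePath(store, kind, blockId),
                    sprintf("e%03d.h5", as.integer(electrodeNumber)))
  if (!file.exists(path))
    stop(sprintf("electrode %d not found in %s/%s", as.integer(electrodeNumber),
                 kind, blockId))
  re <- rhdf5::h5read(path, "spectral/coefficients/real")
  im <- rhdf5::h5read(path, "spectral/coefficients/imag")
  at <- rhdf5::h5readAttributes(path, "spectral/coefficients/real")
  mask <- tryCatch(rhdf5::h5read(path, "spectral/valid_mask") != 0L,
                   error = function(e) NULL)
  rhdf5::h5closeAll()
  SpectralArray(electrode = as.integer(at$electrode),
                coefficients = complex(real = re, imaginary = im) |>
                  matrix(nrow = nrow(re)),
                frequencies = as.numeric(at$frequencies),
                spectralRate = as.numeric(at$spectral_rate),
                reference = as.character(at$reference),
                validMask = mask)
}

#' List electrodes with stored spectral data
#' @inheritParams readSpectral
#' @return Integer vector of electrode numbers.
#' @export
listSpectralElectrodes <- function(store, blockId,
                                   kind = c("spectral", "referenced")) {
  kind <- match.arg(kind)
  f <- list.files(storePath(store, kind, blockId), pattern = "^e[0-9]+\\.h5$")
  sort(as.integer(sub("^e([0-9]+)\\.h5$", "\\1", f)))
}

## ---- metadata tables ----------------------------------------------------

electrodeRequiredCols <- c("Electrode", "Label", "x", "y", "z",
                           "AnatomicalLabel", "Group", "Excluded")

#' Read / write the electrode metadata table
#'
#' Required columns: `Electrode` (unique positive integer), `Label`,
#' `x`, `y`, `z` (subject anatomical space, millimetres; stored but never
#' interpreted geometrically), `AnatomicalLabel`, `Group` (grid/shaft name)
#' and `Excluded` (logical mask; excluded rows are kept, never dropped).
#' Unknown extra columns (e.g. a clinician's `EpileptiformIndex`) are
#' preserved and queryable.
#'
#' @param path CSV file path.
#' @return A `data.frame` with one row per electrode.
#' @export
readElectrodeTable <- function(path) {
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
  validateElectrodeTable(tbl)
}

#' @rdname readElectrodeTable
#' @param table an electrode table to validate or write.
#' @export
validateElectrodeTable <- function(table) {
  miss <- setdiff(electrodeRequiredCols, names(table))
  if (length(miss))
    stop("electrode table lacks required column(s): ",
         paste(miss, collapse = ", "))
  if (any(!isWholeNumber(table$Electrode)) || any(table$Electrode < 1))
    stop("Electrode numbers must be positive integers (1-based)")
  dup <- unique(table$Electrode[duplicated(table$Electrode)])
  if (length(dup))
    stop("duplicate electrode number(s): ", paste(dup, collapse = ", "))
  table$Electrode <- as.integer(table$Electrode)
  table$Excluded <- as.logical(table$Excluded)
  if (anyNA(table$Excluded)) stop("Excluded must be logical (TRUE/FALSE)")
  table
}

#' @rdname readElectrodeTable
#' @export
writeElectrodeTable <- function(table, path) {
  table <- validateElectrodeTable(table)
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

epochRequiredCols <- c("Block", "Trial", "Condition", "Time")

#' Read / write the trial epoch table
#'
#' Required columns: `Block`, `Trial` (unique within block), `Condition`
#' and `Time` — the primary onset event, in seconds from block start
#' (0-based). Any additional `<EventName>_Time` column defines a further
#' event usable for time-locking. An optional logical `Outlier` column
#' flags trials excluded from statistics.
#'
#' @param path CSV file path.
#' @return A `data.frame` with one row per trial.
#' @export
readEpochTable <- function(path) {
  ## Block ids are labels, not numbers: "001" must stay "001"
  tbl <- suppressWarnings(
    utils::read.csv(path, stringsAsFactors = FALSE,
                    colClasses = c(Block = "character")))
  validateEpochTable(tbl)
}

#' @rdname readEpochTable
#' @param table an epoch table to validate or write.
#' @export
validateEpochTable <- function(table) {
  miss <- setdiff(epochRequiredCols, names(table))
  if (length(miss))
    stop("epoch table lacks required column(s): ", paste(miss, collapse = ", "))
  key <- paste(table$Block, table$Trial, sep = "/")
  dup <- unique(key[duplicated(key)])
  if (length(dup))
    stop("duplicate (Block, Trial) key(s): ", paste(dup, collapse = ", "))
  if (any(!is.finite(table$Time)) || any(table$Time < 0))
    stop("Time must be finite and non-negative (seconds from block start)")
  if (is.null(table$Outlier)) table$Outlier <- FALSE
  table$Outlier <- as.logical(table$Outlier)
  table$Block <- as.character(table$Block)
  table$Trial <- as.integer(table$Trial)
  table
}

#' @rdname readEpochTable
#' @export
writeEpochTable <- function(table, path) {
  table <- validateEpochTable(table)
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Event names available in an epoch table
#'
#' The primary onset is named `"Trial"` (column `Time`); every extra
#' `<EventName>_Time` column contributes `<EventName>`.
#'
#' @param epochs an epoch table.
#' @return Character vector of event names.
#' @export
epochEventNames <- function(epochs) {
  extra <- grep("_Time$", names(epochs), value = TRUE)
  c("Trial", sub("_Time$", "", extra))
}

## ---- long-format export -------------------------------------------------

#' Export per-trial power-by-time data in long format
#'
#' One row per (subject, electrode, trial, timepoint) with the power value
#' (in whatever unit the tensors carry), condition and block — the input
#' contract of the group analysis. Outlier-flagged trials are excluded.
#'
#' @param tensors named list of [TrialTensor-class] (names = electrode
#'   numbers), identical time/frequency axes and unit.
#' @param subject subject identifier.
#' @param freqRange optional `c(low, high)` Hz band to average over
#'   (default: all frequencies).
#' @param file optional CSV path to also write the table to.
#' @return A `data.frame` with columns `Subject`, `Electrode`, `Block`,
#'   `Trial`, `Condition`, `Time`, `Power`.
#' @export
exportLongTable <- function(tensors, subject, freqRange = NULL, file = NULL) {
  if (length(tensors) == 0L)
    stop("empty electrode selection: nothing to export")
  if (is.null(names(tensors)))
    names(tensors) <- vapply(tensors, function(t) as.character(t@electrode),
                             character(1))
  rows <- lapply(tensors, function(tt) {
    stopifnot(is(tt, "TrialTensor"))
    fidx <- if (is.null(freqRange)) seq_along(tt@frequencies) else
      which(tt@frequencies >= freqRange[1] & tt@frequencies <= freqRange[2])
    if (!length(fidx)) stop("freqRange selects no frequencies")
    keep <- which(!tt@trialMeta$is_outlier)
    if (!length(keep)) return(NULL)
    ## trial x time after averaging the band
    tm <- apply(tt@power[keep, fidx, , drop = FALSE], c(1, 3), mean)
    nT <- length(tt@timeAxis)
    data.frame(
      Subject = subject,
      Electrode = tt@electrode,
      Block = rep(tt@trialMeta$block[keep], each = nT),
      Trial = rep(tt@trialMeta$trial_number[keep], each = nT),
      Condition = rep(tt@trialMeta$condition[keep], each = nT),
      Time = rep(tt@timeAxis, times = length(keep)),
      Power = as.vector(t(tm)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || !nrow(out))
    stop("empty electrode selection: all trials are outlier-flagged")
  rownames(out) <- NULL
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}

#' Collapse a long table over an analysis time window
#'
#' Averages `Power` over timepoints in the half-open window per
#' (Subject, Electrode, Block, Trial), producing the per-trial scalar
#' dataset the linear mixed-effects model consumes.
#'
#' @param long a long table from [exportLongTable()].
#' @param window `c(start, end)` seconds relative to the locking event.
#' @return A `data.frame` with one row per trial and a `Power` column.
#' @export
collapseLongTable <- function(long, window) {
  sel <- long[inWindow(long$Time, window), , drop = FALSE]
  if (!nrow(sel)) stop("analysis window contains no timepoints")
  agg <- stats::aggregate(
    Power ~ Subject + Electrode + Block + Trial + Condition,
    data = sel, FUN = mean)
  agg[order(agg$Subject, agg$Electrode, agg$Block, agg$Trial), , drop = FALSE]
}
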