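#' @include AllClasses.R
NULL

#' Detect event onsets on an analog trigger channel
#'
#' Returns the times of upward threshold crossings — the first sample at
#' or above `threshold` after being below it — suppressing crossings
#' closer than `minSeparation` seconds to the previously accepted onset
#' (refractory rule against pulse chatter). Typical inputs are acquisition
#' system analog channels from photodiodes or microphones.
#'
#' @param x numeric vector of analog samples, or a [VoltageBlock-class].
#' @param sampleRate Hz (taken from the block when `x` is one).
#' @param threshold crossing threshold, in the channel's units.
#' @param minSeparation refractory period in seconds (default 0).
#' @param channel electrode number to use when `x` is a block.
#' @return Numeric vector of onset times in seconds (0-based from block
#'   start). A threshold outside the signal range yields an empty result
#'   with a warning, not an error.
#' @export
detectEvents <- function(x, sampleRate = NULL, threshold, minSeparation = 0,
                         channel = NULL) {
  if (is(x, "VoltageBlock")) {
    if (is.null(channel)) {
      if (nrow(x@data) != 1L)
        stop("specify 'channel' when the block has multiple channels")
      channel <- x@channelNumbers[1]
    }
    i <- match(channel, x@channelNumbers)
    if (is.na(i)) stop("channel ", channel, " not in block")
    sampleRate <- x@sampleRate
    x <- x@data[i, ]
  }
  assertScalarNumber(sampleRate, "sampleRate", positive = TRUE)
  if (minSeparation < 0) stop("minSeparation must be >= 0")
  if (threshold > max(x) || threshold <= min(x)) {
    warning("threshold outside signal range: no events detected")
    return(numeric(0))
  }
  above <- x >= threshold
  crossings <- which(above & !c(FALSE, above[-length(above)]))
  times <- (crossings - 1L) / sampleRate
  if (minSeparation > 0 && length(times) > 1L) {
    keep <- logical(length(times))
    last <- -Inf
    for (i in seq_along(times)) {
      if (times[i] - last >= minSeparation) {
        keep[i] <- TRUE
        last <- times[i]
      }
    }
    times <- times[keep]
  }
  times
}

#' Propose an epoch table from detected onsets
#'
#' The semi-automated epoching flow: detected onsets are written to an
#' epoch CSV that the user may hand-edit and read back.
#'
#' @param onsets numeric vector of onset times (seconds).
#' @param blockId block identifier.
#' @param conditions condition label(s), recycled across trials.
#' @return An epoch table `data.frame`.
#' @export
proposeEpochs <- function(onsets, blockId, conditions = "unlabeled") {
  n <- length(onsets)
  validateEpochTable(data.frame(
    Block = rep(as.character(blockId), n),
    Trial = seq_len(n),
    Condition = rep_len(as.character(conditions), n),
    Time = as.numeric(onsets),
    stringsAsFactors = FALSE
  ))
}

#' Slice continuous spectral data into a trial tensor
#'
#' Epochs one electrode's complex coefficients into a
#' trial x frequency x time tensor time-locked to the chosen event, with
#' `power = |coef|^2` and `phase = arg(coef)`. The epoch window is
#' half-open `[pre, post)` with the event sample included at t = 0.
#' Trials whose window exceeds the block bounds, or overlaps the wavelet
#' edge-validity mask, are excluded with a warning by default
#' (`onEdge = "keep"` retains edge-contaminated trials). Outlier flags
#' from the epoch table are carried through.
#'
#' @param spectral a [SpectralArray-class], or a named list of them keyed
#'   by block id when the epoch table spans several blocks.
#' @param epochs an epoch table (see [readEpochTable()]).
#' @param lockingEvent `"Trial"` (the primary onset) or the name of any
#'   `<EventName>_Time` column.
#' @param window `c(pre, post)` seconds relative to the event
#'   (`pre < post`, `pre` typically negative).
#' @param onEdge `"exclude"` (default) or `"keep"` for trials overlapping
#'   the wavelet edge mask.
#' @return A [TrialTensor-class].
#' @export
buildTrialTensor <- function(spectral, epochs, lockingEvent = "Trial",
                             window = c(-1, 2),
                             onEdge = c("exclude", "keep")) {
  onEdge <- match.arg(onEdge)
  epochs <- validateEpochTable(epochs)
  if (window[1] >= window[2]) stop("window must satisfy pre < post")
  events <- epochEventNames(epochs)
  if (!lockingEvent %in% events)
    stop(sprintf("unknown locking event '%s'; available: %s", lockingEvent,
                 paste(events, collapse = ", ")))
  timeCol <- if (lockingEvent == "Trial") "Time" else
    paste0(lockingEvent, "_Time")

  if (is(spectral, "SpectralArray")) {
    blocks <- unique(epochs$Block)
    if (length(blocks) != 1L)
      stop("epoch table spans several blocks; supply a named list of ",
           "SpectralArray keyed by block id")
    spectral <- stats::setNames(list(spectral), blocks)
  }
  missingBlocks <- setdiff(unique(epochs$Block), names(spectral))
  if (length(missingBlocks))
    stop("no spectral data for block(s): ", paste(missingBlocks, collapse = ", "))
  first <- spectral[[1]]
  rate <- first@spectralRate
  offsets <- seq.int(round(window[1] * rate), round(window[2] * rate) - 1L)
  nT <- length(offsets)
  K <- length(first@frequencies)

  nTrials <- nrow(epochs)
  power <- array(NA_real_, c(nTrials, K, nT))
  phase <- array(NA_real_, c(nTrials, K, nT))
  dropped <- integer()
  edgeTrials <- integer()
  for (i in seq_len(nTrials)) {
    sa <- spectral[[epochs$Block[i]]]
    t0 <- epochs[[timeCol]][i]
    cols <- round(t0 * rate) + 1L + offsets
    if (cols[1] < 1L || cols[nT] > ncol(sa@coefficients)) {
      dropped <- c(dropped, i)
      next
    }
    if (!is.null(sa@validMask) && !all(sa@validMask[, cols])) {
      edgeTrials <- c(edgeTrials, i)
      if (onEdge == "exclude") { dropped <- c(dropped, i); next }
    }
    co <- sa@coefficients[, cols, drop = FALSE]
    power[i, , ] <- Mod(co)^2
    phase[i, , ] <- Arg(co)
  }
  if (length(edgeTrials))
    warning(sprintf("trial(s) %s overlap the wavelet edge-validity mask%s",
                    paste(epochs$Trial[edgeTrials], collapse = ", "),
                    if (onEdge == "exclude") " and were excluded" else ""))
  outOfBounds <- setdiff(dropped, if (onEdge == "exclude") edgeTrials else integer())
  if (length(outOfBounds))
    warning(sprintf("trial(s) %s exceed block bounds and were excluded",
                    paste(epochs$Trial[outOfBounds], collapse = ", ")))
  keep <- setdiff(seq_len(nTrials), dropped)
  if (!length(keep)) stop("no trials remain after bounds/edge exclusion")
  meta <- data.frame(
    trial_number = epochs$Trial[keep],
    block = epochs$Block[keep],
    condition = epochs$Condition[keep],
    is_outlier = epochs$Outlier[keep],
    stringsAsFactors = FALSE
  )
  new("TrialTensor",
      electrode = first@electrode,
      power = power[keep, , , drop = FALSE],
      phase = phase[keep, , , drop = FALSE],
      timeAxis = offsets / rate,
      frequencies = first@frequencies,
      trialMeta = meta,
      lockingEvent = lockingEvent,
      unit = "power")
}
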