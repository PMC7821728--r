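#' @include AllClasses.R
NULL

#' Build a common-average reference scheme
#'
#' The reference set is every electrode not flagged `Excluded` in the
#' electrode table — user masking must propagate, because concentrated
#' coverage over one brain area is otherwise strongly weighted in the
#' common average.
#'
#' @param electrodeTable an electrode table (see [readElectrodeTable()]).
#' @return A [ReferenceScheme-class] of kind `"common_average"`.
#' @export
buildCAR <- function(electrodeTable) {
  electrodeTable <- validateElectrodeTable(electrodeTable)
  usable <- electrodeTable$Electrode[!electrodeTable$Excluded]
  if (length(usable) < 2L)
    stop("common average reference needs at least 2 non-excluded electrodes")
  new("ReferenceScheme", kind = "common_average",
      electrodes = sort(as.integer(usable)))
}

#' Build a white-matter reference scheme
#'
#' The reference is the complex mean over a user-designated set of one or
#' more contacts presumed to sit in neurally quiet white matter.
#'
#' @param wmElectrodes integer vector of reference electrode numbers.
#' @return A [ReferenceScheme-class] of kind `"white_matter"`.
#' @export
buildWhiteMatter <- function(wmElectrodes) {
  wmElectrodes <- as.integer(wmElectrodes)
  if (!length(wmElectrodes)) stop("white-matter reference set must be nonempty")
  new("ReferenceScheme", kind = "white_matter",
      electrodes = sort(unique(wmElectrodes)))
}

#' Build a bipolar reference scheme
#'
#' Default pairing rule (standard sEEG practice): within each group
#' (shaft/grid), numerically consecutive contacts are paired `(k, k+1)`;
#' the last contact of each group yields no derived channel, and a missing
#' contact breaks the chain (the gap is messaged). Derived channels are
#' labeled `"A-B"` and receive synthetic electrode numbers above the
#' native range so downstream tables stay keyed by a single integer.
#' An explicit pairs table (`Anode`, `Cathode`, optional `Label`)
#' overrides the rule.
#'
#' @param electrodeTable an electrode table.
#' @param pairs optional data.frame (or CSV path) of explicit pairs.
#' @return A [ReferenceScheme-class] of kind `"bipolar"`.
#' @export
buildBipolar <- function(electrodeTable, pairs = NULL) {
  electrodeTable <- validateElectrodeTable(electrodeTable)
  lab <- stats::setNames(electrodeTable$Label,
                         as.character(electrodeTable$Electrode))
  if (!is.null(pairs)) {
    if (is.character(pairs)) pairs <- utils::read.csv(pairs)
    if (!all(c("Anode", "Cathode") %in% names(pairs)))
      stop("explicit pairs need columns Anode, Cathode")
    a <- as.integer(pairs$Anode); c2 <- as.integer(pairs$Cathode)
    known <- electrodeTable$Electrode
    missing <- setdiff(c(a, c2), known)
    if (length(missing))
      stop("pairs reference unknown electrode(s): ",
           paste(missing, collapse = ", "))
    if (any(a == c2)) stop("bipolar pairs must reference distinct electrodes")
    label <- if (!is.null(pairs$Label)) as.character(pairs$Label) else
      paste0(lab[as.character(a)], "-", lab[as.character(c2)])
    pr <- data.frame(anode = a, cathode = c2,
                     derived = max(known) + seq_along(a), label = label,
                     stringsAsFactors = FALSE)
    return(new("ReferenceScheme", kind = "bipolar", pairs = pr))
  }
  prs <- list()
  for (g in unique(electrodeTable$Group)) {
    contacts <- sort(electrodeTable$Electrode[electrodeTable$Group == g])
    if (length(contacts) < 2L) {
      warning(sprintf("group '%s' has a single contact: no bipolar pairs", g))
      next
    }
    step <- diff(contacts)
    gaps <- which(step != 1L)
    if (length(gaps))
      message(sprintf("group '%s': gap after contact(s) %s; pair(s) skipped",
                      g, paste(contacts[gaps], collapse = ", ")))
    keep <- which(step == 1L)
    if (length(keep))
      prs[[g]] <- data.frame(anode = contacts[keep],
                             cathode = contacts[keep + 1L],
                             stringsAsFactors = FALSE)
  }
  pr <- if (length(prs)) do.call(rbind, prs) else
    data.frame(anode = integer(), cathode = integer())
  rownames(pr) <- NULL
  pr$derived <- if (nrow(pr)) max(electrodeTable$Electrode) + seq_len(nrow(pr)) else integer()
  pr$label <- if (nrow(pr))
    paste0(lab[as.character(pr$anode)], "-", lab[as.character(pr$cathode)]) else character()
  new("ReferenceScheme", kind = "bipolar", pairs = pr)
}

#' Apply a reference scheme in the complex spectral domain
#'
#' Because the wavelet transform is linear and referencing is a linear
#' combination of channels, re-referencing the complex coefficients equals
#' wavelet-transforming time-domain-referenced voltages — provided both
#' real and imaginary parts were preserved. Common-average / white-matter:
#' the complex mean over the reference set is subtracted from every
#' electrode. Bipolar: each pair yields a derived channel
#' `anode - cathode`.
#'
#' @param spectra named list of [SpectralArray-class] (names = electrode
#'   numbers), identical frequency/time axes.
#' @param scheme a [ReferenceScheme-class].
#' @return Named list of referenced [SpectralArray-class]; for bipolar, the
#'   derived channels keyed by their synthetic electrode numbers.
#' @export
applyReference <- function(spectra, scheme) {
  stopifnot(is(scheme, "ReferenceScheme"))
  if (is.null(names(spectra)))
    names(spectra) <- vapply(spectra, function(s) as.character(s@electrode),
                             character(1))
  checkAxes(spectra)
  if (scheme@kind == "none") return(spectra)
  if (scheme@kind %in% c("common_average", "white_matter")) {
    refIds <- as.character(scheme@electrodes)
    missing <- setdiff(refIds, names(spectra))
    if (length(missing))
      stop("scheme references missing electrode(s): ",
           paste(missing, collapse = ", "))
    ref <- Reduce(`+`, lapply(spectra[refIds], spectralCoefs)) / length(refIds)
    tag <- sprintf("%s(%s)",
                   if (scheme@kind == "common_average") "car" else "wm",
                   paste(scheme@electrodes, collapse = ","))
    return(lapply(spectra, function(s)
      SpectralArray(s@electrode, s@coefficients - ref, s@frequencies,
                    s@spectralRate, tag, s@validMask)))
  }
  ## bipolar
  pr <- scheme@pairs
  need <- as.character(unique(c(pr$anode, pr$cathode)))
  missing <- setdiff(need, names(spectra))
  if (length(missing))
    stop("scheme references missing electrode(s): ",
         paste(missing, collapse = ", "))
  out <- lapply(seq_len(nrow(pr)), function(i) {
    a <- spectra[[as.character(pr$anode[i])]]
    b <- spectra[[as.character(pr$cathode[i])]]
    mask <- if (is.null(a@validMask) || is.null(b@validMask)) NULL else
      a@validMask & b@validMask
    SpectralArray(pr$derived[i], a@coefficients - b@coefficients,
                  a@frequencies, a@spectralRate,
                  sprintf("bipolar:%s(%d-%d)", pr$label[i], pr$anode[i],
                          pr$cathode[i]),
                  mask)
  })
  names(out) <- as.character(pr$derived)
  out
}

checkAxes <- function(spectra) {
  if (!length(spectra)) stop("no spectral arrays supplied")
  ref <- spectra[[1]]
  for (s in spectra) {
    if (!isTRUE(all.equal(s@frequencies, ref@frequencies)) ||
        !identical(dim(s@coefficients), dim(ref@coefficients)) ||
        abs(s@spectralRate - ref@spectralRate) > 1e-9)
      stop("all electrodes must share identical frequency/time axes")
  }
  invisible(TRUE)
}

#' Apply a reference scheme to time-domain voltages
#'
#' The conventional reference-then-decompose order, provided for
#' completeness and cross-checking; numerically equivalent (to rounding)
#' to [applyReference()] on the wavelet coefficients.
#'
#' @param block a [VoltageBlock-class].
#' @param scheme a [ReferenceScheme-class].
#' @return A referenced [VoltageBlock-class]; for bipolar, channels are the
#'   derived pairs keyed by their synthetic numbers.
#' @export
applyReferenceVoltage <- function(block, scheme) {
  stopifnot(is(block, "VoltageBlock"), is(scheme, "ReferenceScheme"))
  if (scheme@kind == "none") return(block)
  idx <- function(e) {
    i <- match(e, block@channelNumbers)
    if (anyNA(i)) stop("scheme references missing electrode(s): ",
                       paste(e[is.na(i)], collapse = ", "))
    i
  }
  if (scheme@kind %in% c("common_average", "white_matter")) {
    ref <- colMeans(block@data[idx(scheme@electrodes), , drop = FALSE])
    out <- sweep(block@data, 2L, ref, `-`)
    return(VoltageBlock(block@blockId, out, block@sampleRate,
                        block@channelNumbers))
  }
  pr <- scheme@pairs
  out <- block@data[idx(pr$anode), , drop = FALSE] -
    block@data[idx(pr$cathode), , drop = FALSE]
  VoltageBlock(block@blockId, out, block@sampleRate, as.integer(pr$derived))
}
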