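#' @include AllClasses.R
NULL

baselineUnits <- c("percent_power", "percent_amplitude", "zscore_power",
                   "zscore_amplitude", "decibel")

#' Baseline-normalize a trial tensor
#'
#' Expresses power relative to a pre-event baseline window, per trial and
#' per frequency. With `m` and `s` the mean and SD of the trial's
#' baseline-window samples (of power, or of amplitude = sqrt(power) for
#' the amplitude units):
#' percent units give `100 * (x - m) / m`, z-score units `(x - m) / s`,
#' and decibel `10 * log10(power / m)`.
#'
#' The default mode computes `m`, `s` within each trial, keeping trials
#' exchangeable units for the group model. `mode = "pooled"` instead pools
#' the baseline samples of all non-outlier trials (per frequency), which
#' removes the small-sample inflation of the per-trial ratio estimator
#' when baseline windows are short relative to the wavelet smoothing.
#'
#' @param tensor a [TrialTensor-class] with `unit == "power"`.
#' @param window `c(start, end)` seconds relative to the locking event
#'   (half-open).
#' @param unit one of `"percent_power"`, `"percent_amplitude"`,
#'   `"zscore_power"`, `"zscore_amplitude"`, `"decibel"`.
#' @param mode `"per_trial"` (default) or `"pooled"`.
#' @return A [TrialTensor-class] of the same shape, unit annotated.
#' @export
baselineTransform <- function(tensor, window, unit = baselineUnits,
                              mode = c("per_trial", "pooled")) {
  stopifnot(is(tensor, "TrialTensor"))
  unit <- match.arg(unit)
  mode <- match.arg(mode)
  if (!identical(tensor@unit, "power"))
    stop("tensor is already in unit '", tensor@unit, "'; baseline from raw power")
  idx <- which(inWindow(tensor@timeAxis, window))
  if (!length(idx)) stop("baseline window contains no timepoints")
  d <- dim(tensor@power)
  p <- tensor@power
  x <- if (unit %in% c("percent_amplitude", "zscore_amplitude")) sqrt(p) else p
  bl <- x[, , idx, drop = FALSE]

  if (mode == "per_trial") {
    m <- apply(bl, c(1, 2), mean)
    s <- apply(bl, c(1, 2), stats::sd)
  } else {
    keep <- which(!tensor@trialMeta$is_outlier)
    if (!length(keep)) keep <- seq_len(d[1])
    pool <- bl[keep, , , drop = FALSE]
    mf <- apply(pool, 2L, mean)
    sf <- apply(pool, 2L, stats::sd)
    m <- matrix(mf, d[1], d[2], byrow = TRUE)
    s <- matrix(sf, d[1], d[2], byrow = TRUE)
  }
  badm <- which(m == 0, arr.ind = TRUE)
  if (nrow(badm))
    stop(sprintf("zero baseline mean for electrode %d, trial %s: all-zero signal?",
                 tensor@electrode,
                 paste(unique(tensor@trialMeta$trial_number[badm[, 1]]),
                       collapse = ", ")))
  mArr <- array(m, d)  # trial x freq slabs recycle along time
  out <- switch(unit,
    percent_power = ,
    percent_amplitude = 100 * (x - mArr) / mArr,
    zscore_power = ,
    zscore_amplitude = {
      bads <- which(s == 0, arr.ind = TRUE)
      if (nrow(bads))
        stop(sprintf("zero baseline SD for electrode %d, trial %s: cannot z-score",
                     tensor@electrode,
                     paste(unique(tensor@trialMeta$trial_number[bads[, 1]]),
                           collapse = ", ")))
      (x - mArr) / array(s, d)
    },
    decibel = 10 * log10(p / mArr)
  )
  methods::initialize(tensor, power = out, unit = unit)
}

#' Condition grouping
#'
#' Groups trial conditions into named analysis groups; conditions not
#' assigned to any group are excluded from statistics. The default groups
#' all conditions into a single group.
#'
#' @param groups named list of character vectors of condition labels, or
#'   `NULL` for the single-group default.
#' @param conditions all condition labels (required when `groups` is
#'   `NULL`).
#' @return An object of class `ConditionGrouping`.
#' @export
conditionGrouping <- function(groups = NULL, conditions = NULL) {
  if (is.null(groups)) {
    if (is.null(conditions)) stop("supply 'conditions' for the default grouping")
    groups <- list(All = unique(as.character(conditions)))
  }
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("every group must be named")
  if (anyDuplicated(names(groups))) stop("group names must be unique")
  flat <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(flat))
    stop("condition(s) in more than one group: ",
         paste(unique(flat[duplicated(flat)]), collapse = ", "))
  structure(lapply(groups, as.character), class = "ConditionGrouping")
}

#' @export
print.ConditionGrouping <- function(x, ...) {
  cat("ConditionGrouping:\n")
  for (g in names(x)) cat("  ", g, ": ", paste(x[[g]], collapse = ", "), "\n", sep = "")
  invisible(x)
}

# map condition labels to group names (NA = ungrouped/excluded)
assignGroups <- function(conditions, grouping) {
  out <- rep(NA_character_, length(conditions))
  for (g in names(grouping)) out[conditions %in% grouping[[g]]] <- g
  factor(out, levels = names(grouping))
}

#' Serialize / restore a condition grouping
#'
#' Analysis groupings can be saved to disk (YAML) and reloaded.
#'
#' @param grouping a `ConditionGrouping`.
#' @param path file path.
#' @return `readConditionGrouping` returns a `ConditionGrouping`.
#' @export
writeConditionGrouping <- function(grouping, path) {
  yaml::write_yaml(lapply(unclass(grouping), as.list), path)
  invisible(path)
}

#' @rdname writeConditionGrouping
#' @export
readConditionGrouping <- function(path) {
  raw <- yaml::read_yaml(path)
  conditionGrouping(lapply(raw, function(v) unlist(v, use.names = FALSE)))
}

#' Collapse a tensor over a time x frequency analysis window
#'
#' Averages the cells inside the window to a single value per trial.
#' Outlier trials are carried through but flagged.
#'
#' @param tensor a (typically baseline-transformed) [TrialTensor-class].
#' @param timeWindow `c(start, end)` seconds, half-open.
#' @param freqRange `c(low, high)` Hz, inclusive; `NULL` = all.
#' @return A `data.frame` with columns `trial_number`, `block`,
#'   `condition`, `is_outlier`, `value`; attribute `unit`.
#' @export
collapseWindow <- function(tensor, timeWindow, freqRange = NULL) {
  stopifnot(is(tensor, "TrialTensor"))
  ti <- which(inWindow(tensor@timeAxis, timeWindow))
  fi <- if (is.null(freqRange)) seq_along(tensor@frequencies) else
    which(tensor@frequencies >= freqRange[1] & tensor@frequencies <= freqRange[2])
  if (!length(ti) || !length(fi))
    stop("analysis window has empty intersection with the tensor axes")
  vals <- apply(tensor@power[, fi, ti, drop = FALSE], 1L, mean)
  out <- cbind(tensor@trialMeta, value = vals)
  attr(out, "unit") <- tensor@unit
  out
}

#' Power-over-time traces per condition group
#'
#' Collapses the frequency band, then returns mean +/- SEM across
#' non-outlier trials per group at each timepoint. Groups with zero trials
#' are dropped with a warning; a single-trial group has its SEM reported
#' as missing.
#'
#' @param tensor a [TrialTensor-class].
#' @param freqRange `c(low, high)` Hz; `NULL` = all frequencies.
#' @param grouping a `ConditionGrouping` (default: all conditions in one
#'   group).
#' @return A `data.frame` with columns `group`, `time`, `mean`, `sem`,
#'   `n_trials`.
#' @export
powerOverTime <- function(tensor, freqRange = NULL, grouping = NULL) {
  stopifnot(is(tensor, "TrialTensor"))
  if (is.null(grouping))
    grouping <- conditionGrouping(conditions = tensor@trialMeta$condition)
  fi <- if (is.null(freqRange)) seq_along(tensor@frequencies) else
    which(tensor@frequencies >= freqRange[1] & tensor@frequencies <= freqRange[2])
  if (!length(fi)) stop("freqRange selects no frequencies")
  tm <- apply(tensor@power[, fi, , drop = FALSE], c(1, 3), mean)  # trial x time
  grp <- assignGroups(tensor@trialMeta$condition, grouping)
  keep <- !tensor@trialMeta$is_outlier & !is.na(grp)
  out <- list()
  for (g in names(grouping)) {
    rows <- which(keep & grp == g)
    if (!length(rows)) {
      warning(sprintf("group '%s' has no usable trials and was dropped", g))
      next
    }
    sub <- tm[rows, , drop = FALSE]
    out[[g]] <- data.frame(
      group = g,
      time = tensor@timeAxis,
      mean = colMeans(sub),
      sem = if (nrow(sub) > 1L) apply(sub, 2L, stats::sd) / sqrt(nrow(sub)) else NA_real_,
      n_trials = nrow(sub),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Statistical contrast between condition groups
#'
#' One group: one-sample t-test of the per-trial values against zero,
#' with `beta` the group mean. Two groups: Welch two-sample t-test, with
#' `beta` the difference of group means (first minus second in grouping
#' order). More than two: one-way ANOVA omnibus plus per-group one-sample
#' tests against zero. Outlier-flagged trials are excluded throughout.
#'
#' @param values per-trial data.frame from [collapseWindow()].
#' @param grouping a `ConditionGrouping` (default: single group).
#' @return An object of class `ConditionContrast`: list with `groups`
#'   (per-group mean, sem, n, one-sample t and p), `test`, `statistic`,
#'   `df`, `p_value`, `beta`.
#' @export
conditionContrast <- function(values, grouping = NULL) {
  if (is.null(grouping))
    grouping <- conditionGrouping(conditions = values$condition)
  grp <- assignGroups(values$condition, grouping)
  keep <- !values$is_outlier & !is.na(grp)
  v <- values$value[keep]
  g <- droplevels(grp[keep])
  empty <- setdiff(names(grouping), levels(g))
  if (length(empty))
    stop("group(s) without usable trials: ", paste(empty, collapse = ", "))
  gstats <- do.call(rbind, lapply(levels(g), function(gl) {
    x <- v[g == gl]
    ts <- safeOneSampleT(x)
    data.frame(group = gl, mean = mean(x), sem = sem(x), n = length(x),
               t_vs0 = ts$t, p_vs0 = ts$p, stringsAsFactors = FALSE)
  }))
  nG <- nlevels(g)
  if (nG == 1L) {
    ts <- safeOneSampleT(v)
    res <- list(test = "one-sample t", statistic = ts$t, df = ts$df,
                p_value = ts$p, beta = mean(v))
  } else if (nG == 2L) {
    x1 <- v[g == levels(g)[1]]; x2 <- v[g == levels(g)[2]]
    ts <- safeWelchT(x1, x2)
    res <- list(test = "welch t", statistic = ts$t, df = ts$df,
                p_value = ts$p, beta = mean(x1) - mean(x2))
  } else {
    ft <- stats::oneway.test(v ~ g, var.equal = TRUE)
    res <- list(test = "anova F", statistic = unname(ft$statistic),
                df = unname(ft$parameter), p_value = ft$p.value,
                beta = NA_real_)
  }
  structure(c(list(groups = gstats), res), class = "ConditionContrast")
}

#' @export
print.ConditionContrast <- function(x, ...) {
  cat(sprintf("ConditionContrast [%s]: statistic = %.4g, p = %.4g, beta = %.4g\n",
              x$test, x$statistic, x$p_value, x$beta))
  print(x$groups, row.names = FALSE)
  invisible(x)
}

# t-tests that survive zero-variance input (identical values)
safeOneSampleT <- function(x) {
  if (length(x) < 2L) return(list(t = NA_real_, df = NA_real_, p = NA_real_))
  if (stats::sd(x) == 0) {
    if (mean(x) == 0) return(list(t = 0, df = length(x) - 1, p = 1))
    return(list(t = sign(mean(x)) * Inf, df = length(x) - 1, p = 0))
  }
  tt <- stats::t.test(x)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

safeWelchT <- function(x1, x2) {
  if (length(x1) < 2L || length(x2) < 2L)
    return(list(t = NA_real_, df = NA_real_, p = NA_real_))
  if (stats::sd(x1) == 0 && stats::sd(x2) == 0) {
    d <- mean(x1) - mean(x2)
    if (d == 0) return(list(t = 0, df = length(x1) + length(x2) - 2, p = 1))
    return(list(t = sign(d) * Inf, df = length(x1) + length(x2) - 2, p = 0))
  }
  tt <- stats::t.test(x1, x2)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' All-electrode statistics table with FDR correction
#'
#' Applies identical settings (baseline, windows, grouping) to every
#' electrode, runs [conditionContrast()] per electrode, and corrects the
#' p-values across electrodes by Benjamini-Hochberg within the contrast.
#' Per-electrode rows carry the raw beta, t (or F) statistic, p, FDR-
#' corrected p, per-group means/SEMs and trial counts, joined with the
#' electrode metadata when supplied.
#'
#' @param tensors named list of [TrialTensor-class] (names = electrode
#'   numbers), identical axes and unit.
#' @param grouping a `ConditionGrouping` (default: single group).
#' @param timeWindow,freqRange analysis window, as [collapseWindow()].
#' @param baselineWindow,baselineUnit,baselineMode optional baseline
#'   settings applied first when the tensors are still raw power.
#' @param electrodeTable optional electrode metadata to join.
#' @return A `data.frame` of class `ElectrodeStatsTable`.
#' @export
electrodeStatistics <- function(tensors, grouping = NULL, timeWindow,
                                freqRange = NULL, baselineWindow = NULL,
                                baselineUnit = "percent_power",
                                baselineMode = "per_trial",
                                electrodeTable = NULL) {
  if (!length(tensors)) stop("no tensors supplied")
  units <- unique(vapply(tensors, analysisUnit, character(1)))
  if (length(units) != 1L)
    stop("inconsistent units across electrodes: ", paste(units, collapse = ", "))
  ax <- lapply(tensors, function(t) list(t@timeAxis, t@frequencies))
  if (!all(vapply(ax, identical, logical(1), ax[[1]])))
    stop("inconsistent time/frequency axes across electrodes")
  rows <- lapply(tensors, function(tt) {
    if (!is.null(baselineWindow) && identical(tt@unit, "power"))
      tt <- baselineTransform(tt, baselineWindow, baselineUnit,
                              mode = baselineMode)
    vals <- collapseWindow(tt, timeWindow, freqRange)
    ct <- conditionContrast(vals, grouping)
    row <- data.frame(Electrode = tt@electrode, beta = ct$beta,
                      statistic = ct$statistic, test = ct$test,
                      p = ct$p_value, n_trials = sum(ct$groups$n),
                      stringsAsFactors = FALSE)
    for (i in seq_len(nrow(ct$groups))) {
      row[[paste0("mean_", ct$groups$group[i])]] <- ct$groups$mean[i]
      row[[paste0("sem_", ct$groups$group[i])]] <- ct$groups$sem[i]
    }
    row
  })
  tbl <- do.call(rbind, rows)
  rownames(tbl) <- NULL
  tbl$t <- ifelse(grepl("t$", tbl$test), tbl$statistic, NA_real_)
  tbl$p_fdr <- stats::p.adjust(tbl$p, method = "BH")
  if (!is.null(electrodeTable)) {
    electrodeTable <- validateElectrodeTable(electrodeTable)
    tbl <- merge(tbl, electrodeTable, by = "Electrode", all.x = TRUE,
                 sort = TRUE)
  }
  class(tbl) <- c("ElectrodeStatsTable", "data.frame")
  tbl
}

#' Flag or unflag outlier trials
#'
#' Outlier/artifact trials are flags on the trial metadata, never deleted:
#' all downstream statistics exclude flagged trials and the operation is
#' reversible.
#'
#' @param tensor a [TrialTensor-class].
#' @param trials trial numbers to (un)flag.
#' @param flag `TRUE` to mark as outlier, `FALSE` to clear.
#' @param block optional block id to disambiguate trial numbers.
#' @return The updated [TrialTensor-class].
#' @export
setTrialOutliers <- function(tensor, trials, flag = TRUE, block = NULL) {
  stopifnot(is(tensor, "TrialTensor"))
  meta <- tensor@trialMeta
  sel <- meta$trial_number %in% trials
  if (!is.null(block)) sel <- sel & meta$block %in% block
  found <- unique(meta$trial_number[sel])
  unknown <- setdiff(trials, found)
  if (length(unknown))
    stop("unknown trial id(s): ", paste(unknown, collapse = ", "))
  meta$is_outlier[sel] <- flag
  methods::initialize(tensor, trialMeta = meta)
}
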