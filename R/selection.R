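#' @include AllClasses.R
NULL

#' Define electrode selection criteria
#'
#' Up to three functional predicates (a statistic column from the
#' electrode stats table, a comparator, a threshold) and up to two
#' anatomical predicates (a metadata column and a set of accepted labels,
#' matched by exact string membership) may be combined; predicates combine
#' by conjunction.
#'
#' @param functional list of `list(stat =, op =, threshold =)` entries;
#'   `op` one of `">"`, `">="`, `"<"`, `"<="`.
#' @param anatomical list of `list(column =, labels =)` entries.
#' @return An object of class `SelectionCriteria`.
#' @examples
#' crit <- selectionCriteria(
#'   functional = list(list(stat = "p_fdr", op = "<", threshold = 0.01)),
#'   anatomical = list(list(column = "AnatomicalLabel",
#'                          labels = "superior temporal gyrus")))
#' @export
selectionCriteria <- function(functional = list(), anatomical = list()) {
  if (length(functional) > 3L)
    stop("at most 3 functional criteria are allowed (got ",
         length(functional), ")")
  if (length(anatomical) > 2L)
    stop("at most 2 anatomical criteria are allowed (got ",
         length(anatomical), ")")
  ops <- c(">", ">=", "<", "<=")
  for (f in functional) {
    if (!all(c("stat", "op", "threshold") %in% names(f)))
      stop("functional criteria need fields stat, op, threshold")
    if (!f$op %in% ops)
      stop("comparator must be one of: ", paste(ops, collapse = " "))
    assertScalarNumber(f$threshold, "threshold")
  }
  for (a in anatomical) {
    if (!all(c("column", "labels") %in% names(a)))
      stop("anatomical criteria need fields column, labels")
  }
  structure(list(functional = functional, anatomical = anatomical),
            class = "SelectionCriteria")
}

#' @export
print.SelectionCriteria <- function(x, ...) {
  cat("SelectionCriteria:\n")
  for (f in x$functional)
    cat(sprintf("  functional: %s %s %g\n", f$stat, f$op, f$threshold))
  for (a in x$anatomical)
    cat(sprintf("  anatomical: %s in {%s}\n", a$column,
                paste(a$labels, collapse = ", ")))
  if (!length(x$functional) && !length(x$anatomical)) cat("  (empty)\n")
  invisible(x)
}

evalPredicate <- function(stats, pred, kind) {
  col <- if (kind == "functional") pred$stat else pred$column
  if (!col %in% names(stats))
    stop("unknown column in criteria: ", col)
  v <- stats[[col]]
  if (kind == "functional") {
    if (!is.numeric(v)) stop("criteria column '", col, "' is not numeric")
    ok <- switch(pred$op,
                 ">" = v > pred$threshold, ">=" = v >= pred$threshold,
                 "<" = v < pred$threshold, "<=" = v <= pred$threshold)
  } else {
    ok <- v %in% pred$labels
  }
  ok & !is.na(ok)
}

#' Apply selection criteria to an electrode stats table
#'
#' The mask is TRUE for electrodes passing every predicate; the summary
#' reports the count passing each predicate alone and the joint count
#' (supporting filled/empty threshold displays). Empty criteria select
#' all electrodes (vacuous conjunction); zero electrodes passing is not
#' an error.
#'
#' @param stats an `ElectrodeStatsTable` (any data.frame with an
#'   `Electrode` column works).
#' @param criteria a `SelectionCriteria`.
#' @return list with `mask` (named logical vector by electrode number),
#'   `selected` (electrode numbers), `summary` (per-predicate counts).
#' @export
applySelection <- function(stats, criteria) {
  stopifnot(inherits(criteria, "SelectionCriteria"))
  n <- nrow(stats)
  mask <- rep(TRUE, n)
  summ <- list()
  for (f in criteria$functional) {
    ok <- evalPredicate(stats, f, "functional")
    mask <- mask & ok
    summ[[length(summ) + 1L]] <- data.frame(
      predicate = sprintf("%s %s %g", f$stat, f$op, f$threshold),
      kind = "functional", n_pass = sum(ok), stringsAsFactors = FALSE)
  }
  for (a in criteria$anatomical) {
    ok <- evalPredicate(stats, a, "anatomical")
    mask <- mask & ok
    summ[[length(summ) + 1L]] <- data.frame(
      predicate = sprintf("%s in {%s}", a$column,
                          paste(a$labels, collapse = ",")),
      kind = "anatomical", n_pass = sum(ok), stringsAsFactors = FALSE)
  }
  summ[[length(summ) + 1L]] <- data.frame(
    predicate = "joint", kind = "joint", n_pass = sum(mask),
    stringsAsFactors = FALSE)
  names(mask) <- as.character(stats$Electrode)
  list(mask = mask, selected = stats$Electrode[mask],
       summary = do.call(rbind, summ))
}

#' Electrode-versus-statistic threshold profile
#'
#' The data behind a per-electrode statistic plot with a threshold line:
#' each electrode's value of the chosen statistic and whether it passes
#' the current criteria (joint mask).
#'
#' @param stats an `ElectrodeStatsTable`.
#' @param statistic column name to profile.
#' @param criteria optional `SelectionCriteria`; without it every
#'   electrode passes.
#' @return A `data.frame` with columns `Electrode`, `value`, `pass`,
#'   ordered by electrode number.
#' @export
thresholdProfile <- function(stats, statistic, criteria = NULL) {
  if (!statistic %in% names(stats))
    stop("unknown statistic column: ", statistic)
  pass <- if (is.null(criteria)) rep(TRUE, nrow(stats)) else
    applySelection(stats, criteria)$mask
  out <- data.frame(Electrode = stats$Electrode,
                    value = stats[[statistic]],
                    pass = unname(pass))
  out[order(out$Electrode), , drop = FALSE]
}

#' Serialize / restore selection criteria
#'
#' @param criteria a `SelectionCriteria`.
#' @param path YAML file path.
#' @return `readSelectionCriteria` returns a `SelectionCriteria`.
#' @export
writeSelectionCriteria <- function(criteria, path) {
  yaml::write_yaml(unclass(criteria), path)
  invisible(path)
}

#' @rdname writeSelectionCriteria
#' @export
readSelectionCriteria <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$anatomical <- lapply(raw$anatomical, function(a) {
    a$labels <- unlist(a$labels); a
  })
  selectionCriteria(functional = raw$functional %||% list(),
                    anatomical = raw$anatomical %||% list())
}
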