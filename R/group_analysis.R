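#' @include AllClasses.R
NULL

validateGroupDataset <- function(data) {
  need <- c("Subject", "Electrode", "Trial", "Condition", "Power")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("group dataset lacks column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(data$Power))) stop("Power must be finite")
  if (!nrow(data)) stop("group dataset is empty")
  data$Subject <- factor(data$Subject)
  data$Condition <- factor(data$Condition)
  data$Electrode <- factor(data$Electrode)
  data
}

#' Fit the group-level linear mixed-effects model
#'
#' Default model: intercept-only fixed part with random intercepts for
#' subject and for electrode nested within subject —
#' `Power ~ 1 + (1|Subject/Electrode)` — fitted by REML, with
#' Satterthwaite approximate degrees of freedom for the fixed-effect
#' t-tests. Treating electrodes as a random effect nested in subjects
#' avoids the illusion of immense statistical power that comes from
#' pooling thousands of trials as if they were independent.
#'
#' @param data long-format data with columns `Subject`, `Electrode`,
#'   `Trial`, `Condition`, `Power` (one row per trial, `Power` the
#'   collapsed per-trial value in the chosen analysis unit).
#' @param fixed character vector of fixed effects (e.g. `"Condition"`),
#'   or `NULL` for intercept-only.
#' @param random random-effects specification in lme4 syntax. Default
#'   `"(1|Subject/Electrode)"`. Additional terms (e.g. a stimulus
#'   exemplar) may be appended, e.g.
#'   `"(1|Subject/Electrode) + (1|Exemplar)"`.
#' @param reml fit by REML (default) or ML.
#' @return An object of class `LMEResult`: list with `formula` (text),
#'   `fit` (the lmerTest model), `fixedEffects`, `randomEffects`,
#'   `omnibus`, `levelTests`, `pairwise`, `nGroups`.
#' @export
fitLME <- function(data, fixed = NULL, random = "(1|Subject/Electrode)",
                   reml = TRUE) {
  data <- validateGroupDataset(data)
  fixedPart <- if (is.null(fixed) || !length(fixed)) "1" else
    paste(fixed, collapse = " + ")
  formulaText <- paste0("Power ~ ", fixedPart, " + ", random)

  groupVars <- unique(unlist(strsplit(
    gsub("[()]|1\\s*\\|", "", unlist(regmatches(
      random, gregexpr("\\(1\\s*\\|[^)]+\\)", random)))), "[/:]")))
  groupVars <- trimws(groupVars)
  for (gv in groupVars) {
    if (!gv %in% names(data))
      stop("random grouping column not in data: ", gv)
    if (length(unique(data[[gv]])) < 2L)
      stop(sprintf(paste0(
        "grouping '%s' has a single level; random-effect estimation is ",
        "impossible - treat it as a fixed effect or add data"), gv))
  }
  for (fv in (fixed %||% character())) {
    if (!fv %in% names(data)) stop("fixed effect column not in data: ", fv)
    data[[fv]] <- factor(data[[fv]])
  }

  fit <- tryCatch(
    lmerTest::lmer(stats::as.formula(formulaText), data = data, REML = reml),
    error = function(e) stop("LME fit failed (", conditionMessage(e),
                             ") for model: ", formulaText, call. = FALSE)
  )
  conv <- fit@optinfo$conv$lme4
  if (!is.null(conv$code) && conv$code != 0)
    stop("LME did not converge: ", paste(unlist(conv$messages), collapse = "; "))

  cs <- as.data.frame(stats::coef(summary(fit)))
  fixedEffects <- data.frame(
    term = rownames(cs), estimate = cs[, "Estimate"],
    se = cs[, "Std. Error"], df = cs[, "df"], t = cs[, "t value"],
    p = cs[, "Pr(>|t|)"], row.names = NULL, stringsAsFactors = FALSE)

  vc <- as.data.frame(lme4::VarCorr(fit))
  vc <- vc[is.na(vc$var2), c("grp", "var1", "vcov", "sdcor")]
  ng <- lme4::ngrps(fit)
  randomEffects <- data.frame(
    grouping = vc$grp,
    n_levels = ifelse(vc$grp %in% names(ng), ng[vc$grp],
                      ifelse(vc$grp == "Residual", nrow(data), NA_integer_)),
    variance = vc$vcov, sd = vc$sdcor, row.names = NULL,
    stringsAsFactors = FALSE)

  hasFixed <- !is.null(fixed) && length(fixed) > 0L
  if (hasFixed) {
    an <- stats::anova(fit)   # lmerTest: Type III, Satterthwaite
    omnibus <- data.frame(
      term = rownames(an), F = an[, "F value"],
      df1 = an[, "NumDF"], df2 = an[, "DenDF"], p = an[, "Pr(>F)"],
      row.names = NULL, stringsAsFactors = FALSE)
    emm <- emmeans::emmeans(fit, stats::as.formula(paste0("~", fixed[1])),
                            lmer.df = "satterthwaite",
                            lmerTest.limit = 1e6)
    lt <- as.data.frame(emmeans::test(emm))
    levelTests <- data.frame(
      level = as.character(lt[[1]]), estimate = lt$emmean, se = lt$SE,
      df = lt$df, t = lt$t.ratio, p = lt$p.value, stringsAsFactors = FALSE)
    pw <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                          adjust = "none"))
    pairwise <- data.frame(
      contrast = as.character(pw$contrast), estimate = pw$estimate,
      se = pw$SE, df = pw$df, t = pw$t.ratio, p = pw$p.value,
      stringsAsFactors = FALSE)
    emmGrid <- emm
  } else {
    ## intercept-only: the omnibus is the intercept test itself
    omnibus <- data.frame(term = "(Intercept)",
                          F = fixedEffects$t[1]^2, df1 = 1,
                          df2 = fixedEffects$df[1], p = fixedEffects$p[1],
                          stringsAsFactors = FALSE)
    levelTests <- fixedEffects[, c("term", "estimate", "se", "df", "t", "p")]
    names(levelTests)[1] <- "level"
    pairwise <- data.frame(contrast = character(), estimate = numeric(),
                           se = numeric(), df = numeric(), t = numeric(),
                           p = numeric(), stringsAsFactors = FALSE)
    emmGrid <- NULL
  }
  structure(list(formula = formulaText, fit = fit,
                 fixedEffects = fixedEffects, randomEffects = randomEffects,
                 omnibus = omnibus, levelTests = levelTests,
                 pairwise = pairwise, emmGrid = emmGrid,
                 nGroups = if (hasFixed) nlevels(data[[fixed[1]]]) else 1L),
            class = "LMEResult")
}

#' @export
print.LMEResult <- function(x, ...) {
  cat("Linear mixed-effects model:", x$formula, "\n\nFixed effects:\n")
  print(x$fixedEffects, row.names = FALSE, digits = 4)
  cat("\nRandom effects:\n")
  print(x$randomEffects, row.names = FALSE, digits = 4)
  cat("\nOmnibus test:\n")
  print(x$omnibus, row.names = FALSE, digits = 4)
  if (nrow(x$pairwise)) {
    cat("\nPairwise contrasts (unadjusted):\n")
    print(x$pairwise, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Omnibus and pairwise contrast tables
#'
#' The omnibus joint test of the condition effects (equivalent to a main
#' effect of condition), each level tested against zero, and all
#' `C(levels, 2)` pairwise differences. Pairwise p-values are unadjusted
#' by default; `adjust` accepts any emmeans adjustment (e.g.
#' `"bonferroni"`, `"tukey"`).
#'
#' @param result an `LMEResult` from [fitLME()].
#' @param adjust p-value adjustment for the pairwise table.
#' @return list with `omnibus`, `levels`, `pairwise`.
#' @export
omnibusAndPairwise <- function(result, adjust = "none") {
  stopifnot(inherits(result, "LMEResult"))
  pairwise <- result$pairwise
  if (!is.null(result$emmGrid) && !identical(adjust, "none")) {
    pw <- as.data.frame(emmeans::contrast(result$emmGrid,
                                          method = "pairwise",
                                          adjust = adjust))
    pairwise <- data.frame(
      contrast = as.character(pw$contrast), estimate = pw$estimate,
      se = pw$SE, df = pw$df, t = pw$t.ratio, p = pw$p.value,
      stringsAsFactors = FALSE)
  }
  list(omnibus = result$omnibus, levels = result$levelTests,
       pairwise = pairwise)
}

#' Per-electrode univariate tests
#'
#' For each electrode in the group dataset, runs the same condition
#' contrast used in the single-subject analysis, yielding a table
#' sortable and searchable by any column.
#'
#' @param data a group dataset (see [fitLME()]).
#' @param grouping optional `ConditionGrouping`; default treats each
#'   condition label as its own group when 2+ conditions exist.
#' @param metadata optional per-electrode metadata to join (columns
#'   `Subject`, `Electrode`, ...).
#' @return A `data.frame`, one row per (Subject, Electrode).
#' @export
univariateByElectrode <- function(data, grouping = NULL, metadata = NULL) {
  data <- validateGroupDataset(data)
  if (is.null(grouping)) {
    conds <- levels(data$Condition)
    grouping <- conditionGrouping(stats::setNames(as.list(conds), conds))
  }
  keys <- unique(data[, c("Subject", "Electrode")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- data[data$Subject == keys$Subject[i] &
                  data$Electrode == keys$Electrode[i], , drop = FALSE]
    vals <- data.frame(trial_number = sub$Trial,
                       block = sub$Block %||% "1",
                       condition = as.character(sub$Condition),
                       is_outlier = FALSE, value = sub$Power,
                       stringsAsFactors = FALSE)
    ct <- conditionContrast(vals, grouping)
    row <- data.frame(Subject = as.character(keys$Subject[i]),
                      Electrode = as.character(keys$Electrode[i]),
                      test = ct$test, statistic = ct$statistic,
                      p = ct$p_value, beta = ct$beta, n_trials = sum(ct$groups$n),
                      stringsAsFactors = FALSE)
    for (j in seq_len(nrow(ct$groups)))
      row[[paste0("mean_", ct$groups$group[j])]] <- ct$groups$mean[j]
    row
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- stats::p.adjust(out$p, method = "BH")
  if (!is.null(metadata))
    out <- merge(out, metadata, by = intersect(c("Subject", "Electrode"),
                                               names(metadata)),
                 all.x = TRUE, sort = FALSE)
  rownames(out) <- NULL
  out
}

#' Sort / search helper for result tables
#'
#' @param table a data.frame.
#' @param by column to sort by.
#' @param decreasing sort order.
#' @param column,pattern for `searchTable`: column to search and substring
#'   pattern (fixed, case-insensitive).
#' @return The sorted / filtered data.frame. Sorting is stable with ties
#'   broken by electrode number when present.
#' @export
sortTable <- function(table, by, decreasing = FALSE) {
  if (!by %in% names(table)) stop("unknown column: ", by)
  tie <- if ("Electrode" %in% names(table))
    as.numeric(factor(table$Electrode)) else seq_len(nrow(table))
  ord <- order(table[[by]], tie, decreasing = c(decreasing, FALSE),
               method = "radix")
  table[ord, , drop = FALSE]
}

#' @rdname sortTable
#' @export
searchTable <- function(table, column, pattern) {
  if (!column %in% names(table)) stop("unknown column: ", column)
  table[grepl(pattern, table[[column]], fixed = TRUE) |
          grepl(pattern, table[[column]], ignore.case = TRUE),
        , drop = FALSE]
}

## ---- post-hoc x/y/z analyses -------------------------------------------

safeCalls <- c("+", "-", "*", "/", "^", "(", "log", "log2", "log10",
               "sqrt", "exp", "abs")

evalSafeExpression <- function(exprText, table) {
  expr <- tryCatch(str2lang(exprText),
                   error = function(e) stop("cannot parse expression: ",
                                            exprText, call. = FALSE))
  checkNode <- function(node) {
    if (is.call(node)) {
      fn <- as.character(node[[1]])
      if (!fn %in% safeCalls)
        stop("function '", fn, "' is not allowed in derived expressions ",
             "(arithmetic only)", call. = FALSE)
      lapply(as.list(node)[-1], checkNode)
    } else if (is.symbol(node)) {
      nm <- as.character(node)
      if (!nm %in% names(table))
        stop("expression references unknown column: ", nm, call. = FALSE)
      if (!is.numeric(table[[nm]]))
        stop("expression references non-numeric column: ", nm, call. = FALSE)
    } else if (!is.numeric(node)) {
      stop("only numbers, columns and arithmetic are allowed", call. = FALSE)
    }
    invisible(NULL)
  }
  checkNode(expr)
  eval(expr, envir = table, enclos = baseenv())
}

#' Post-hoc analysis of per-electrode variables
#'
#' Tests the relationship between two per-electrode variables with a
#' Pearson or Spearman correlation, or a paired t-test / Wilcoxon
#' signed-rank test of their differences. With a third variable `z`, both
#' `x` and `y` are first residualized on `z` by ordinary least squares
#' and the test applied to the residuals (partial correlation / partial
#' difference). New variables may be derived on the fly from a restricted
#' arithmetic expression over existing columns (e.g.
#' `"mean_A - mean_B"`).
#'
#' @param table per-electrode data.frame (e.g. an `ElectrodeStatsTable`).
#' @param x,y,z column names or derived-variable names; `z` optional.
#' @param test one of `"pearson"`, `"spearman"`, `"t_test"`,
#'   `"wilcoxon"`.
#' @param derived named list of expression strings defining new columns.
#' @return list with `test`, `statistic`, `p_value`, `estimate`, `n`,
#'   `partialled` and `points` (the per-electrode values used).
#' @export
posthocAnalysis <- function(table, x, y, z = NULL,
                            test = c("pearson", "spearman", "t_test",
                                     "wilcoxon"),
                            derived = NULL) {
  test <- match.arg(test)
  for (nm in names(derived))
    table[[nm]] <- evalSafeExpression(derived[[nm]], table)
  getNum <- function(col) {
    if (!col %in% names(table)) stop("unknown column: ", col)
    v <- table[[col]]
    if (!is.numeric(v)) stop("column '", col, "' is not numeric")
    v
  }
  xv <- getNum(x); yv <- getNum(y)
  zv <- if (!is.null(z)) getNum(z)
  ok <- is.finite(xv) & is.finite(yv) & (is.null(zv) | is.finite(zv %||% xv))
  xv <- xv[ok]; yv <- yv[ok]; if (!is.null(zv)) zv <- zv[ok]
  if (!is.null(zv)) {
    xv <- stats::resid(stats::lm(xv ~ zv))
    yv <- stats::resid(stats::lm(yv ~ zv))
  }
  res <- switch(test,
    pearson = {
      ct <- stats::cor.test(xv, yv, method = "pearson")
      list(statistic = unname(ct$statistic), p = ct$p.value,
           estimate = unname(ct$estimate))
    },
    spearman = {
      ct <- stats::cor.test(xv, yv, method = "spearman", exact = FALSE)
      list(statistic = unname(ct$statistic), p = ct$p.value,
           estimate = unname(ct$estimate))
    },
    t_test = {
      tt <- stats::t.test(xv, yv, paired = TRUE)
      list(statistic = unname(tt$statistic), p = tt$p.value,
           estimate = unname(tt$estimate))
    },
    wilcoxon = {
      wt <- stats::wilcox.test(xv, yv, paired = TRUE, exact = FALSE)
      list(statistic = unname(wt$statistic), p = wt$p.value,
           estimate = stats::median(xv - yv))
    })
  list(test = test, statistic = res$statistic, p_value = res$p,
       estimate = res$estimate, n = length(xv), partialled = !is.null(z),
       points = data.frame(x = xv, y = yv))
}

#' Group power-over-time traces with across-electrode variance
#'
#' Per condition: each electrode's trials are first averaged into a
#' per-electrode trace, then traces are averaged across electrodes, with
#' the SEM computed across electrodes (not trials). A single electrode
#' yields a missing SEM.
#'
#' @param long long table with columns `Subject`, `Electrode`,
#'   `Condition`, `Time`, `Power` (see [exportLongTable()]).
#' @return A `data.frame` with columns `condition`, `time`, `mean`,
#'   `sem`, `n_electrodes`.
#' @export
groupPowerOverTime <- function(long) {
  need <- c("Subject", "Electrode", "Condition", "Time", "Power")
  miss <- setdiff(need, names(long))
  if (length(miss)) stop("long table lacks column(s): ",
                         paste(miss, collapse = ", "))
  key <- interaction(long$Subject, long$Electrode, drop = TRUE)
  perElec <- stats::aggregate(
    Power ~ key + Condition + Time, data = cbind(long, key = key), FUN = mean)
  out <- do.call(rbind, lapply(split(perElec, perElec$Condition), function(d) {
    byTime <- split(d$Power, d$Time)
    data.frame(condition = d$Condition[1],
               time = as.numeric(names(byTime)),
               mean = vapply(byTime, mean, numeric(1)),
               sem = vapply(byTime, sem, numeric(1)),
               n_electrodes = vapply(byTime, length, numeric(1)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$condition, out$time), , drop = FALSE]
}
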