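`%||%` <- function(a, b) if (is.null(a)) b else a

# half-open window membership on a numeric axis: start inclusive, end exclusive
inWindow <- function(x, window) {
  stopifnot(length(window) == 2L)
  if (window[1] >= window[2]) stop("window start must be before window end")
  x >= window[1] & x < window[2]
}

sem <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

# near-integer check tolerant to floating division
isWholeNumber <- function(x, tol = 1e-8) abs(x - round(x)) < tol

assertScalarNumber <- function(x, name, positive = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be positive", name), call. = FALSE)
  invisible(x)
}
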