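#' @include AllClasses.R
NULL

#' Notch-filter line noise from a voltage block
#'
#' Zero-phase Butterworth band-stop filtering (order 2 per band, applied
#' forward and backward) at each line frequency. At every notch centre the
#' power spectral density is reduced by well over 20 dB while the passband
#' further than two half-bandwidths from a centre is attenuated by less
#' than 1 dB.
#'
#' @param block a [VoltageBlock-class].
#' @param lineFreqs notch centre frequencies in Hz. Default `c(60, 120,
#'   180)` (US mains fundamental plus harmonics).
#' @param halfBandwidths per-band half widths in Hz. Default `c(1, 2, 2)`.
#' @return A new, filtered [VoltageBlock-class].
#' @export
notchFilter <- function(block, lineFreqs = c(60, 120, 180),
                        halfBandwidths = c(1, 2, 2)) {
  stopifnot(is(block, "VoltageBlock"))
  if (length(halfBandwidths) == 1L)
    halfBandwidths <- rep(halfBandwidths, length(lineFreqs))
  stopifnot(length(lineFreqs) == length(halfBandwidths))
  nyq <- block@sampleRate / 2
  bad <- lineFreqs + halfBandwidths >= nyq
  if (any(bad))
    stop(sprintf("notch band(s) at/above Nyquist (%g Hz): %s", nyq,
                 paste(lineFreqs[bad], collapse = ", ")))
  x <- block@data
  for (i in seq_along(lineFreqs)) {
    w <- c(lineFreqs[i] - halfBandwidths[i], lineFreqs[i] + halfBandwidths[i]) / nyq
    bf <- signal::butter(2, w, type = "stop")
    for (ch in seq_len(nrow(x)))
      x[ch, ] <- signal::filtfilt(bf, x[ch, ])
  }
  VoltageBlock(block@blockId, x, block@sampleRate, block@channelNumbers)
}

## Welch-style segment-averaged periodogram (Hann window, 50% overlap).
## r-signal has no pwelch; this is the standard construction.
welchPsd <- function(x, rate, nSegments = 8) {
  n <- length(x)
  segLen <- max(16L, 2L^floor(log2(2 * n / (nSegments + 1))))
  segLen <- min(segLen, n)
  step <- max(1L, segLen %/% 2L)
  starts <- seq(1L, n - segLen + 1L, by = step)
  win <- 0.5 * (1 - cos(2 * pi * seq_len(segLen) / (segLen + 1)))
  u <- sum(win^2)
  acc <- numeric(segLen %/% 2L + 1L)
  for (s in starts) {
    seg <- x[s:(s + segLen - 1L)] * win
    p <- Mod(stats::fft(seg))^2 / (u * rate)
    acc <- acc + p[seq_len(segLen %/% 2L + 1L)]
  }
  psd <- acc / length(starts)
  freq <- (seq_len(segLen %/% 2L + 1L) - 1L) * rate / segLen
  data.frame(freq = freq, psd = psd)
}

#' Per-electrode data-quality analytics
#'
#' Computes, per electrode: a post-notch voltage summary, Welch-averaged
#' periodograms before and after notch filtering (returned once; linear-
#' and log10-frequency views are both derived from the same grid, the log10
#' view simply dropping DC), and a voltage histogram whose counts sum to
#' the sample count. Rendering is left to the caller; these are the
#' numeric analytics behind a per-electrode quality report.
#'
#' @param block a raw (pre-notch) [VoltageBlock-class].
#' @param lineFreqs,halfBandwidths notch settings, as [notchFilter()].
#' @param nBins number of histogram bins.
#' @return An object of class `QualityReport`: a list with one entry per
#'   electrode, each containing `voltage` (summary stats), `periodogramPre`,
#'   `periodogramPost`, `logFreqPre`, `logFreqPost` and `histogram`.
#' @export
qualityReport <- function(block, lineFreqs = c(60, 120, 180),
                          halfBandwidths = c(1, 2, 2), nBins = 50) {
  stopifnot(is(block, "VoltageBlock"))
  filtered <- notchFilter(block, lineFreqs, halfBandwidths)
  out <- lapply(seq_along(block@channelNumbers), function(i) {
    raw <- block@data[i, ]
    post <- filtered@data[i, ]
    pre.psd <- welchPsd(raw, block@sampleRate)
    post.psd <- welchPsd(post, block@sampleRate)
    h <- graphicsFreeHist(raw, nBins)
    list(
      electrode = block@channelNumbers[i],
      voltage = c(mean = mean(post), sd = stats::sd(post),
                  min = min(post), max = max(post)),
      periodogramPre = pre.psd,
      periodogramPost = post.psd,
      logFreqPre = data.frame(log10freq = log10(pre.psd$freq[-1]),
                              psd = pre.psd$psd[-1]),
      logFreqPost = data.frame(log10freq = log10(post.psd$freq[-1]),
                               psd = post.psd$psd[-1]),
      histogram = h
    )
  })
  names(out) <- as.character(block@channelNumbers)
  structure(list(blockId = block@blockId, electrodes = out,
                 notch = list(freqs = lineFreqs, halfBandwidths = halfBandwidths)),
            class = "QualityReport")
}

# histogram without graphics machinery; constant input gets one occupied bin
graphicsFreeHist <- function(x, nBins) {
  rng <- range(x)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = nBins + 1L)
  counts <- tabulate(pmin(nBins, pmax(1L, findInterval(x, breaks,
                                                       rightmost.closed = TRUE))),
                     nbins = nBins)
  list(breaks = breaks, counts = counts)
}

#' @export
print.QualityReport <- function(x, ...) {
  cat(sprintf("QualityReport for block '%s': %d electrode(s)\n",
              x$blockId, length(x$electrodes)))
  invisible(x)
}

#' Default wavelet centre frequencies
#'
#' Sixteen log-spaced frequencies chosen so that, with cycles interpolated
#' from 3 to 16, kernel durations `cycles / frequency` span 0.101 s at the
#' highest frequency to 1.433 s at the lowest (approximately 2.09 to
#' 158.4 Hz). The grid is fully overridable.
#'
#' @return Numeric vector of 16 frequencies in Hz.
#' @export
waveletDefaultFrequencies <- function() {
  exp(seq(log(3 / 1.433), log(16 / 0.101), length.out = 16))
}

#' Design a complex Morlet wavelet bank
#'
#' Kernel k is a complex exponential at `frequencies[k]` windowed by a
#' Gaussian envelope (standard deviation `duration/6`), truncated to
#' `duration = cycles[k] / frequencies[k]` seconds and normalized to unit
#' energy. Cycles are assigned by interpolating from `cycleRange[1]` at the
#' lowest frequency to `cycleRange[2]` at the highest, linearly in
#' log-frequency, so time resolution degrades gracefully towards low
#' frequencies. Defaults give 16 kernels with cycles from 3 to 16.
#'
#' @param frequencies centre frequencies in Hz (default
#'   [waveletDefaultFrequencies()]).
#' @param cycleRange `c(min, max)` cycles.
#' @param designRate sampling rate (Hz) of the data to be transformed.
#' @return A [WaveletBank-class].
#' @export
designWaveletBank <- function(frequencies = waveletDefaultFrequencies(),
                              cycleRange = c(3, 16), designRate) {
  assertScalarNumber(designRate, "designRate", positive = TRUE)
  frequencies <- sort(as.numeric(frequencies))
  if (any(frequencies <= 0)) stop("frequencies must be positive")
  if (any(frequencies >= designRate / 2))
    stop(sprintf("frequencies at/above Nyquist (%g Hz): %s", designRate / 2,
                 paste(frequencies[frequencies >= designRate / 2], collapse = ", ")))
  if (length(cycleRange) != 2L || any(cycleRange <= 0) ||
      cycleRange[1] > cycleRange[2])
    stop("cycleRange must be positive with min <= max")
  K <- length(frequencies)
  lf <- log(frequencies)
  frac <- if (K == 1L || diff(range(lf)) == 0) rep(0, K) else
    (lf - lf[1]) / (lf[K] - lf[1])
  cyc <- cycleRange[1] + frac * (cycleRange[2] - cycleRange[1])
  dur <- cyc / frequencies
  kern <- lapply(seq_len(K), function(k) {
    L <- 2L * floor(dur[k] * designRate / 2) + 1L   # odd, ~duration samples
    t <- (seq_len(L) - (L + 1L) / 2L) / designRate
    sdv <- dur[k] / 6
    w <- exp(-t^2 / (2 * sdv^2)) * exp(2i * pi * frequencies[k] * t)
    w / sqrt(sum(Mod(w)^2))
  })
  new("WaveletBank", frequencies = frequencies, cycles = cyc,
      durations = dur, kernels = kern, designRate = designRate)
}

#' Morlet wavelet transform of a voltage block
#'
#' Convolves each channel with each kernel of the bank (FFT convolution,
#' zero-padded edges, same-length centred output) producing one complex
#' [SpectralArray-class] per channel at the block's sampling rate. An edge
#' validity mask marks, per frequency, the half-kernel-duration stretch at
#' each end contaminated by zero padding.
#'
#' The transform is a linear operator: the coefficients of a sum of signals
#' equal the sum of the individual coefficients.
#'
#' @param block a [VoltageBlock-class].
#' @param bank a [WaveletBank-class] designed at the block's sampling rate.
#' @return Named list of [SpectralArray-class], names = electrode numbers.
#' @export
waveletTransform <- function(block, bank) {
  stopifnot(is(block, "VoltageBlock"), is(bank, "WaveletBank"))
  if (abs(block@sampleRate - bank@designRate) > 1e-9)
    stop(sprintf("bank designed at %g Hz but block sampled at %g Hz",
                 bank@designRate, block@sampleRate))
  n <- ncol(block@data)
  lens <- lengths(bank@kernels)
  m <- stats::nextn(n + max(lens) - 1L, 2)
  kernF <- lapply(bank@kernels, function(k)
    stats::fft(c(k, rep(0 + 0i, m - length(k)))))
  halves <- (lens - 1L) %/% 2L
  mask <- matrix(TRUE, length(bank@frequencies), n)
  for (k in seq_along(halves)) {
    h <- halves[k]
    if (h > 0 && 2 * h < n) mask[k, c(seq_len(h), (n - h + 1L):n)] <- FALSE
    else if (2 * h >= n) mask[k, ] <- FALSE
  }
  out <- lapply(seq_len(nrow(block@data)), function(ch) {
    xF <- stats::fft(c(block@data[ch, ], rep(0, m - n)))
    coef <- matrix(0 + 0i, length(bank@frequencies), n)
    for (k in seq_along(kernF)) {
      y <- stats::fft(xF * kernF[[k]], inverse = TRUE) / m
      coef[k, ] <- y[(halves[k] + 1L):(halves[k] + n)]
    }
    SpectralArray(block@channelNumbers[ch], coef, bank@frequencies,
                  block@sampleRate, reference = "none", validMask = mask)
  })
  names(out) <- as.character(block@channelNumbers)
  out
}

#' Downsample complex spectral coefficients
#'
#' Decimates the time axis by averaging each consecutive group of
#' `spectralRate / targetRate` complex samples (a linear operation on the
#' coefficients, so re-referencing commutes with it exactly). Trailing
#' samples that do not fill a whole group are dropped. The default target
#' of 100 Hz reduces disk space roughly tenfold for 1000 Hz recordings.
#'
#' @param spectral a [SpectralArray-class].
#' @param targetRate target rate in Hz; must divide `spectralRate`.
#' @return A downsampled [SpectralArray-class].
#' @export
downsampleSpectral <- function(spectral, targetRate = 100) {
  stopifnot(is(spectral, "SpectralArray"))
  assertScalarNumber(targetRate, "targetRate", positive = TRUE)
  ratio <- spectral@spectralRate / targetRate
  if (!isWholeNumber(ratio)) {
    divs <- spectral@spectralRate / seq_len(ceiling(ratio) + 1L)
    divs <- divs[isWholeNumber(divs)]
    near <- divs[order(abs(divs - targetRate))][seq_len(min(3L, length(divs)))]
    stop(sprintf("targetRate %g does not divide spectral rate %g; nearest valid rates: %s",
                 targetRate, spectral@spectralRate,
                 paste(signif(near, 6), collapse = ", ")))
  }
  f <- as.integer(round(ratio))
  if (f == 1L) return(spectral)
  Tn <- ncol(spectral@coefficients)
  T2 <- Tn %/% f
  if (T2 < 1L) stop("too few samples to downsample")
  idx0 <- seq.int(1L, T2 * f, by = f)
  coef <- spectral@coefficients[, idx0, drop = FALSE]
  mask <- spectral@validMask
  m2 <- if (is.null(mask)) NULL else mask[, idx0, drop = FALSE]
  for (i in seq_len(f - 1L)) {
    coef <- coef + spectral@coefficients[, idx0 + i, drop = FALSE]
    if (!is.null(m2)) m2 <- m2 & mask[, idx0 + i, drop = FALSE]
  }
  SpectralArray(spectral@electrode, coef / f, spectral@frequencies,
                targetRate, spectral@reference, m2)
}
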