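test_that("notch filter removes line components and spares the passband", {
  rate <- 1000
  t <- (0:19999) / rate
  x <- sin(2 * pi * 10 * t) + sin(2 * pi * 60 * t)
  blk <- VoltageBlock("b", matrix(x, 1), rate, 1L)
  out <- notchFilter(blk, 60, 1)
  ## FFT oracle on the filtered output (interior, away from filter edges)
  idx <- 2001:18000
  amp <- function(v, f) {
    n <- length(v)
    2 * Mod(sum(v * exp(-2i * pi * f * (seq_len(n) - 1) / rate))) / n
  }
  y <- voltageData(out)[1, idx]
  expect_lt(amp(y, 60), 0.01)                       # >= 99% amplitude removed
  expect_equal(amp(y, 10), 1, tolerance = 0.01)     # 10 Hz within 1%

  ## pure DC passes unchanged (interior; zero-phase filtering leaves a
  ## small decaying transient at the block edges)
  dc <- VoltageBlock("b", matrix(rep(2.5, 4000), 1), rate, 1L)
  dcOut <- voltageData(notchFilter(dc, 60, 1))[1, 1001:3000]
  expect_equal(dcOut, rep(2.5, 2000), tolerance = 1e-3)

  expect_error(notchFilter(blk, 600, 1), "Nyquist")
})

test_that("quality report analytics behave on known inputs", {
  rate <- 500
  set.seed(11)
  n <- 8192
  white <- rnorm(n)
  contaminated <- white + 4 * sin(2 * pi * 60 * (0:(n - 1)) / rate)
  blk <- VoltageBlock("b", rbind(white, contaminated, rep(1, n)), rate, 1:3)
  qr <- qualityReport(blk, 60, 1, nBins = 30)

  ## white noise: log-power vs log-frequency slope ~ 0
  pg <- qr$electrodes[["1"]]$periodogramPost
  sel <- pg$freq > 5 & pg$freq < 200
  fit <- lm(log10(pg$psd[sel]) ~ log10(pg$freq[sel]))
  expect_lt(abs(coef(fit)[2]), 0.15)

  ## 60 Hz peak present pre-notch, gone post-notch
  pre <- qr$electrodes[["2"]]$periodogramPre
  post <- qr$electrodes[["2"]]$periodogramPost
  at60 <- which.min(abs(pre$freq - 60))
  near <- abs(pre$freq - 60) > 5 & abs(pre$freq - 60) < 20
  expect_gt(pre$psd[at60] / median(pre$psd[near]), 50)
  expect_lt(post$psd[at60] / median(post$psd[near]), 5)

  ## constant channel: one occupied histogram bin, counts sum to n
  h <- qr$electrodes[["3"]]$histogram
  expect_equal(sum(h$counts > 0), 1L)
  expect_equal(sum(h$counts), n)
  expect_equal(sum(qr$electrodes[["1"]]$histogram$counts), n)
})

test_that("default wavelet bank matches the printed configuration", {
  bank <- designWaveletBank(designRate = 1000)
  expect_length(frequencies(bank), 16L)
  expect_equal(min(cycles(bank)), 3)
  expect_equal(max(cycles(bank)), 16)
  expect_equal(durations(bank), cycles(bank) / frequencies(bank))
  expect_equal(range(durations(bank)), c(0.101, 1.433), tolerance = 1e-10)
  ## unit energy
  for (k in kernels(bank))
    expect_equal(sum(Mod(k)^2), 1, tolerance = 1e-9)
})

test_that("wavelet bank edge cases: single frequency, constant cycles, Nyquist", {
  one <- designWaveletBank(10, c(5, 5), designRate = 1000)
  expect_equal(durations(one), 0.5)     # 5 cycles / 10 Hz

  two <- designWaveletBank(c(8, 32), c(3, 3), designRate = 1000)
  expect_equal(cycles(two), c(3, 3))

  expect_error(designWaveletBank(c(10, 600), c(3, 16), designRate = 1000),
               "Nyquist")
})

test_that("wavelet transform localizes sinusoids and is linear", {
  rate <- 1000
  bank <- designWaveletBank(designRate = rate)
  n <- 8000
  t <- (0:(n - 1)) / rate
  f0idx <- 11
  f0 <- frequencies(bank)[f0idx]
  blk <- VoltageBlock("b", matrix(sin(2 * pi * f0 * t), 1), rate, 1L)
  sa <- waveletTransform(blk, bank)[[1]]
  interior <- 2000:6000
  pw <- rowMeans(Mod(spectralCoefs(sa)[, interior])^2)
  expect_equal(which.max(pw), f0idx)

  ## stationary sinusoid: interior power constant within 5% CV
  p0 <- Mod(spectralCoefs(sa)[f0idx, interior])^2
  expect_lt(sd(p0) / mean(p0), 0.05)

  ## all-zero channel -> all-zero coefficients
  z <- waveletTransform(VoltageBlock("b", matrix(0, 1, 2000), rate, 1L),
                        bank)[[1]]
  expect_equal(max(Mod(spectralCoefs(z))), 0)

  ## linearity: T(alpha a + beta b) = alpha T(a) + beta T(b)
  set.seed(5)
  a <- rnorm(3000); b <- rnorm(3000); al <- 1.7; be <- -0.4
  Ta <- spectralCoefs(waveletTransform(
    VoltageBlock("b", matrix(a, 1), rate, 1L), bank)[[1]])
  Tb <- spectralCoefs(waveletTransform(
    VoltageBlock("b", matrix(b, 1), rate, 1L), bank)[[1]])
  Tab <- spectralCoefs(waveletTransform(
    VoltageBlock("b", matrix(al * a + be * b, 1), rate, 1L), bank)[[1]])
  relErr <- max(Mod(Tab - (al * Ta + be * Tb))) / max(Mod(Tab))
  expect_lt(relErr, 1e-10)

  ## rate mismatch
  expect_error(waveletTransform(VoltageBlock("b", matrix(a, 1), 500, 1L),
                                bank), "designed at")
})

test_that("spectral downsampling averages complex groups and is linear", {
  set.seed(6)
  co <- matrix(complex(real = rnorm(2 * 1000), imaginary = rnorm(2 * 1000)), 2)
  sa <- SpectralArray(1L, co, c(10, 20), 1000)
  ds <- downsampleSpectral(sa, 100)
  expect_equal(dim(spectralCoefs(ds)), c(2L, 100L))
  expect_equal(spectralRate(ds), 100)
  ## first output sample = mean of first 10 inputs
  expect_equal(spectralCoefs(ds)[1, 1], mean(co[1, 1:10]), tolerance = 1e-12)

  ## identity when target equals current rate
  expect_identical(downsampleSpectral(sa, 1000), sa)

  ## linearity to 1e-12
  co2 <- matrix(complex(real = rnorm(2000), imaginary = rnorm(2000)), 2)
  sb <- SpectralArray(1L, co2, c(10, 20), 1000)
  sab <- SpectralArray(1L, co + co2, c(10, 20), 1000)
  lhs <- spectralCoefs(downsampleSpectral(sab, 100))
  rhs <- spectralCoefs(downsampleSpectral(sa, 100)) +
    spectralCoefs(downsampleSpectral(sb, 100))
  expect_lt(max(Mod(lhs - rhs)), 1e-12)

  ## non-divisor target suggests valid rates
  expect_error(downsampleSpectral(sa, 300), "nearest valid rates")
})
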