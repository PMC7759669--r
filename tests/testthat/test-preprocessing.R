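test_that("band-pass filter passes the band and rejects outside it", {
  fs <- 250
  t <- seq(0, 8, by = 1 / fs)

  # DC sits in the stop band of a 4-38 Hz filter
  dc <- matrix(1, 1, length(t))
  out <- bandpassFilter(dc, fs, 4, 38)
  expect_lt(max(abs(out[, 200:(length(t) - 200)])), 1e-3)

  # 10 Hz rides through nearly unattenuated
  x10 <- sin(2 * pi * 10 * t)
  y10 <- bandpassFilter(x10, fs, 4, 38)
  ratio <- fftPeakAmplitude(y10, fs, 10) / fftPeakAmplitude(x10, fs, 10)
  expect_gt(ratio, 0.9)
  expect_lt(ratio, 1.1)

  # 80 Hz is crushed by the 38 Hz low-pass
  x80 <- sin(2 * pi * 80 * t)
  y80 <- bandpassFilter(x80, fs, 0, 38)
  expect_lt(fftPeakAmplitude(y80, fs, 80) / fftPeakAmplitude(x80, fs, 80), 0.1)
})

test_that("filter rejects invalid configurations and data", {
  x <- matrix(rnorm(500), 2, 250)
  expect_error(bandpassFilter(x, 250, 4, 130), "Nyquist")
  expect_error(bandpassFilter(x, 250, 40, 38), "invalid band")
  x[1, 5] <- NA
  expect_error(bandpassFilter(x, 250, 4, 38), "non-finite")
})

test_that("filtering is applied per channel independently", {
  fs <- 250
  t <- seq(0, 4, by = 1 / fs)
  x <- rbind(sin(2 * pi * 10 * t), sin(2 * pi * 80 * t))
  y <- bandpassFilter(x, fs, 4, 38)
  expect_equal(y[1, ], bandpassFilter(x[1, ], fs, 4, 38))
  expect_equal(y[2, ], bandpassFilter(x[2, ], fs, 4, 38))
})

test_that("exponential moving standardization matches the explicit recursion", {
  set.seed(4)
  x <- rnorm(50)
  decay <- 0.999; epsVar <- 1e-4
  # sample-by-sample recursion, scripted independently
  m <- x[1]; v <- 0; ref <- numeric(50)
  for (t in 2:50) {
    m <- decay * m + (1 - decay) * x[t]
    d <- x[t] - m
    v <- decay * v + (1 - decay) * d^2
    ref[t] <- d / max(sqrt(v), sqrt(epsVar))
  }
  out <- exponentialMovingStandardize(x, decay, epsVar)
  expect_lt(max(abs(out - ref)), 1e-10)
})

test_that("standardizing a constant signal yields zero", {
  out <- exponentialMovingStandardize(matrix(3.7, 2, 200))
  expect_equal(max(abs(out)), 0)
})

test_that("standardized white noise has unit variance after burn-in", {
  set.seed(9)
  x <- rnorm(50000)
  out <- exponentialMovingStandardize(x, 0.999, 1e-4)
  v <- var(out[25001:50000])
  expect_gt(v, 0.8)
  expect_lt(v, 1.2)
})

test_that("standardization is invariant to constant input shifts", {
  set.seed(10)
  x <- matrix(rnorm(2 * 1000), 2)
  a <- exponentialMovingStandardize(x)
  b <- exponentialMovingStandardize(x + 5)
  burn <- 201:1000   # last 80%
  expect_lt(max(abs(a[, burn] - b[, burn])), 1e-6)
})

test_that("standardizer rejects empty and bad inputs", {
  expect_error(exponentialMovingStandardize(matrix(0, 2, 0)), "empty")
  expect_error(exponentialMovingStandardize(rnorm(10), decay = 1.2), "decay")
  expect_error(exponentialMovingStandardize(rnorm(10), epsVar = 0), "epsVar")
})

test_that("resampling halves 500 Hz to 250 Hz with the expected length", {
  set.seed(2)
  x <- matrix(rnorm(44 * 2250), 44, 2250)
  y <- resampleSignal(x, 500, 250)
  expect_identical(dim(y), c(44L, 1125L))
})

test_that("resampling at the same rate is the identity", {
  x <- matrix(rnorm(100), 2)
  expect_identical(resampleSignal(x, 250, 250), x)
})

test_that("resampling preserves the spectral peak location", {
  fs <- 500
  t <- seq(0, 6, by = 1 / fs)
  x <- sin(2 * pi * 10 * t)
  y <- resampleSignal(x, 500, 250)
  amp <- 2 * abs(fft(y))[seq_len(length(y) %/% 2)] / length(y)
  f <- (seq_len(length(y) %/% 2) - 1) * 250 / length(y)
  expect_lt(abs(f[which.max(amp)] - 10), 0.5)
  expect_error(resampleSignal(x, 500, Inf), "finite")
})

test_that("epoch extraction uses the half-open cue-aligned window", {
  fs <- 250
  n <- 5000
  H <- 3
  sig <- matrix(rep(seq_len(n), each = H), H)   # ramp: value = sample index
  cues <- c(400, 1800, 3200)
  rec <- eegRecording(sig, fs, events = data.frame(sample = cues,
                                                   label = c("a", "b", "a")))
  eps <- extractEpochs(rec, c(-0.5, 4))
  expect_identical(dim(epochArray(eps)), c(3L, 1125L, 3L))
  # first sample of each epoch is the ramp value at cue - 125
  for (i in 1:3) expect_equal(epochArray(eps)[1, 1, i], cues[i] - 125)
  expect_identical(as.character(epochLabels(eps)), c("a", "b", "a"))
})

test_that("epoching a recording with no events yields an empty container", {
  rec <- eegRecording(matrix(rnorm(3 * 2000), 3), 250)
  eps <- extractEpochs(rec, c(-0.5, 4))
  expect_identical(nEpochs(eps), 0L)
})

test_that("out-of-bounds event windows are skipped with a warning", {
  rec <- eegRecording(matrix(rnorm(2 * 2000), 2), 250,
                      events = data.frame(sample = c(50, 800), label = c("x", "y")))
  expect_warning(eps <- extractEpochs(rec, c(-0.5, 4)), "skipped")
  expect_identical(nEpochs(eps), 1L)
  expect_identical(as.character(epochLabels(eps)), "y")
})

test_that("filtering and epoching commute in the steady state", {
  fs <- 250
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  sig <- rbind(sin(2 * pi * 10 * t), sin(2 * pi * 22 * t) + 0.5 * sin(2 * pi * 9 * t))
  events <- data.frame(sample = c(2000, 3200), label = c("a", "b"))
  filtThenEpoch <- extractEpochs(
    eegRecording(bandpassFilter(sig, fs, 4, 38), fs, events = events), c(-0.5, 4))
  epochThenFilt <- extractEpochs(eegRecording(sig, fs, events = events), c(-0.5, 4))
  for (i in 1:2) {
    a <- epochArray(filtThenEpoch)[, , i]
    b <- bandpassFilter(epochArray(epochThenFilt)[, , i], fs, 4, 38)
    # compare away from the epoch-level zero-phase filter transients, which
    # decay below 1e-6 roughly 400 samples in from either edge
    expect_lt(max(abs(a - b)[, 450:700]), 1e-6)
  }
})

test_that("the pipeline equals the manual filter -> standardize -> epoch chain", {
  set.seed(6)
  fs <- 250
  sig <- matrix(rnorm(4 * 4000), 4)
  events <- data.frame(sample = c(600, 2200), label = c("l", "r"))
  rec <- eegRecording(sig, fs, events = events)
  cfg <- preprocessConfig(lowCut = 0, highCut = 38, window = c(-0.5, 4))
  auto <- preprocessRecording(rec, cfg)
  manual <- extractEpochs(
    eegRecording(exponentialMovingStandardize(bandpassFilter(sig, fs, 0, 38),
                                              cfg@decay, cfg@epsVar),
                 fs, events = events), cfg@window)
  expect_identical(epochArray(auto), epochArray(manual))
})

test_that("pipeline resamples before filtering when targetFs is set", {
  set.seed(8)
  sig <- matrix(rnorm(2 * 9000), 2)
  rec <- eegRecording(sig, 500, events = data.frame(sample = 4000, label = "a"))
  eps <- preprocessRecording(rec, preprocessConfig(targetFs = 250))
  expect_identical(dim(epochArray(eps))[1:2], c(2L, 1125L))
  expect_equal(samplingRate(eps), 250)
})
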