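test_that("epoch geometry and determinism hold", {
  spec <- smallSpec()
  set.seed(1)
  M <- generateEpoch(spec, "left_hand")
  expect_identical(dim(M), c(8L, 250L))
  expect_error(generateEpoch(spec, "jumping"), "unknown class")

  ds <- generateDataset(spec, 5, seed = 2)
  expect_identical(nEpochs(ds), 20L)
  expect_true(all(table(epochLabels(ds)) == 5))
  expect_identical(epochArray(generateDataset(spec, 5, seed = 2)), epochArray(ds))
  expect_false(identical(epochArray(generateDataset(spec, 5, seed = 3)),
                         epochArray(ds)))
})

test_that("classes with identical factors are statistically indistinguishable", {
  spec <- syntheticSpec(nChannels = 4, fs = 125, epochLengthS = 2,
                        classes = list(a = list(), b = list()))
  ds <- generateDataset(spec, 100, seed = 4)   # 200 epochs
  X <- epochArray(ds)
  pw <- vapply(seq_len(nEpochs(ds)),
               function(i) welchBandPower(X[2, , i], 125, c(8, 12)), 1)
  labs <- as.character(epochLabels(ds))
  expect_gt(t.test(pw[labs == "a"], pw[labs == "b"])$p.value, 0.01)
})

test_that("band-power ratio between ERS and ERD classes matches the PSD oracle", {
  fs <- 125; len <- 2; nCh <- 4; ch <- 3
  spec <- syntheticSpec(
    nChannels = nCh, fs = fs, epochLengthS = len,
    classes = list(
      ers = list(list(band = "mu", channels = ch, factor = 2.0)),
      erd = list(list(band = "mu", channels = ch, factor = 0.5))))
  ds <- generateDataset(spec, 100, seed = 5)   # 200 epochs
  X <- epochArray(ds); labs <- as.character(epochLabels(ds))
  pw <- vapply(seq_len(nEpochs(ds)),
               function(i) welchBandPower(X[ch, , i], fs, c(8, 12)), 1)
  measured <- mean(pw[labs == "ers"]) / mean(pw[labs == "erd"])

  # analytic oracle: the ratio of total 8-12 Hz power, with the oscillation
  # (unit variance, scaled by amplitude * factor) diluted by the in-band share
  # of the 1/f background and of the white noise
  n <- fs * len
  k <- seq_len(n %/% 2)
  f <- k * fs / n
  bgShare <- sum(1 / f[f >= 8 & f <= 12]) / sum(1 / f)    # 1/f spectral weights
  p0 <- spec@bgScale^2 * bgShare + spec@noiseSd^2 * (12 - 8) / (fs / 2)
  posc <- spec@oscAmplitude[["mu"]]^2
  expected <- (p0 + 4 * posc) / (p0 + 0.25 * posc)
  expect_gt(measured / expected, 0.65)
  expect_lt(measured / expected, 1.45)
  # the dilution keeps the ratio between the chance value 1 and the pure
  # squared-amplitude ratio 16, well clear of 1
  expect_gt(measured, 2.5)
  expect_lt(measured, 16)
})

test_that("a linear band-power decoder clears the 25% chance floor", {
  spec <- smallSpec()
  tr <- generateDataset(spec, 20, seed = 6)
  te <- generateDataset(spec, 10, seed = 7)
  bl <- bandPowerBaseline(tr, te)
  expect_gt(bl$accuracy, 25)
})

test_that("welch PSD concentrates power of a sinusoid at its frequency", {
  fs <- 125
  x <- sin(2 * pi * 10 * seq(0, 4, by = 1 / fs))
  w <- welchPsd(x, fs)
  expect_lt(abs(w$freq[which.max(w$psd)] - 10), 1)
  # Parseval-style sanity: band power around the peak carries most variance
  expect_gt(welchBandPower(x, fs, c(8, 12)), 0.3)
})

test_that("spatial attention is not worse than the frozen baseline when only
           two non-motor channels carry class information", {
  # class structure confined to channels 7 and 8; every other channel is noise
  mods <- function(chs) lapply(chs, function(ch)
    list(band = "mu", channels = ch, factor = 0.35))
  spec <- syntheticSpec(nChannels = 8, fs = 125, epochLengthS = 2,
                        classes = list(c1 = mods(7), c2 = mods(8),
                                       c3 = mods(c(7, 8)), c4 = list()))
  tr <- generateDataset(spec, 30, seed = 31)
  te <- generateDataset(spec, 15, seed = 32)
  tc <- trainConfig(lr = 1e-3, batchSize = 16, patience = 3,
                    maxEpochsPhase1 = 12, maxEpochsPhase2 = 4, seed = 5)
  fitAtt <- fitTwoPhase(stsaModel(smallConfig()), tr, tc)
  fitFrz <- fitTwoPhase(stsaModel(smallConfig()), tr, tc, freezeLambdas = TRUE)
  expect_identical(fitFrz@model@params$lam1, 0)
  accAtt <- accuracy(epochLabels(te), predict(fitAtt@model, te))
  accFrz <- accuracy(epochLabels(te), predict(fitFrz@model, te))
  expect_gte(accAtt, accFrz)
})
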