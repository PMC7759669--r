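# shared fixtures: everything is generated in code at test time

# small architecture that keeps the kernel chain valid (250 - 25 + 1 = 226,
# pooling (226 - 75)/15 + 1 = 11)
smallConfig <- function(...) {
  modelConfig(nChannels = 8, nSamples = 250, attMaps = 3, headMaps = 10, ...)
}

smallSpec <- function(...) {
  syntheticSpec(nChannels = 8, fs = 125, epochLengthS = 2, ...)
}

randomAttentionParams <- function(nMaps, lam = 0.5, seed = 1) {
  set.seed(seed)
  attentionParams(nMaps, w1 = rnorm(nMaps), b1 = rnorm(nMaps, sd = 0.3),
                  w2 = rnorm(nMaps), b2 = rnorm(nMaps, sd = 0.3), lam = lam)
}

# model params made non-trivial (nonzero lambdas/biases, random BN statistics)
# so equivalence tests exercise every code path
randomizedModelParams <- function(model, seed = 1) {
  set.seed(seed)
  p <- model@params
  Fn <- length(p$sw1); K <- length(p$gamma)
  p$lam1 <- rnorm(1, sd = 0.3); p$lam2 <- rnorm(1, sd = 0.3)
  p$sb1 <- rnorm(Fn, sd = 0.2); p$sb2 <- rnorm(Fn, sd = 0.2)
  p$tb1 <- rnorm(Fn, sd = 0.2); p$tb2 <- rnorm(Fn, sd = 0.2)
  p$b2 <- rnorm(K, sd = 0.1); p$beta <- rnorm(K, sd = 0.1)
  p$gamma <- runif(K, 0.5, 1.5)
  p$bn_rmean <- rnorm(K, sd = 0.3); p$bn_rvar <- runif(K, 0.5, 2)
  model@params <- p
  model
}

# scalar double-loop expansion of the attention equations: the score between
# elements i and j is the dot product of the concatenated F-map projections,
# then row softmax, then the weighted sum of the raw signal
oracleAttention <- function(M, params, type = c("spatial", "temporal")) {
  type <- match.arg(type)
  H <- nrow(M); W <- ncol(M); Fn <- length(params$w1)
  n <- if (type == "spatial") H else W
  sc <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- 0
    for (f in seq_len(Fn)) {
      if (type == "spatial") {
        for (w in seq_len(W))
          s <- s + (params$w1[f] * M[i, w] + params$b1[f]) *
                   (params$w2[f] * M[j, w] + params$b2[f])
      } else {
        for (c in seq_len(H))
          s <- s + (params$w1[f] * M[c, i] + params$b1[f]) *
                   (params$w2[f] * M[c, j] + params$b2[f])
      }
    }
    sc[i, j] <- s
  }
  map <- exp(sc - apply(sc, 1, max))
  map <- map / rowSums(map)
  pred <- if (type == "spatial") map %*% M else M %*% t(map)
  list(scores = sc, map = map, predicted = pred,
       feature = params$lam * pred + M)
}

# FFT amplitude of the dominant spectral peak near a target frequency
fftPeakAmplitude <- function(x, fs, freq, halfWidth = 2) {
  n <- length(x)
  amp <- 2 * abs(fft(x))[seq_len(n %/% 2)] / n
  f <- (seq_len(n %/% 2) - 1) * fs / n
  max(amp[abs(f - freq) <= halfWidth])
}

expect_exit_code <- function(expr, code) {
  got <- withVisible(expr)$value
  expect_identical(as.integer(got), as.integer(code))
}
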