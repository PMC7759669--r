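test_that("feature stacking fixes the (M, S, T) order", {
  set.seed(1)
  M <- matrix(rnorm(12), 3); S <- matrix(rnorm(12), 3); T <- matrix(rnorm(12), 3)
  C1 <- concatFeatures(M, S, T)
  expect_identical(dim(C1), c(3L, 3L, 4L))
  expect_identical(matrix(C1[1, , ], 3), M)
  expect_identical(matrix(C1[2, , ], 3), S)
  expect_identical(matrix(C1[3, , ], 3), T)
  expect_error(concatFeatures(M, S, matrix(0, 2, 2)), "dimensions")
})

test_that("the shape trace reproduces every tabulated dimension", {
  tr <- shapeTrace(modelConfig())
  want <- c(s21 = "(22, 9000)", s22 = "(9000, 22)", s3 = "(22, 22)",
            s4 = "(22, 1125)", t21 = "(1125, 176)", t22 = "(176, 1125)",
            t3 = "(1125, 1125)", t4 = "(22, 1125)", C1 = "(3, 22, 1125)",
            C2 = "(40, 22, 1101)", C3 = "(40, 1, 1101)", avgPool = "(40, 1, 69)",
            C5 = "(4, 1, 1)")
  for (st in names(want))
    expect_identical(tr$output[tr$stage == st], unname(want[st]))
})

test_that("pooling arithmetic comes from the built model, not a constant", {
  cfg <- modelConfig()
  expect_identical(stsaEEG:::poolOutWidth(cfg),
                   (1125L - 25L + 1L - 75L) %/% 15L + 1L)
  cfg2 <- modelConfig(nSamples = 600, poolKernel = 50, poolStride = 10)
  expect_identical(stsaEEG:::poolOutWidth(cfg2), (600L - 25L + 1L - 50L) %/% 10L + 1L)
  expect_error(modelConfig(nSamples = 90), "pooling")
})

test_that("forward pass intermediates match the trace on a small model", {
  cfg <- smallConfig()
  m <- randomizedModelParams(initParameters(stsaModel(cfg), seed = 2), seed = 3)
  set.seed(4)
  M <- matrix(rnorm(8 * 250), 8)
  out <- modelForward(m, M)
  expect_identical(dim(out$C1), c(3L, 8L, 250L))
  expect_identical(dim(out$C2), c(10L, 8L, 226L))
  expect_identical(dim(out$C3), c(10L, 226L))
  # pooling width from the kernel arithmetic: (226 - 75) %/% 15 + 1
  expect_identical(dim(out$C4), c(10L, (226L - 75L) %/% 15L + 1L))
  expect_length(out$C5, 4L)
})

test_that("log-softmax output normalizes over random epochs", {
  cfg <- smallConfig()
  m <- randomizedModelParams(initParameters(stsaModel(cfg), seed = 5), seed = 6)
  set.seed(7)
  X <- array(rnorm(8 * 250 * 100), c(8, 250, 100))
  logp <- forwardLogProb(m, X)
  expect_lt(max(abs(rowSums(exp(logp)) - 1)), 1e-5)
  expect_true(all(logp <= 0))
})

test_that("with frozen lambdas the model equals the head on {M, M, M}", {
  cfg <- smallConfig()
  m <- initParameters(stsaModel(cfg), seed = 8)   # lam1 = lam2 = 0 at init
  set.seed(9)
  M <- matrix(rnorm(8 * 250), 8)
  full <- modelForward(m, M)
  headOnly <- stsaEEG:::headForwardR(concatFeatures(M, M, M), m@params, cfg)
  expect_identical(full$logp, headOnly$logp)
})

test_that("compiled fast path agrees with the plain-R reference", {
  cfg <- smallConfig()
  m <- randomizedModelParams(initParameters(stsaModel(cfg), seed = 10), seed = 11)
  set.seed(12)
  X <- array(rnorm(8 * 250 * 5), c(8, 250, 5))
  fast <- forwardLogProb(m, X)
  for (i in 1:5) {
    ref <- modelForward(m, X[, , i])$logp
    expect_lt(max(abs(fast[i, ] - ref)), 5e-4)
    expect_identical(which.max(fast[i, ]), which.max(ref))
  }
})

test_that("evaluation-mode prediction is deterministic", {
  cfg <- smallConfig()
  m <- randomizedModelParams(initParameters(stsaModel(cfg), seed = 13), seed = 14)
  set.seed(15)
  X <- array(rnorm(8 * 250 * 6), c(8, 250, 6))
  expect_identical(forwardLogProb(m, X), forwardLogProb(m, X))
})

test_that("prediction requires parameters and preserves batch order", {
  cfg <- smallConfig()
  expect_error(predict(stsaModel(cfg), array(0, c(8, 250, 1))), "fitted")
  m <- randomizedModelParams(initParameters(stsaModel(cfg), seed = 16), seed = 17)
  set.seed(18)
  X <- array(rnorm(8 * 250 * 32), c(8, 250, 32))
  pred <- predict(m, X)
  expect_length(pred, 32)
  # order preserving: predicting a subset matches the batch prediction
  expect_identical(as.character(pred[3:7]), as.character(predict(m, X[, , 3:7])))
})

test_that("argmax ties resolve to the lowest class index", {
  logp <- rbind(log(c(0.7, 0.1, 0.1, 0.1)), log(c(0.1, 0.4, 0.4, 0.1)))
  idx <- apply(logp, 1, which.max)
  cls <- stsaEEG:::classFromLogProb(logp, c("a", "b", "c", "d"))
  expect_identical(as.character(cls), c("a", "b"))
})

test_that("parameter counts are exact and monotone", {
  cfg <- modelConfig()
  pc <- countParameters(cfg)
  expect_identical(pc$parameters[pc$layer == "conv2"], 40L * (3L * 25L) + 40L)
  expect_identical(pc$parameters[pc$layer == "lambda"], 2L)
  expect_identical(pc$parameters[pc$layer == "conv3"], 40L * 40L * 22L)
  expect_gt(totalParameters(modelConfig(headMaps = 80)), totalParameters(cfg))
  # the count matches the materialized parameter list
  m <- initParameters(stsaModel(smallConfig()), seed = 1)
  live <- sum(vapply(m@params[setdiff(names(m@params), c("bn_rmean", "bn_rvar"))],
                     length, 1L))
  expect_identical(live, totalParameters(smallConfig()))
})

test_that("training-path gradients match finite differences", {
  cfg <- modelConfig(nChannels = 6, nSamples = 160, attMaps = 3, headMaps = 8)
  m <- randomizedModelParams(initParameters(stsaModel(cfg), seed = 20), seed = 21)
  p <- m@params
  set.seed(22)
  X <- array(rnorm(6 * 160 * 3), c(6, 160, 3))
  y <- c(0L, 2L, 3L)
  cfgL <- stsaEEG:::cfgList(cfg)
  cfgL$dropout_p <- 0   # deterministic loss for differencing
  res <- stsaEEG:::cpp_train_batch(p, X, y, cfgL, 1)
  lossAt <- function(pp) stsaEEG:::cpp_train_batch(pp, X, y, cfgL, 1)$loss
  eps <- 2e-3
  set.seed(23)
  for (nm in names(res$grads)) {
    g <- res$grads[[nm]]
    for (idx in sample(length(g), min(3, length(g)))) {
      pp <- p; pp[[nm]][idx] <- pp[[nm]][idx] + eps
      up <- lossAt(pp)
      pp[[nm]][idx] <- pp[[nm]][idx] - 2 * eps
      dn <- lossAt(pp)
      fd <- (up - dn) / (2 * eps)
      # single-precision loss gives a differencing noise floor ~5e-5
      expect_lt(abs(fd - g[idx]), 2e-4 + 0.03 * abs(g[idx]))
    }
  }
})
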