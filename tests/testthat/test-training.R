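test_that("initialization is seeded, Xavier-scaled, with zero lambdas and biases", {
  cfg <- smallConfig()
  a <- initParameters(stsaModel(cfg), seed = 42)
  b <- initParameters(stsaModel(cfg), seed = 42)
  expect_identical(a@params, b@params)
  expect_false(identical(a@params, initParameters(stsaModel(cfg), seed = 43)@params))
  expect_identical(a@params$lam1, 0)
  expect_identical(a@params$lam2, 0)
  expect_true(all(a@params$b2 == 0) && all(a@params$beta == 0))
  # Xavier variance of the big temporal conv: 2 / (fanIn + fanOut)
  big <- initParameters(stsaModel(modelConfig()), seed = 1)
  fanIn <- 3 * 25; fanOut <- 40 * 25
  expect_lt(abs(var(as.vector(big@params$W2)) / (2 / (fanIn + fanOut)) - 1), 0.2)
})

test_that("stratified split reproduces the 288-trial geometry", {
  set.seed(1)
  X <- array(rnorm(4 * 60 * 288), c(4, 60, 288))
  eps <- eegEpochs(X, rep(c("l", "r", "f", "t"), each = 72), 250)
  sp <- splitTrainValid(eps, 0.2, seed = 3)
  expect_identical(nEpochs(sp$train), 230L)
  expect_identical(nEpochs(sp$valid), 58L)
  # class proportions within one trial of 25% each
  tab <- table(epochLabels(sp$valid))
  expect_true(all(abs(tab - 58 / 4) <= 1))
  # disjoint and exhaustive
  expect_identical(nEpochs(sp$train) + nEpochs(sp$valid), 288L)
  expect_error(splitTrainValid(eps, 0), "between 0 and 1")
})

test_that("split errors name a class with too few epochs", {
  X <- array(rnorm(4 * 60 * 5), c(4, 60, 5))
  eps <- eegEpochs(X, c("a", "a", "b", "b", "c"), 250)
  expect_error(splitTrainValid(eps, 0.2), "c")
})

test_that("the loss is the NLL of the true class under the log-probabilities", {
  logp <- rbind(log(c(0.7, 0.1, 0.1, 0.1)), log(c(0.25, 0.25, 0.25, 0.25)))
  expect_lt(abs(nllLoss(logp, c(0L, 3L)) - (-(log(0.7) + log(0.25)) / 2)), 1e-6)
})

test_that("two-phase training learns a separable problem and keeps its contracts", {
  tr <- generateDataset(smallSpec(), 30, seed = 5)
  cfg <- smallConfig()
  tc <- trainConfig(lr = 1e-3, batchSize = 16, patience = 4,
                    maxEpochsPhase1 = 25, maxEpochsPhase2 = 15, seed = 2)
  fit <- fitTwoPhase(stsaModel(cfg), tr, tc)
  h <- fit@history

  # descent on the training loss
  p1 <- h[h$phase == 1, ]
  expect_lt(p1$trainLoss[fit@phase1EndEpoch], p1$trainLoss[1])

  # patience bookkeeping: phase 1 stops only after `patience` stale epochs
  # (or at the cap), and the recorded threshold is the best epoch's train loss
  bestEpoch <- which.max(p1$validAcc)   # first epoch reaching the maximum
  expect_equal(fit@bestValidAcc, max(p1$validAcc))
  expect_equal(fit@phase1TrainLoss, p1$trainLoss[bestEpoch])
  expect_identical(fit@phase1EndEpoch, nrow(p1))
  if (fit@phase1EndEpoch < tc@maxEpochsPhase1)
    expect_identical(fit@phase1EndEpoch, bestEpoch + tc@patience)

  # phase 2 termination rule: former-validation loss reached the threshold
  p2 <- h[h$phase == 2, ]
  if (!fit@phase2MaxedOut && nrow(p2) > 0)
    expect_lte(p2$validLoss[nrow(p2)], fit@phase1TrainLoss)
  expect_true(fit@model@fitted)
})

test_that("phase-1-only training restores the best-validation parameters", {
  tr <- generateDataset(smallSpec(), 20, seed = 7)
  cfg <- smallConfig()
  tc <- trainConfig(lr = 1e-3, batchSize = 16, patience = 3,
                    maxEpochsPhase1 = 12, maxEpochsPhase2 = 0, seed = 4)
  fit <- fitTwoPhase(stsaModel(cfg), tr, tc)
  # re-evaluate the restored parameters on the same validation split
  sp <- splitTrainValid(tr, tc@validFraction, seed = tc@seed)
  pred <- predict(fit@model, sp$valid)
  expect_equal(accuracy(epochLabels(sp$valid), pred), fit@bestValidAcc)
})

test_that("training runs are reproducible under a fixed seed", {
  tr <- generateDataset(smallSpec(), 12, seed = 9)
  cfg <- smallConfig()
  tc <- trainConfig(lr = 1e-3, batchSize = 8, patience = 2,
                    maxEpochsPhase1 = 4, maxEpochsPhase2 = 2, seed = 11)
  f1 <- fitTwoPhase(stsaModel(cfg), tr, tc)
  f2 <- fitTwoPhase(stsaModel(cfg), tr, tc)
  expect_equal(f1@history, f2@history)
  expect_identical(f1@model@params, f2@model@params)
})

test_that("fold assignment yields the printed 518/58 geometry for 576 trials", {
  folds <- cvFolds(576, 10, seed = 1)
  sizes <- as.integer(table(folds))
  expect_identical(sort(sizes, decreasing = TRUE), c(rep(58L, 6), rep(57L, 4)))
  expect_identical(length(folds), 576L)            # union = input, disjoint by construction
  expect_identical(576L - sizes[1], 518L)          # training size for a 58-trial fold
  expect_identical(cvFolds(576, 10, seed = 1), folds)
  expect_false(identical(cvFolds(576, 10, seed = 2), folds))
  expect_error(cvFolds(5, 10), "at least")
})

test_that("cross-validation trains on k-1 folds and reports both accuracies", {
  tr <- generateDataset(smallSpec(), 12, seed = 13)     # 48 trials
  tc <- trainConfig(lr = 1e-3, batchSize = 16, patience = 2,
                    maxEpochsPhase1 = 6, maxEpochsPhase2 = 3, seed = 3)
  cv <- crossval10fold(tr, function() stsaModel(smallConfig()), tc, nFolds = 4)
  expect_length(cv$foldBestAcc, 4)
  expect_length(cv$foldFinalAcc, 4)
  expect_identical(cv$folds, cvFolds(48, 4, seed = 3))
  expect_true(all(cv$foldBestAcc >= cv$foldFinalAcc - 1e-9))
  expect_equal(cv$meanBestAcc, mean(cv$foldBestAcc))
})

test_that("transfer pretrains without the target subject and helps on it", {
  s1 <- generateDataset(smallSpec(), 25, seed = 15, subjectId = "S01")
  s2 <- generateDataset(smallSpec(), 25, seed = 16, subjectId = "S02")
  target <- generateDataset(smallSpec(), 12, seed = 17, subjectId = "S03")
  all <- combineEpochs(s1, s2, target)
  test <- generateDataset(smallSpec(), 10, seed = 18, subjectId = "S03")
  tc <- trainConfig(lr = 1e-3, batchSize = 16, patience = 3,
                    maxEpochsPhase1 = 10, maxEpochsPhase2 = 5, seed = 6)
  factory <- function() stsaModel(smallConfig())

  fitT <- transferPretrainFinetune("S03", all, factory, tc)
  # leakage check: pretraining never saw the target subject
  expect_identical(sort(fitT@extra$pretrainSubjects), c("S01", "S02"))
  # fine-tuning started from the phase-A weights
  expect_identical(names(fitT@extra$phaseAParams), names(fitT@model@params))

  fitS <- fitTwoPhase(factory(), all[subjectIds(all) == "S03"], tc)
  accT <- accuracy(epochLabels(test), predict(fitT@model, test))
  accS <- accuracy(epochLabels(test), predict(fitS@model, test))
  expect_gte(accT, accS - 5)
  expect_error(transferPretrainFinetune("S99", all, factory, tc), "S99")
})
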