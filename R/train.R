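# Training: negative log-likelihood loss, Adam, the stratified split, the
# two-phase early-stopping schedule, 10-fold cross-validation, and the
# inter-subject transfer protocol.

#' Negative log-likelihood of the true classes
#'
#' @param logp n x nClasses matrix of log-probabilities.
#' @param y integer class indices (0-based) of length n.
#' @return Mean NLL over the batch.
#' @export
nllLoss <- function(logp, y) {
  stopifnot(nrow(logp) == length(y))
  -mean(logp[cbind(seq_along(y), y + 1L)])
}

labelsToIdx <- function(labels, classLevels) {
  idx <- match(as.character(labels), classLevels) - 1L
  if (anyNA(idx)) stop("epoch labels outside the model's class levels")
  idx
}

#' Stratified train/validation split
#'
#' Splits epochs into a training and a validation set, stratified by class:
#' the total validation size is round(n * fraction), allocated across classes
#' by largest remainder so class proportions are preserved to within one
#' trial. Seeded and reproducible.
#'
#' @param epochs an \linkS4class{EEGEpochs}.
#' @param fraction validation fraction, strictly between 0 and 1.
#' @param seed integer seed.
#' @return list(train = , valid = ) of \linkS4class{EEGEpochs}.
#' @export
splitTrainValid <- function(epochs, fraction = 0.2, seed = 1) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be strictly between 0 and 1")
  labs <- as.character(epochLabels(epochs))
  counts <- table(labs)
  small <- names(counts)[counts < 2]
  if (length(small))
    stop("class with fewer than 2 epochs: ", paste(small, collapse = ", "))
  nValid <- round(nEpochs(epochs) * fraction)
  if (nValid < 1) stop("validation set would be empty; increase fraction or data size")
  exact <- setNames(as.numeric(counts) * fraction, names(counts))
  base <- floor(exact)
  rem <- nValid - sum(base)
  if (rem > 0) {
    order_ <- order(exact - base, decreasing = TRUE)
    base[order_[seq_len(rem)]] <- base[order_[seq_len(rem)]] + 1
  } else if (rem < 0) {
    order_ <- order(exact - base)
    base[order_[seq_len(-rem)]] <- base[order_[seq_len(-rem)]] - 1
  }
  set.seed(seed)
  validIdx <- integer()
  for (cl in names(counts)) {
    idx <- which(labs == cl)
    validIdx <- c(validIdx, sample(idx, base[[cl]]))
  }
  validIdx <- sort(validIdx)
  list(train = epochs[-validIdx], valid = epochs[validIdx])
}

adamInit <- function(params) {
  trainable <- setdiff(names(params), c("bn_rmean", "bn_rvar"))
  list(m = lapply(params[trainable], function(p) p * 0),
       v = lapply(params[trainable], function(p) p * 0),
       t = 0L)
}

adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(state$m)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# one pass over the training data; returns updated params/opt state and the
# mean training loss; freeze pins both attention residual scalars at 0
# (attention-off ablation baseline)
trainOneEpoch <- function(params, X, yIdx, cfgL, opt, lr, batchSize, bnMomentum,
                          freeze = FALSE) {
  n <- dim(X)[3]
  ord <- sample.int(n)
  lossSum <- 0
  for (start in seq(1, n, by = batchSize)) {
    idx <- ord[start:min(start + batchSize - 1, n)]
    dropSeed <- sample.int(.Machine$integer.max, 1)
    res <- cpp_train_batch(params, X[, , idx, drop = FALSE], as.integer(yIdx[idx]),
                           cfgL, dropSeed)
    if (!is.finite(res$loss))
      stop(sprintf("non-finite training loss (batch starting at %d); lambda1=%.3g lambda2=%.3g",
                   start, params$lam1, params$lam2))
    upd <- adamStep(params, res$grads, opt, lr)
    params <- upd$params; opt <- upd$state
    if (freeze) { params$lam1 <- 0; params$lam2 <- 0 }
    params$bn_rmean <- (1 - bnMomentum) * params$bn_rmean + bnMomentum * res$bn_mean
    params$bn_rvar <- (1 - bnMomentum) * params$bn_rvar + bnMomentum * res$bn_var
    lossSum <- lossSum + res$loss * length(idx)
  }
  list(params = params, opt = opt, loss = lossSum / n)
}

evalMetrics <- function(params, cfgL, X, yIdx) {
  logp <- cpp_eval_forward(params, X, cfgL)
  pred <- apply(logp, 1, which.max) - 1L
  list(loss = nllLoss(logp, yIdx), acc = 100 * mean(pred == yIdx))
}

#' Two-phase early-stopping training
#'
#' Phase 1 trains on a stratified 80/20-style split of the supplied epochs
#' with Adam on the negative log-likelihood, tracking validation accuracy;
#' it stops once the validation accuracy has not improved for `patience`
#' epochs (or at the epoch cap) and restores the parameters of the
#' best-validation epoch. Phase 2 continues training on the combined
#' training + validation data and stops when the loss on the former
#' validation subset drops to the training-loss value recorded at the
#' best-validation epoch of phase 1 (or at the epoch cap, which sets
#' `phase2MaxedOut`).
#'
#' @param model an \linkS4class{STSAModel}; initialized with
#'   \code{\link{initParameters}}(seed) if its parameters are empty.
#' @param epochs training \linkS4class{EEGEpochs}.
#' @param config a \linkS4class{TrainConfig}.
#' @param monitor optional \linkS4class{EEGEpochs} evaluated (accuracy) after
#'   every epoch and recorded in the history as `monitorAcc`; never used for
#'   any training decision.
#' @param freezeLambdas keep both attention residual scalars pinned at 0, so
#'   the network trains as the attention-free head on (M, M, M); the ablation
#'   baseline for the attention modules.
#' @param verbose print per-epoch progress.
#' @return An \linkS4class{STSAFit}.
#' @export
fitTwoPhase <- function(model, epochs, config = trainConfig(), monitor = NULL,
                        freezeLambdas = FALSE, verbose = FALSE) {
  stopifnot(is(model, "STSAModel"), is(epochs, "EEGEpochs"))
  cfg <- model@config
  if (!length(model@classLevels)) model@classLevels <- levels(epochLabels(epochs))
  if (length(model@classLevels) != cfg@nClasses)
    stop("number of classes in the data does not match the model configuration")
  if (!length(model@params)) model <- initParameters(model, seed = config@seed)
  cfgL <- cfgList(cfg)

  split <- splitTrainValid(epochs, config@validFraction, seed = config@seed)
  Xtr <- epochArray(split$train); ytr <- labelsToIdx(epochLabels(split$train), model@classLevels)
  Xva <- epochArray(split$valid); yva <- labelsToIdx(epochLabels(split$valid), model@classLevels)
  Xmon <- if (!is.null(monitor)) epochArray(monitor)
  ymon <- if (!is.null(monitor)) labelsToIdx(epochLabels(monitor), model@classLevels)

  set.seed(config@seed + 1L)
  params <- model@params
  opt <- adamInit(params)
  hist <- list()
  best <- list(acc = -Inf, params = params, opt = opt, trainLoss = NA_real_, epoch = 0L)
  since <- 0L

  for (ep in seq_len(config@maxEpochsPhase1)) {
    st <- trainOneEpoch(params, Xtr, ytr, cfgL, opt, config@lr, config@batchSize,
                        cfg@bnMomentum, freeze = freezeLambdas)
    params <- st$params; opt <- st$opt
    vm <- evalMetrics(params, cfgL, Xva, yva)
    row <- data.frame(phase = 1L, epoch = ep, trainLoss = st$loss,
                      validLoss = vm$loss, validAcc = vm$acc)
    if (!is.null(monitor)) row$monitorAcc <- evalMetrics(params, cfgL, Xmon, ymon)$acc
    hist[[length(hist) + 1]] <- row
    if (verbose)
      message(sprintf("phase 1 epoch %3d: train %.4f valid %.4f acc %.2f%%",
                      ep, st$loss, vm$loss, vm$acc))
    if (vm$acc > best$acc) {
      best <- list(acc = vm$acc, params = params, opt = opt,
                   trainLoss = st$loss, epoch = ep)
      since <- 0L
    } else {
      since <- since + 1L
      if (since >= config@patience) break
    }
  }
  phase1End <- length(hist)
  params <- best$params
  opt <- best$opt

  Xall <- epochArray(epochs); yall <- labelsToIdx(epochLabels(epochs), model@classLevels)
  maxedOut <- FALSE
  # maxEpochsPhase2 = 0 requests a phase-1-only run (parameters stay at the
  # restored best-validation state)
  if (config@maxEpochsPhase2 > 0 && is.finite(best$trainLoss)) {
    maxedOut <- TRUE
    for (ep in seq_len(config@maxEpochsPhase2)) {
      st <- trainOneEpoch(params, Xall, yall, cfgL, opt, config@lr, config@batchSize,
                          cfg@bnMomentum, freeze = freezeLambdas)
      params <- st$params; opt <- st$opt
      vm <- evalMetrics(params, cfgL, Xva, yva)
      row <- data.frame(phase = 2L, epoch = phase1End + ep, trainLoss = st$loss,
                        validLoss = vm$loss, validAcc = vm$acc)
      if (!is.null(monitor)) row$monitorAcc <- evalMetrics(params, cfgL, Xmon, ymon)$acc
      hist[[length(hist) + 1]] <- row
      if (verbose)
        message(sprintf("phase 2 epoch %3d: train %.4f former-valid %.4f (target %.4f)",
                        ep, st$loss, vm$loss, best$trainLoss))
      if (vm$loss <= best$trainLoss) { maxedOut <- FALSE; break }
    }
    if (maxedOut)
      warning("phase 2 reached its epoch cap before the validation loss dropped to the phase-1 training loss")
  }

  model@params <- params
  model@fitted <- TRUE
  new("STSAFit", model = model, history = do.call(rbind, hist),
      phase1EndEpoch = as.integer(phase1End), phase1TrainLoss = best$trainLoss,
      bestValidAcc = best$acc, phase2MaxedOut = maxedOut, extra = list())
}

#' Seeded fold assignment for k-fold cross-validation
#'
#' For n not divisible by k, the larger folds come first: the first n %% k
#' folds have floor(n/k) + 1 members. Assignment is a seeded random shuffle.
#'
#' @param n number of trials.
#' @param k number of folds.
#' @param seed integer seed.
#' @return Integer vector of length n with fold ids in 1..k.
#' @export
cvFolds <- function(n, k = 10, seed = 1) {
  if (n < k) stop("need at least as many trials as folds")
  base <- n %/% k
  sizes <- rep(base, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- base + 1
  set.seed(seed)
  sample(rep(seq_len(k), times = sizes))
}

#' 10-fold cross-validation protocol
#'
#' Pools all supplied epochs, assigns seeded folds (\code{\link{cvFolds}}),
#' and for each fold trains a fresh model (two-phase schedule) on the other
#' k-1 folds, monitoring the held-out fold after every epoch. Reports, per
#' fold, both the final-model accuracy and the best per-epoch accuracy on the
#' held-out fold, plus their means.
#'
#' @param epochs pooled \linkS4class{EEGEpochs}.
#' @param modelFactory zero-argument function returning a fresh
#'   \linkS4class{STSAModel}.
#' @param config a \linkS4class{TrainConfig}.
#' @param nFolds number of folds (default 10).
#' @param verbose print per-fold progress.
#' @return list(foldBestAcc, foldFinalAcc, meanBestAcc, meanFinalAcc, folds).
#' @export
crossval10fold <- function(epochs, modelFactory, config = trainConfig(),
                           nFolds = 10, verbose = FALSE) {
  n <- nEpochs(epochs)
  folds <- cvFolds(n, nFolds, seed = config@seed)
  bestAcc <- finalAcc <- numeric(nFolds)
  for (f in seq_len(nFolds)) {
    testIdx <- which(folds == f)
    train <- epochs[-testIdx]; test <- epochs[testIdx]
    fit <- fitTwoPhase(modelFactory(), train, config, monitor = test)
    pred <- predict(fit@model, test)
    finalAcc[f] <- accuracy(epochLabels(test), pred)
    bestAcc[f] <- max(fit@history$monitorAcc)
    if (verbose)
      message(sprintf("fold %2d: final %.2f%%, best %.2f%% (train %d / test %d)",
                      f, finalAcc[f], bestAcc[f], n - length(testIdx), length(testIdx)))
  }
  list(foldBestAcc = bestAcc, foldFinalAcc = finalAcc,
       meanBestAcc = mean(bestAcc), meanFinalAcc = mean(finalAcc), folds = folds)
}

#' Inter-subject transfer: pretrain on other subjects, fine-tune on the target
#'
#' Phase A trains one model (two-phase schedule) on the concatenated data of
#' every subject except the target. Phase B starts from the phase-A weights
#' (no layers frozen) and runs the two-phase schedule on the target subject's
#' epochs. The returned fit's `extra` records the pretraining subjects, the
#' phase-A parameters (the fine-tuning initialization), and the phase-A
#' history.
#'
#' @param targetSubject subject id present in `epochs`.
#' @param epochs \linkS4class{EEGEpochs} of all subjects.
#' @param modelFactory zero-argument function returning a fresh model.
#' @param config a \linkS4class{TrainConfig}.
#' @param verbose print progress.
#' @return An \linkS4class{STSAFit} for the fine-tuned target model.
#' @export
transferPretrainFinetune <- function(targetSubject, epochs, modelFactory,
                                     config = trainConfig(), verbose = FALSE) {
  ids <- subjectIds(epochs)
  if (!targetSubject %in% ids) stop("target subject not found: ", targetSubject)
  if (length(unique(ids)) < 2) stop("need at least 2 subjects for transfer")
  source <- epochs[ids != targetSubject]
  target <- epochs[ids == targetSubject]
  if (verbose) message(sprintf("phase A: pretraining on %d epochs from %d subjects",
                               nEpochs(source), length(unique(subjectIds(source)))))
  fitA <- fitTwoPhase(modelFactory(), source, config, verbose = verbose)
  init <- fitA@model
  init@fitted <- FALSE
  if (verbose) message(sprintf("phase B: fine-tuning on %d target epochs", nEpochs(target)))
  fitB <- fitTwoPhase(init, target, config, verbose = verbose)
  fitB@extra <- list(pretrainSubjects = unique(subjectIds(source)),
                     phaseAParams = fitA@model@params,
                     phaseAHistory = fitA@history)
  fitB
}
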