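#' Continuous multi-channel EEG recording
#'
#' Holds a channels x samples signal matrix (microvolts), its sampling rate,
#' channel labels, and cue events. Events are a data frame with columns
#' `sample` (1-based sample index of the cue) and `label` (class of the trial).
#'
#' @slot signal channels x samples numeric matrix.
#' @slot fs sampling rate in Hz.
#' @slot channelLabels character vector, one unique label per channel.
#' @slot events data.frame with columns `sample` (integer) and `label`.
#' @export
setClass("EEGRecording",
  representation(signal = "matrix", fs = "numeric",
                 channelLabels = "character", events = "data.frame"))

setValidity("EEGRecording", function(object) {
  msgs <- character()
  if (length(object@fs) != 1 || !is.finite(object@fs) || object@fs <= 0)
    msgs <- c(msgs, "fs must be a single positive number")
  if (length(object@channelLabels) != nrow(object@signal))
    msgs <- c(msgs, "one channel label per signal row required")
  if (anyDuplicated(object@channelLabels))
    msgs <- c(msgs, "channel labels must be unique")
  if (nrow(object@events) > 0) {
    if (!all(c("sample", "label") %in% names(object@events)))
      msgs <- c(msgs, "events need columns 'sample' and 'label'")
    else if (any(object@events$sample < 1 | object@events$sample > ncol(object@signal)))
      msgs <- c(msgs, "event sample indices must lie within the recording")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an EEGRecording
#'
#' @param signal channels x samples numeric matrix.
#' @param fs sampling rate (Hz).
#' @param channelLabels channel names; defaults to ch01, ch02, ...
#' @param events data.frame with columns `sample` and `label` (may be empty).
#' @return An \linkS4class{EEGRecording}.
#' @export
eegRecording <- function(signal, fs, channelLabels = NULL, events = NULL) {
  signal <- as.matrix(signal)
  if (is.null(channelLabels))
    channelLabels <- sprintf("ch%02d", seq_len(nrow(signal)))
  if (is.null(events))
    events <- data.frame(sample = integer(), label = character())
  new("EEGRecording", signal = signal, fs = as.numeric(fs),
      channelLabels = channelLabels, events = events)
}

#' Labeled fixed-length EEG epochs
#'
#' The atomic input of the classifier: a stack of channels x samples matrices,
#' one class label per epoch. Stored as an H x W x n array.
#'
#' @slot X numeric array of dimension (channels, samples, epochs), standardized units.
#' @slot labels factor of length n (the class of each epoch).
#' @slot fs sampling rate in Hz.
#' @slot channelLabels channel names (length H).
#' @slot subjectIds character vector of length n.
#' @export
setClass("EEGEpochs",
  representation(X = "array", labels = "factor", fs = "numeric",
                 channelLabels = "character", subjectIds = "character"))

setValidity("EEGEpochs", function(object) {
  msgs <- character()
  d <- dim(object@X)
  if (length(d) != 3) msgs <- c(msgs, "X must be a 3-d array (H, W, n)")
  else {
    if (d[1] < 2) msgs <- c(msgs, "at least 2 channels required")
    if (length(object@labels) != d[3]) msgs <- c(msgs, "one label per epoch required")
    if (length(object@subjectIds) != d[3]) msgs <- c(msgs, "one subject id per epoch required")
    if (length(object@channelLabels) != d[1]) msgs <- c(msgs, "one channel label per channel required")
  }
  if (length(object@X) && !all(is.finite(object@X)))
    msgs <- c(msgs, "epochs contain non-finite values")
  if (length(msgs)) msgs else TRUE
})

#' Construct an EEGEpochs container
#'
#' @param X array (H, W, n) of epoch matrices.
#' @param labels class labels, coerced to factor, length n.
#' @param fs sampling rate (Hz).
#' @param channelLabels channel names; defaults to ch01...
#' @param subjectIds subject identifier(s); recycled to length n.
#' @return An \linkS4class{EEGEpochs}.
#' @export
eegEpochs <- function(X, labels, fs, channelLabels = NULL, subjectIds = "S01") {
  if (is.null(channelLabels)) channelLabels <- sprintf("ch%02d", seq_len(dim(X)[1]))
  subjectIds <- rep_len(as.character(subjectIds), dim(X)[3])
  new("EEGEpochs", X = X, labels = as.factor(labels), fs = as.numeric(fs),
      channelLabels = channelLabels, subjectIds = subjectIds)
}

#' Architecture configuration
#'
#' Single source of truth for the network geometry and the classification-head
#' hyperparameters. Defaults reproduce the published architecture for a
#' 22-channel, 1125-sample epoch: F = 8 attention projection maps, 40 head
#' feature maps, 1x25 temporal kernel, H x 1 spatial kernel, 1x75 average
#' pooling with stride 1x15, 4 classes, dropout 0.5, batch-norm eps 1e-5 and
#' running-statistics momentum 0.1.
#'
#' @export
setClass("ModelConfig",
  representation(nChannels = "integer", nSamples = "integer", attMaps = "integer",
                 headMaps = "integer", temporalKernel = "integer",
                 poolKernel = "integer", poolStride = "integer",
                 nClasses = "integer", dropoutP = "numeric", bnEps = "numeric",
                 bnMomentum = "numeric", epsLog = "numeric"))

setValidity("ModelConfig", function(object) {
  msgs <- character()
  convOut <- object@nSamples - object@temporalKernel + 1L
  if (convOut < object@poolKernel)
    msgs <- c(msgs, sprintf(
      "nSamples - temporalKernel + 1 = %d is smaller than the pooling kernel (%d)",
      convOut, object@poolKernel))
  if (object@nClasses < 2) msgs <- c(msgs, "need at least 2 classes")
  if (object@nChannels < 2) msgs <- c(msgs, "need at least 2 channels")
  if (object@dropoutP < 0 || object@dropoutP >= 1) msgs <- c(msgs, "dropoutP must be in [0, 1)")
  if (length(msgs)) msgs else TRUE
})

#' Create a model configuration
#'
#' @param nChannels epoch height H (number of EEG channels).
#' @param nSamples epoch width W (number of time samples).
#' @param attMaps number of 1x1 projection feature maps in each attention module.
#' @param headMaps feature maps of the convolutional head.
#' @param temporalKernel width of the 1 x k temporal convolution.
#' @param poolKernel,poolStride average-pooling kernel width and stride.
#' @param nClasses number of output classes.
#' @param dropoutP dropout probability (applied between the log activation and
#'   the final convolution).
#' @param bnEps,bnMomentum batch normalization epsilon and running-statistics
#'   momentum.
#' @param epsLog floor applied inside the log activation to avoid log(0).
#' @return A \linkS4class{ModelConfig}.
#' @export
modelConfig <- function(nChannels = 22, nSamples = 1125, attMaps = 8,
                        headMaps = 40, temporalKernel = 25, poolKernel = 75,
                        poolStride = 15, nClasses = 4, dropoutP = 0.5,
                        bnEps = 1e-5, bnMomentum = 0.1, epsLog = 1e-6) {
  new("ModelConfig", nChannels = as.integer(nChannels), nSamples = as.integer(nSamples),
      attMaps = as.integer(attMaps), headMaps = as.integer(headMaps),
      temporalKernel = as.integer(temporalKernel), poolKernel = as.integer(poolKernel),
      poolStride = as.integer(poolStride), nClasses = as.integer(nClasses),
      dropoutP = dropoutP, bnEps = bnEps, bnMomentum = bnMomentum, epsLog = epsLog)
}

#' Preprocessing configuration
#'
#' @slot lowCut high-pass edge in Hz; 0 means no high-pass (pure low-pass).
#' @slot highCut low-pass edge in Hz.
#' @slot decay exponential-moving-standardization decay factor in (0, 1).
#' @slot epsVar variance floor of the standardizer.
#' @slot window c(start, end) of the epoch in seconds relative to the cue.
#' @slot targetFs resample target in Hz; NA keeps the native rate.
#' @export
setClass("PreprocessConfig",
  representation(lowCut = "numeric", highCut = "numeric", decay = "numeric",
                 epsVar = "numeric", window = "numeric", targetFs = "numeric"))

setValidity("PreprocessConfig", function(object) {
  msgs <- character()
  if (object@lowCut < 0) msgs <- c(msgs, "lowCut must be >= 0")
  if (object@highCut <= object@lowCut) msgs <- c(msgs, "highCut must exceed lowCut")
  if (object@decay <= 0 || object@decay >= 1) msgs <- c(msgs, "decay must be in (0, 1)")
  if (object@epsVar <= 0) msgs <- c(msgs, "epsVar must be positive")
  if (length(object@window) != 2 || object@window[1] >= object@window[2])
    msgs <- c(msgs, "window must be c(start, end) with start < end")
  if (length(msgs)) msgs else TRUE
})

#' Create a preprocessing configuration
#'
#' Defaults follow the 22-channel benchmark protocol: 38 Hz low-pass with no
#' high-pass, exponential moving standardization with decay 0.999 and variance
#' floor 1e-4, and a [-0.5, 4] s cue-aligned window.
#'
#' @param lowCut,highCut band edges in Hz (lowCut 0 disables the high-pass).
#' @param decay,epsVar standardizer decay factor and variance floor.
#' @param window c(start, end) seconds relative to the cue.
#' @param targetFs optional resampling target (Hz); NA keeps the native rate.
#' @return A \linkS4class{PreprocessConfig}.
#' @export
preprocessConfig <- function(lowCut = 0, highCut = 38, decay = 0.999,
                             epsVar = 1e-4, window = c(-0.5, 4), targetFs = NA_real_) {
  new("PreprocessConfig", lowCut = lowCut, highCut = highCut, decay = decay,
      epsVar = epsVar, window = window, targetFs = as.numeric(targetFs))
}

#' Training configuration
#'
#' @slot lr Adam learning rate (1e-4 for 22-channel benchmark-like data, 1e-3
#'   for larger high-gamma-like data).
#' @slot batchSize mini-batch size.
#' @slot validFraction fraction held out for validation in phase 1.
#' @slot patience epochs without validation-accuracy improvement ending phase 1.
#' @slot maxEpochsPhase1,maxEpochsPhase2 hard epoch caps.
#' @slot seed RNG seed controlling the split, init, shuffling, and dropout.
#' @export
setClass("TrainConfig",
  representation(lr = "numeric", batchSize = "integer", validFraction = "numeric",
                 patience = "integer", maxEpochsPhase1 = "integer",
                 maxEpochsPhase2 = "integer", seed = "integer"))

setValidity("TrainConfig", function(object) {
  msgs <- character()
  if (object@validFraction <= 0 || object@validFraction >= 1)
    msgs <- c(msgs, "validFraction must be strictly between 0 and 1")
  if (object@batchSize < 1) msgs <- c(msgs, "batchSize must be >= 1")
  if (object@patience < 1) msgs <- c(msgs, "patience must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Create a training configuration
#'
#' @param lr learning rate.
#' @param batchSize mini-batch size.
#' @param validFraction validation fraction of the training data.
#' @param patience early-stopping patience (epochs) for phase 1.
#' @param maxEpochsPhase1,maxEpochsPhase2 epoch caps for the two phases.
#' @param seed integer seed.
#' @return A \linkS4class{TrainConfig}.
#' @export
trainConfig <- function(lr = 1e-4, batchSize = 32, validFraction = 0.2,
                        patience = 80, maxEpochsPhase1 = 800,
                        maxEpochsPhase2 = 800, seed = 1) {
  new("TrainConfig", lr = lr, batchSize = as.integer(batchSize),
      validFraction = validFraction, patience = as.integer(patience),
      maxEpochsPhase1 = as.integer(maxEpochsPhase1),
      maxEpochsPhase2 = as.integer(maxEpochsPhase2), seed = as.integer(seed))
}

#' Spatial-temporal self-attention model
#'
#' Wraps the architecture configuration, the trainable parameters, and the
#' batch-normalization running statistics. Parameters are empty until
#' \code{\link{initParameters}} (or a training function) is called.
#'
#' @slot config a \linkS4class{ModelConfig}.
#' @slot params named list of parameter tensors (see \code{\link{initParameters}}).
#' @slot classLevels class names in output order.
#' @slot fitted TRUE once the model has been trained.
#' @export
setClass("STSAModel",
  representation(config = "ModelConfig", params = "list",
                 classLevels = "character", fitted = "logical"))

#' Create an (untrained) model from a configuration
#'
#' @param config a \linkS4class{ModelConfig}.
#' @param classLevels optional class names in output order.
#' @return An \linkS4class{STSAModel} with empty parameters.
#' @export
stsaModel <- function(config = modelConfig(), classLevels = character()) {
  new("STSAModel", config = config, params = list(),
      classLevels = classLevels, fitted = FALSE)
}

#' Result of a training run
#'
#' @slot model the trained \linkS4class{STSAModel}.
#' @slot history per-epoch data.frame: phase, epoch, trainLoss, validLoss,
#'   validAcc (and monitorAcc when a monitoring set was supplied).
#' @slot phase1EndEpoch epoch index at which phase 1 stopped.
#' @slot phase1TrainLoss training loss at the best-validation epoch; the
#'   stopping threshold of phase 2.
#' @slot bestValidAcc best phase-1 validation accuracy (percent).
#' @slot phase2MaxedOut TRUE when phase 2 hit its epoch cap before reaching
#'   the loss threshold.
#' @slot extra protocol-specific extras (e.g. transfer-learning bookkeeping).
#' @export
setClass("STSAFit",
  representation(model = "STSAModel", history = "data.frame",
                 phase1EndEpoch = "integer", phase1TrainLoss = "numeric",
                 bestValidAcc = "numeric", phase2MaxedOut = "logical",
                 extra = "list"))

#' Synthetic ERD/ERS data specification
#'
#' Describes class-conditional motor-imagery-like EEG: 1/f background noise,
#' mu (8-12 Hz) and beta (16-26 Hz) band-limited oscillations on every channel,
#' class-dependent amplitude factors on channel subsets (factor < 1 models
#' event-related desynchronization, > 1 synchronization), and additive white
#' noise.
#'
#' @slot nChannels,fs,epochLengthS geometry of one epoch.
#' @slot classes named list; each class is a list of modulations
#'   \code{list(band = "mu"|"beta", channels = <indices>, factor = <positive>)}.
#' @slot bgExponent,bgScale 1/f^exponent background spectral exponent and scale.
#' @slot oscAmplitude named numeric c(mu = , beta = ) base oscillation amplitudes.
#' @slot noiseSd standard deviation of the additive white noise.
#' @export
setClass("SyntheticSpec",
  representation(nChannels = "integer", fs = "numeric", epochLengthS = "numeric",
                 classes = "list", bgExponent = "numeric", bgScale = "numeric",
                 oscAmplitude = "numeric", noiseSd = "numeric"))

setValidity("SyntheticSpec", function(object) {
  msgs <- character()
  if (is.null(names(object@classes)) || any(names(object@classes) == ""))
    msgs <- c(msgs, "classes must be a named list")
  for (cl in names(object@classes)) {
    for (mod in object@classes[[cl]]) {
      if (!mod$band %in% c("mu", "beta"))
        msgs <- c(msgs, sprintf("class %s: band must be 'mu' or 'beta'", cl))
      if (any(mod$channels < 1 | mod$channels > object@nChannels))
        msgs <- c(msgs, sprintf("class %s: channel index out of range", cl))
      if (mod$factor <= 0)
        msgs <- c(msgs, sprintf("class %s: amplitude factor must be positive", cl))
    }
  }
  if (!all(c("mu", "beta") %in% names(object@oscAmplitude)))
    msgs <- c(msgs, "oscAmplitude needs entries 'mu' and 'beta'")
  if (length(msgs)) msgs else TRUE
})
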