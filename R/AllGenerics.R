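#' @name stsaEEG-generics
#' @title Accessors for stsaEEG containers
#' @param object,x an stsaEEG object.
#' @param i epoch indices.
#' @param ... unused.
NULL

#' @rdname stsaEEG-generics
#' @export
setGeneric("nEpochs", function(object) standardGeneric("nEpochs"))

#' @rdname stsaEEG-generics
#' @export
setGeneric("epochLabels", function(object) standardGeneric("epochLabels"))

#' @rdname stsaEEG-generics
#' @export
setGeneric("channelLabels", function(object) standardGeneric("channelLabels"))

#' @rdname stsaEEG-generics
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' @rdname stsaEEG-generics
#' @export
setGeneric("epochArray", function(object) standardGeneric("epochArray"))

#' @rdname stsaEEG-generics
#' @export
setGeneric("subjectIds", function(object) standardGeneric("subjectIds"))

#' @describeIn EEGEpochs number of epochs.
#' @param object,x an \linkS4class{EEGEpochs}.
#' @export
setMethod("nEpochs", "EEGEpochs", function(object) dim(object@X)[3])

#' @describeIn EEGEpochs class labels (factor of length n).
#' @export
setMethod("epochLabels", "EEGEpochs", function(object) object@labels)

#' @describeIn EEGEpochs channel names.
#' @export
setMethod("channelLabels", "EEGEpochs", function(object) object@channelLabels)

#' @describeIn EEGRecording channel names.
#' @export
setMethod("channelLabels", "EEGRecording", function(object) object@channelLabels)

#' @describeIn EEGEpochs sampling rate (Hz).
#' @export
setMethod("samplingRate", "EEGEpochs", function(object) object@fs)

#' @describeIn EEGRecording sampling rate (Hz).
#' @export
setMethod("samplingRate", "EEGRecording", function(object) object@fs)

#' @describeIn EEGEpochs the (H, W, n) epoch array.
#' @export
setMethod("epochArray", "EEGEpochs", function(object) object@X)

#' @describeIn EEGEpochs subject identifier of each epoch.
#' @export
setMethod("subjectIds", "EEGEpochs", function(object) object@subjectIds)

#' @describeIn EEGEpochs subset epochs by index vector.
#' @param i epoch indices (integer or logical).
#' @param j,drop ignored.
#' @export
setMethod("[", "EEGEpochs", function(x, i, j, ..., drop = FALSE) {
  i <- seq_len(nEpochs(x))[i]
  new("EEGEpochs", X = x@X[, , i, drop = FALSE],
      labels = factor(x@labels[i], levels = levels(x@labels)),
      fs = x@fs, channelLabels = x@channelLabels, subjectIds = x@subjectIds[i])
})

#' Concatenate epoch containers
#'
#' All containers must share geometry, sampling rate, and channel labels.
#'
#' @param ... \linkS4class{EEGEpochs} objects.
#' @return A single \linkS4class{EEGEpochs}.
#' @export
combineEpochs <- function(...) {
  parts <- list(...)
  stopifnot(length(parts) >= 1)
  ref <- parts[[1]]
  for (p in parts[-1]) {
    if (!identical(dim(p@X)[1:2], dim(ref@X)[1:2]) || p@fs != ref@fs ||
        !identical(p@channelLabels, ref@channelLabels))
      stop("epoch containers are not compatible")
  }
  lv <- unique(unlist(lapply(parts, function(p) levels(p@labels))))
  X <- array(unlist(lapply(parts, function(p) p@X)),
             dim = c(dim(ref@X)[1:2], sum(vapply(parts, nEpochs, 1L))))
  new("EEGEpochs", X = X,
      labels = factor(unlist(lapply(parts, function(p) as.character(p@labels))), levels = lv),
      fs = ref@fs, channelLabels = ref@channelLabels,
      subjectIds = unlist(lapply(parts, function(p) p@subjectIds)))
}

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording: %d channels x %d samples @ %g Hz, %d events\n",
              nrow(object@signal), ncol(object@signal), object@fs, nrow(object@events)))
})

setMethod("show", "EEGEpochs", function(object) {
  d <- dim(object@X)
  cat(sprintf("EEGEpochs: %d epochs of %d channels x %d samples @ %g Hz\n",
              d[3], d[1], d[2], object@fs))
  if (d[3] > 0) {
    tab <- table(object@labels)
    cat("  classes:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
    cat("  subjects:", paste(unique(object@subjectIds), collapse = ", "), "\n")
  }
})

setMethod("show", "ModelConfig", function(object) {
  cat(sprintf("ModelConfig: %d x %d epochs, %d attention maps, %d head maps, %d classes\n",
              object@nChannels, object@nSamples, object@attMaps,
              object@headMaps, object@nClasses))
})

setMethod("show", "STSAModel", function(object) {
  cat(sprintf("STSAModel (%s): %d x %d input, %d classes\n",
              if (object@fitted) "fitted" else if (length(object@params)) "initialized" else "uninitialized",
              object@config@nChannels, object@config@nSamples, object@config@nClasses))
  if (length(object@params))
    cat(sprintf("  lambda1 = %.4g, lambda2 = %.4g, %d trainable parameters\n",
                object@params$lam1, object@params$lam2, totalParameters(object@config)))
})

setMethod("show", "STSAFit", function(object) {
  cat(sprintf("STSAFit: %d epochs trained (phase 1 ended at %d), best validation accuracy %.2f%%\n",
              nrow(object@history), object@phase1EndEpoch, object@bestValidAcc))
})
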