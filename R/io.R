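# File interfaces: epoch archives, model checkpoints, and a minimal EDF/EDF+
# reader/writer for continuous recordings with event annotations. Archives and
# checkpoints use R-native serialization with a stable field layout
# (X: n_trials first-dim-free array, y, fs, channel_labels, subject_ids).

#' Write an epoch archive
#'
#' @param epochs an \linkS4class{EEGEpochs}.
#' @param path output file (conventionally .rds).
#' @return Invisibly, the path.
#' @export
writeEpochArchive <- function(epochs, path) {
  saveRDS(list(X = epochs@X, y = as.character(epochs@labels),
               class_levels = levels(epochs@labels),
               fs = epochs@fs, channel_labels = epochs@channelLabels,
               subject_ids = epochs@subjectIds, format = "stsaEEG-epochs-v1"),
          path)
  invisible(path)
}

#' Read an epoch archive
#'
#' @param path file written by \code{\link{writeEpochArchive}}.
#' @return An \linkS4class{EEGEpochs}.
#' @export
readEpochArchive <- function(path) {
  if (!file.exists(path)) stsaStop("io", "no such file: ", path)
  a <- readRDS(path)
  if (!identical(a$format, "stsaEEG-epochs-v1"))
    stsaStop("data", "not an epoch archive: ", path)
  eegEpochs(a$X, factor(a$y, levels = a$class_levels), a$fs,
            a$channel_labels, a$subject_ids)
}

#' Save a model or fit checkpoint
#'
#' Stores the configuration, all parameters (including the attention residual
#' scalars), batch-norm running statistics, class levels, and, for fits, the
#' training history and early-stopping bookkeeping.
#'
#' @param object an \linkS4class{STSAModel} or \linkS4class{STSAFit}.
#' @param path output file (conventionally .rds).
#' @return Invisibly, the path.
#' @export
saveCheckpoint <- function(object, path) {
  if (is(object, "STSAFit")) {
    fit <- object; model <- object@model
  } else if (is(object, "STSAModel")) {
    fit <- NULL; model <- object
  } else stop("object must be an STSAModel or STSAFit")
  cfg <- model@config
  ck <- list(format = "stsaEEG-checkpoint-v1",
             config = list(nChannels = cfg@nChannels, nSamples = cfg@nSamples,
                           attMaps = cfg@attMaps, headMaps = cfg@headMaps,
                           temporalKernel = cfg@temporalKernel,
                           poolKernel = cfg@poolKernel, poolStride = cfg@poolStride,
                           nClasses = cfg@nClasses, dropoutP = cfg@dropoutP,
                           bnEps = cfg@bnEps, bnMomentum = cfg@bnMomentum,
                           epsLog = cfg@epsLog),
             params = model@params, classLevels = model@classLevels,
             fitted = model@fitted)
  if (!is.null(fit))
    ck$fit <- list(history = fit@history, phase1EndEpoch = fit@phase1EndEpoch,
                   phase1TrainLoss = fit@phase1TrainLoss,
                   bestValidAcc = fit@bestValidAcc,
                   phase2MaxedOut = fit@phase2MaxedOut, extra = fit@extra)
  saveRDS(ck, path)
  invisible(path)
}

#' Load a checkpoint
#'
#' @param path file written by \code{\link{saveCheckpoint}}.
#' @return An \linkS4class{STSAFit} if the checkpoint came from a fit,
#'   otherwise an \linkS4class{STSAModel}.
#' @export
loadCheckpoint <- function(path) {
  if (!file.exists(path)) stsaStop("io", "no such file: ", path)
  ck <- readRDS(path)
  if (!identical(ck$format, "stsaEEG-checkpoint-v1"))
    stsaStop("data", "not a checkpoint: ", path)
  model <- new("STSAModel", config = do.call(modelConfig, ck$config),
               params = ck$params, classLevels = ck$classLevels, fitted = ck$fitted)
  fit <- ck[["fit"]]
  if (is.null(fit)) return(model)
  new("STSAFit", model = model, history = fit$history,
      phase1EndEpoch = fit$phase1EndEpoch,
      phase1TrainLoss = fit$phase1TrainLoss,
      bestValidAcc = fit$bestValidAcc,
      phase2MaxedOut = fit$phase2MaxedOut, extra = fit$extra)
}

# ---- minimal EDF/EDF+ ----

padTo <- function(s, n) formatC(substr(s, 1, n), width = -n)

#' Write a recording as EDF+
#'
#' Minimal EDF+ writer: one-second data records, 16-bit samples scaled to the
#' per-channel physical range, and an "EDF Annotations" signal carrying one
#' time-stamped annotation per event (onset = event sample / fs, text = the
#' event label). Intended for round-tripping and for feeding the reader;
#' not a full implementation of the specification.
#'
#' @param recording an \linkS4class{EEGRecording}; its length is truncated to
#'   a whole number of seconds and fs must be a positive integer.
#' @param path output file.
#' @return Invisibly, the path.
#' @export
writeEDF <- function(recording, path) {
  sig <- recording@signal
  fs <- recording@fs
  if (fs != round(fs) || fs <= 0) stop("EDF writer requires an integer sampling rate")
  nRec <- ncol(sig) %/% fs
  if (nRec < 1) stop("recording shorter than one data record (1 s)")
  sig <- sig[, seq_len(nRec * fs), drop = FALSE]
  H <- nrow(sig)
  annBytes <- 120L                  # bytes reserved per record for annotations
  annSamples <- annBytes %/% 2L

  pmin_ <- apply(sig, 1, min); pmax_ <- apply(sig, 1, max)
  pad <- pmax(1e-6, (pmax_ - pmin_) * 0.01)
  pmin_ <- pmin_ - pad; pmax_ <- pmax_ + pad
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  ns <- H + 1L
  headerBytes <- 256L * (ns + 1L)
  writeChar(paste0(
    padTo("0", 8), padTo("X X X X", 80), padTo("Startdate X X X X", 80),
    padTo("01.01.20", 8), padTo("00.00.00", 8),
    padTo(as.character(headerBytes), 8), padTo("EDF+C", 44),
    padTo(as.character(nRec), 8), padTo("1", 8), padTo(as.character(ns), 4)),
    con, eos = NULL)
  field <- function(vals, width)
    writeChar(paste(vapply(vals, padTo, "", n = width), collapse = ""), con, eos = NULL)
  labels <- c(recording@channelLabels, "EDF Annotations")
  field(labels, 16)
  field(rep("", ns), 80)                                   # transducer
  field(c(rep("uV", H), ""), 8)                            # physical dimension
  field(c(formatC(pmin_, format = "g", digits = 6), "-1"), 8)
  field(c(formatC(pmax_, format = "g", digits = 6), "1"), 8)
  field(c(rep(as.character(dmin), H), "-32768"), 8)
  field(c(rep(as.character(dmax), H), "32767"), 8)
  field(rep("", ns), 80)                                   # prefiltering
  field(c(rep(as.character(fs), H), as.character(annSamples)), 8)
  field(rep("", ns), 32)

  events <- recording@events
  evRecord <- if (nrow(events)) pmin((events$sample - 1) %/% fs, nRec - 1) else integer()
  for (r in seq_len(nRec) - 1L) {
    for (c in seq_len(H)) {
      x <- sig[c, (r * fs + 1):(r * fs + fs)]
      dig <- round((x - pmin_[c]) / (pmax_[c] - pmin_[c]) * (dmax - dmin) + dmin)
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2, endian = "little")
    }
    tal <- sprintf("+%d\x14\x14", r)
    for (e in which(evRecord == r)) {
      onset <- (events$sample[e] - 1) / fs
      tal <- paste0(tal, sprintf("+%.6g\x14%s\x14", onset, as.character(events$label[e])))
    }
    raw <- charToRaw(tal)
    if (length(raw) > annBytes) stop("too many events in one record for the reserved annotation space")
    writeBin(c(raw, raw(annBytes - length(raw))), con)
  }
  invisible(path)
}

#' Read an EDF/EDF+ recording
#'
#' Minimal reader for continuous EDF/EDF+ files with equal sampling rate on
#' every ordinary signal: parses the header, rescales 16-bit samples to
#' physical units, and turns "EDF Annotations" time-stamped annotations into
#' cue events (sample = round(onset * fs) + 1, label = annotation text).
#'
#' @param path an EDF/EDF+ file.
#' @param dropChannels optional channel labels to discard (e.g. EOG channels).
#' @return An \linkS4class{EEGRecording}.
#' @export
readEDF <- function(path, dropChannels = character()) {
  if (!file.exists(path)) stsaStop("io", "no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  rd(8 + 80 + 80 + 8 + 8)
  rd(8)                              # header bytes (recomputed below)
  rd(44)
  nRec <- as.integer(rd(8))
  recDur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  rd(80 * ns)
  rd(8 * ns)                         # physical dimension
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  rd(80 * ns)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  rd(32 * ns)

  annIdx <- which(labels == "EDF Annotations")
  sigIdx <- setdiff(seq_len(ns), annIdx)
  if (length(unique(spr[sigIdx])) != 1)
    stsaStop("data", "signals with differing sampling rates are not supported")
  fs <- spr[sigIdx[1]] / recDur
  nCh <- length(sigIdx)
  sig <- matrix(0, nCh, nRec * spr[sigIdx[1]])
  annText <- character()
  for (r in seq_len(nRec) - 1L) {
    for (s in seq_len(ns)) {
      if (s %in% annIdx) {
        raw <- readBin(con, "raw", spr[s] * 2)
        annText <- c(annText, rawToChar(raw[raw != as.raw(0)], multiple = FALSE))
      } else {
        dig <- readBin(con, "integer", spr[s], size = 2, endian = "little")
        c_ <- match(s, sigIdx)
        scale <- (pmax_[s] - pmin_[s]) / (dmax[s] - dmin[s])
        sig[c_, (r * spr[s] + 1):((r + 1) * spr[s])] <- (dig - dmin[s]) * scale + pmin_[s]
      }
    }
  }
  events <- parseTALs(paste(annText, collapse = ""), fs)
  rec <- eegRecording(sig, fs, labels[sigIdx], events)
  if (length(dropChannels)) {
    keep <- !rec@channelLabels %in% dropChannels
    rec <- eegRecording(rec@signal[keep, , drop = FALSE], fs,
                        rec@channelLabels[keep], events)
  }
  rec
}

# parse EDF+ time-stamped annotation lists; keep annotations with text
parseTALs <- function(txt, fs) {
  tals <- strsplit(txt, "\x14\x14|\x14\\x00|\x14(?=\\+|-)", perl = TRUE)[[1]]
  samples <- integer(); labs <- character()
  for (tal in tals) {
    parts <- strsplit(tal, "\x14")[[1]]
    if (length(parts) < 2) next
    onset <- suppressWarnings(as.numeric(strsplit(parts[1], "\x15")[[1]][1]))
    if (!is.finite(onset)) next
    for (txt_ in parts[-1]) {
      if (nzchar(txt_)) {
        samples <- c(samples, as.integer(round(onset * fs)) + 1L)
        labs <- c(labs, txt_)
      }
    }
  }
  data.frame(sample = samples, label = labs)
}
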