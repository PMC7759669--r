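# Preprocessing: band-pass filtering, causal exponential moving
# standardization, resampling, and cue-aligned epoching. Pipeline order is
# fixed: (resample) -> filter -> standardize -> epoch.

#' Zero-phase Butterworth band-pass filter
#'
#' 4th-order Butterworth applied forward-backward (zero phase, so epoch
#' alignment is preserved), independently per channel. A `lowCut` of 0
#' disables the high-pass, leaving a pure low-pass at `highCut`.
#'
#' @param signal channels x samples numeric matrix (a vector is treated as one
#'   channel).
#' @param fs sampling rate (Hz).
#' @param lowCut high-pass edge (Hz); 0 or NULL for low-pass only.
#' @param highCut low-pass edge (Hz); must be below the Nyquist frequency.
#' @param order filter order (default 4).
#' @return Filtered matrix of the same shape.
#' @export
bandpassFilter <- function(signal, fs, lowCut, highCut, order = 4) {
  if (is.null(lowCut) || is.na(lowCut)) lowCut <- 0
  if (lowCut < 0 || highCut <= lowCut)
    stop("invalid band: need 0 <= lowCut < highCut")
  if (highCut >= fs / 2)
    stop("highCut must be below the Nyquist frequency fs/2")
  vec <- is.null(dim(signal))
  x <- if (vec) matrix(signal, nrow = 1) else as.matrix(signal)
  if (!all(is.finite(x))) stop("signal contains non-finite values")
  filt <- if (lowCut > 0)
    signal::butter(order, c(lowCut, highCut) / (fs / 2), type = "pass")
  else
    signal::butter(order, highCut / (fs / 2), type = "low")
  out <- t(apply(x, 1, function(row) signal::filtfilt(filt, row)))
  if (vec) as.vector(out) else out
}

#' Causal exponential moving standardization
#'
#' Standardizes each channel by exponentially weighted running mean and
#' variance updated causally left to right:
#' \deqn{m_t = d\,m_{t-1} + (1-d)\,x_t, \quad
#'       v_t = d\,v_{t-1} + (1-d)(x_t - m_t)^2,}
#' with \eqn{m_1 = x_1}, \eqn{v_1 = 0}, and output
#' \eqn{(x_t - m_t) / \max(\sqrt{v_t}, \sqrt{\epsilon})}.
#' A constant channel therefore maps to all zeros, and adding a constant
#' offset to the input leaves the output unchanged after burn-in.
#'
#' @param signal channels x samples matrix (or vector, one channel).
#' @param decay decay factor d in (0, 1); default 0.999.
#' @param epsVar variance floor; default 1e-4.
#' @return Standardized matrix of the same shape.
#' @export
exponentialMovingStandardize <- function(signal, decay = 0.999, epsVar = 1e-4) {
  if (decay <= 0 || decay >= 1) stop("decay must be in (0, 1)")
  if (epsVar <= 0) stop("epsVar must be positive")
  vec <- is.null(dim(signal))
  x <- if (vec) matrix(signal, nrow = 1) else as.matrix(signal)
  if (ncol(x) == 0) stop("empty signal")
  if (!all(is.finite(x))) stop("signal contains non-finite values")
  out <- cpp_ems(x, decay, epsVar)
  if (vec) as.vector(out) else out
}

#' Band-limited resampling
#'
#' Polyphase resampling of each channel from `fsFrom` to `fsTo` Hz. The output
#' length is round(n * fsTo / fsFrom); when the rates are equal the input is
#' returned unchanged.
#'
#' @param signal channels x samples matrix or vector.
#' @param fsFrom,fsTo source and target sampling rates (Hz).
#' @return Resampled signal.
#' @export
resampleSignal <- function(signal, fsFrom, fsTo) {
  if (!is.finite(fsFrom) || !is.finite(fsTo) || fsFrom <= 0 || fsTo <= 0)
    stop("sampling rates must be positive and finite")
  if (fsFrom == fsTo) return(signal)
  scale <- if (fsFrom %% 1 == 0 && fsTo %% 1 == 0) 1 else 1e6
  a <- round(fsTo * scale); b <- round(fsFrom * scale)
  g <- gcdInt(a, b)
  p <- a / g; q <- b / g
  vec <- is.null(dim(signal))
  x <- if (vec) matrix(signal, nrow = 1) else as.matrix(signal)
  nOut <- round(ncol(x) * fsTo / fsFrom)
  out <- matrix(0, nrow(x), nOut)
  for (c in seq_len(nrow(x))) {
    y <- signal::resample(x[c, ], p, q)
    out[c, ] <- if (length(y) >= nOut) y[seq_len(nOut)] else c(y, rep(y[length(y)], nOut - length(y)))
  }
  if (vec) as.vector(out) else out
}

gcdInt <- function(a, b) { while (b != 0) { t <- b; b <- a %% b; a <- t }; a }

#' Extract cue-aligned epochs from a continuous recording
#'
#' One epoch per event, over the half-open sample interval
#' [cue + round(start*fs), cue + round(end*fs)), so the width is exactly
#' round((end - start) * fs) samples. Events whose window exceeds the
#' recording bounds are skipped with a warning.
#'
#' @param recording an \linkS4class{EEGRecording}.
#' @param window c(start, end) in seconds relative to the cue sample.
#' @param subjectId subject identifier attached to the epochs.
#' @return An \linkS4class{EEGEpochs} (possibly with zero epochs).
#' @export
extractEpochs <- function(recording, window = c(-0.5, 4), subjectId = "S01") {
  stopifnot(is(recording, "EEGRecording"))
  fs <- recording@fs
  Wn <- round((window[2] - window[1]) * fs)
  off <- round(window[1] * fs)
  H <- nrow(recording@signal)
  nS <- ncol(recording@signal)
  keep <- list(); labs <- character()
  for (e in seq_len(nrow(recording@events))) {
    i0 <- recording@events$sample[e] + off
    if (i0 < 1 || i0 + Wn - 1 > nS) {
      warning(sprintf("event %d at sample %d: window outside recording, skipped",
                      e, recording@events$sample[e]))
      next
    }
    keep[[length(keep) + 1]] <- recording@signal[, i0:(i0 + Wn - 1), drop = FALSE]
    labs <- c(labs, as.character(recording@events$label[e]))
  }
  X <- if (length(keep)) array(unlist(keep), dim = c(H, Wn, length(keep)))
       else array(numeric(0), dim = c(H, Wn, 0))
  eegEpochs(X, factor(labs), fs, recording@channelLabels, subjectId)
}

#' Full preprocessing pipeline
#'
#' Fixed order: optional resampling to `targetFs` (event samples are rescaled
#' accordingly), band-pass filtering, causal exponential moving
#' standardization, then cue-aligned epoching.
#'
#' @param recording an \linkS4class{EEGRecording}.
#' @param config a \linkS4class{PreprocessConfig}.
#' @param subjectId subject identifier attached to the epochs.
#' @return An \linkS4class{EEGEpochs}.
#' @export
preprocessRecording <- function(recording, config = preprocessConfig(), subjectId = "S01") {
  fs <- recording@fs
  sig <- recording@signal
  events <- recording@events
  if (!is.na(config@targetFs) && config@targetFs != fs) {
    sig <- resampleSignal(sig, fs, config@targetFs)
    events$sample <- pmin(round(events$sample * config@targetFs / fs), ncol(sig))
    fs <- config@targetFs
  }
  if (config@highCut >= fs / 2)
    stop("highCut must be below the Nyquist frequency of the (resampled) signal")
  sig <- bandpassFilter(sig, fs, config@lowCut, config@highCut)
  sig <- exponentialMovingStandardize(sig, config@decay, config@epsVar)
  rec <- eegRecording(sig, fs, recording@channelLabels, events)
  extractEpochs(rec, config@window, subjectId)
}
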