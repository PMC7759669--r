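# Synthetic motor-imagery-like EEG with class-dependent ERD/ERS: 1/f
# background, band-limited mu and beta oscillations whose per-channel
# amplitudes are scaled by class-specific factors, and additive white noise.

#' Default four-class ERD/ERS layout
#'
#' Emulates the classic contralateral organization of motor imagery:
#' left-hand imagery suppresses mu and beta over the right motor region,
#' right-hand over the left motor region, feet over the midline, and tongue
#' imagery enhances beta bilaterally. For 22 channels the groups follow a
#' standard 22-electrode montage neighborhood of C3 / C4 / Cz; for other
#' channel counts the channels are split into three contiguous groups.
#'
#' @param nChannels number of channels.
#' @param erdFactor amplitude factor for suppressed bands (default 0.4).
#' @param ersFactor amplitude factor for enhanced bands (default 1.7).
#' @return Named list of class modulation lists, suitable for
#'   \code{\link{syntheticSpec}}.
#' @export
defaultMotorImageryClasses <- function(nChannels = 22, erdFactor = 0.4,
                                       ersFactor = 1.7) {
  if (nChannels >= 22) {
    left <- c(2, 7, 8, 9, 14); right <- c(6, 11, 12, 13, 18); mid <- c(4, 10, 15, 20)
  } else {
    thirds <- split(seq_len(nChannels), cut(seq_len(nChannels), 3, labels = FALSE))
    left <- thirds[[1]]; right <- thirds[[2]]; mid <- thirds[[3]]
  }
  mods <- function(chs, muF, betaF)
    list(list(band = "mu", channels = chs, factor = muF),
         list(band = "beta", channels = chs, factor = betaF))
  list(
    left_hand = mods(right, erdFactor, sqrt(erdFactor)),
    right_hand = mods(left, erdFactor, sqrt(erdFactor)),
    feet = mods(mid, erdFactor, sqrt(erdFactor)),
    tongue = list(list(band = "beta", channels = c(left, right), factor = ersFactor)))
}

#' Create a synthetic ERD/ERS specification
#'
#' @param nChannels,fs,epochLengthS epoch geometry (defaults 22 channels,
#'   250 Hz, 4.5 s = 1125 samples).
#' @param classes named list of class modulations; see
#'   \code{\link{defaultMotorImageryClasses}}.
#' @param bgExponent exponent of the 1/f^exponent background (default 1).
#' @param bgScale background standard deviation (default 1).
#' @param oscAmplitude base oscillation amplitudes, c(mu = 1, beta = 0.6):
#'   mu rhythm is the dominant sensorimotor oscillation.
#' @param noiseSd additive white-noise standard deviation (default 0.5).
#' @return A \linkS4class{SyntheticSpec}.
#' @export
syntheticSpec <- function(nChannels = 22, fs = 250, epochLengthS = 4.5,
                          classes = defaultMotorImageryClasses(nChannels),
                          bgExponent = 1, bgScale = 1,
                          oscAmplitude = c(mu = 1, beta = 0.6), noiseSd = 0.5) {
  new("SyntheticSpec", nChannels = as.integer(nChannels), fs = fs,
      epochLengthS = epochLengthS, classes = classes, bgExponent = bgExponent,
      bgScale = bgScale, oscAmplitude = oscAmplitude, noiseSd = noiseSd)
}

bandLimits <- list(mu = c(8, 12), beta = c(16, 26))

# 1/f^exponent spectrally shaped Gaussian noise, unit variance
coloredNoise <- function(n, exponent) {
  wn <- rnorm(n)
  sp <- fft(wn)
  k <- c(0, seq_len(n - 1))
  freqIdx <- pmin(k, n - k)          # two-sided frequency bin index
  amp <- c(0, 1 / freqIdx[-1]^(exponent / 2))
  x <- Re(fft(sp * amp, inverse = TRUE)) / n
  x / sd(x)
}

# white noise band-passed into [lo, hi] Hz, unit variance (random phase
# realization each call, so epochs are non-trivially variable)
bandOscillation <- function(n, fs, band) {
  filt <- signal::butter(4, bandLimits[[band]] / (fs / 2), type = "pass")
  x <- signal::filtfilt(filt, rnorm(n + 2 * fs))   # pad to suppress transients
  x <- x[(fs + 1):(fs + n)]
  x / sd(x)
}

#' Generate one synthetic epoch
#'
#' Each channel is 1/f background + mu oscillation + beta oscillation + white
#' noise; the oscillation amplitude on a channel is the base band amplitude
#' times the class's factor for that channel (1 where the class specifies
#' nothing). Consumes the R random number stream, so results are deterministic
#' after \code{set.seed}.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @param classLabel one of names(spec@classes).
#' @return Channels x samples matrix.
#' @export
generateEpoch <- function(spec, classLabel) {
  if (!classLabel %in% names(spec@classes))
    stop("unknown class: ", classLabel)
  n <- round(spec@fs * spec@epochLengthS)
  H <- spec@nChannels
  fac <- matrix(1, H, 2, dimnames = list(NULL, c("mu", "beta")))
  for (mod in spec@classes[[classLabel]])
    fac[mod$channels, mod$band] <- mod$factor
  M <- matrix(0, H, n)
  for (c in seq_len(H)) {
    M[c, ] <- spec@bgScale * coloredNoise(n, spec@bgExponent) +
      spec@oscAmplitude[["mu"]] * fac[c, "mu"] * bandOscillation(n, spec@fs, "mu") +
      spec@oscAmplitude[["beta"]] * fac[c, "beta"] * bandOscillation(n, spec@fs, "beta") +
      spec@noiseSd * rnorm(n)
  }
  M
}

#' Generate a balanced, shuffled synthetic dataset
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @param nPerClass epochs per class.
#' @param seed integer seed; the same seed yields a bit-identical dataset.
#' @param subjectId subject identifier attached to the epochs.
#' @return An \linkS4class{EEGEpochs} with nPerClass * nClasses epochs.
#' @export
generateDataset <- function(spec, nPerClass, seed = 1, subjectId = "S01") {
  stopifnot(nPerClass >= 1)
  set.seed(seed)
  classes <- names(spec@classes)
  n <- nPerClass * length(classes)
  W <- round(spec@fs * spec@epochLengthS)
  labs <- rep(classes, each = nPerClass)
  X <- array(0, c(spec@nChannels, W, n))
  for (i in seq_len(n)) X[, , i] <- generateEpoch(spec, labs[i])
  ord <- sample.int(n)
  eegEpochs(X[, , ord, drop = FALSE], factor(labs[ord], levels = classes),
            spec@fs, subjectIds = subjectId)
}

#' Welch power spectral density
#'
#' Hann-windowed averaged periodograms with 50% overlap.
#'
#' @param x numeric vector.
#' @param fs sampling rate (Hz).
#' @param segLength segment length (default 256, capped at length(x)).
#' @return list(freq, psd) with psd in power per Hz.
#' @export
welchPsd <- function(x, fs, segLength = 256) {
  n <- length(x)
  segLength <- min(segLength, n)
  step <- max(1, segLength %/% 2)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(segLength) / (segLength + 1))
  u <- sum(win^2)
  starts <- seq(1, n - segLength + 1, by = step)
  nf <- segLength %/% 2 + 1
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + segLength - 1)] * win
    sp <- abs(fft(seg))^2 / (u * fs)
    acc <- acc + sp[seq_len(nf)]
  }
  psd <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist for even lengths)
  dbl <- rep(2, nf); dbl[1] <- 1
  if (segLength %% 2 == 0) dbl[nf] <- 1
  list(freq = (seq_len(nf) - 1) * fs / segLength, psd = psd * dbl)
}

#' Welch band power
#'
#' @param x numeric vector.
#' @param fs sampling rate (Hz).
#' @param band c(lo, hi) in Hz.
#' @param segLength Welch segment length.
#' @return Mean PSD over the band times the band width (power in the band).
#' @export
welchBandPower <- function(x, fs, band, segLength = 256) {
  w <- welchPsd(x, fs, segLength)
  sel <- w$freq >= band[1] & w$freq <= band[2]
  mean(w$psd[sel]) * (band[2] - band[1])
}

#' Per-epoch log band-power features
#'
#' Log mu- and beta-band Welch power for every channel: the feature a
#' classical linear band-power decoder would use.
#'
#' @param epochs an \linkS4class{EEGEpochs}.
#' @return n x (2 * nChannels) feature matrix.
#' @export
bandPowerFeatures <- function(epochs) {
  X <- epochArray(epochs)
  fs <- samplingRate(epochs)
  H <- dim(X)[1]; n <- dim(X)[3]
  feat <- matrix(0, n, 2 * H)
  for (i in seq_len(n)) for (c in seq_len(H)) {
    feat[i, c] <- log(welchBandPower(X[c, , i], fs, bandLimits$mu))
    feat[i, H + c] <- log(welchBandPower(X[c, , i], fs, bandLimits$beta))
  }
  feat
}

#' Linear band-power baseline classifier
#'
#' Least squares on class-indicator targets over log band-power features,
#' predictions by argmax: a sanity floor that any deep model must beat.
#'
#' @param train,test \linkS4class{EEGEpochs} with shared class levels.
#' @return list(accuracy = test accuracy in percent, predictions = factor).
#' @export
bandPowerBaseline <- function(train, test) {
  lv <- levels(epochLabels(train))
  Xtr <- cbind(1, bandPowerFeatures(train))
  Ytr <- outer(as.character(epochLabels(train)), lv, "==") * 1
  B <- solve(crossprod(Xtr) + 1e-6 * diag(ncol(Xtr)), crossprod(Xtr, Ytr))
  Xte <- cbind(1, bandPowerFeatures(test))
  pred <- factor(lv[max.col(Xte %*% B, ties.method = "first")], levels = lv)
  list(accuracy = accuracy(epochLabels(test), pred), predictions = pred)
}
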