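# Reference implementations of the two self-attention modules, written in the
# reshape + matrix-multiplication form of the architecture tables so every
# intermediate (s11, s21, ..., t3, t4) is available for inspection. The
# training loop uses an algebraically identical compiled fast path
# (src/stsa_core.cpp); tests assert the two agree.

#' Numerically stabilized row-wise softmax
#'
#' Each row of the score matrix is mapped to a probability vector: the row
#' maximum is subtracted before exponentiation, so arbitrarily large score
#' magnitudes are handled without overflow.
#'
#' @param scores numeric matrix of similarity scores (finite).
#' @return Matrix of the same shape; every row is nonnegative and sums to 1.
#' @export
rowSoftmax <- function(scores) {
  scores <- as.matrix(scores)
  if (!all(is.finite(scores))) stop("scores must be finite")
  e <- exp(scores - apply(scores, 1, max))
  e / rowSums(e)
}

#' Attention module parameters
#'
#' A query and a key projection, each a 1x1 convolution from the single-map
#' epoch image to `nMaps` feature maps (so `nMaps` scalar weights plus biases
#' each), and the learnable residual scalar lambda (initialized to 0 so the
#' module starts as the identity).
#'
#' @param nMaps number of projection feature maps F.
#' @param w1,b1 query projection weights and biases (length F).
#' @param w2,b2 key projection weights and biases (length F).
#' @param lam residual scalar.
#' @return A list with elements w1, b1, w2, b2, lam.
#' @export
attentionParams <- function(nMaps = 8, w1 = numeric(nMaps), b1 = numeric(nMaps),
                            w2 = numeric(nMaps), b2 = numeric(nMaps), lam = 0) {
  stopifnot(length(w1) == nMaps, length(b1) == nMaps,
            length(w2) == nMaps, length(b2) == nMaps, length(lam) == 1)
  list(w1 = w1, b1 = b1, w2 = w2, b2 = b2, lam = lam)
}

# F-map 1x1 projection of a single-map image: arr[f, , ] = w[f]*M + b[f]
project1x1 <- function(M, w, b) {
  Fn <- length(w)
  arr <- array(0, c(Fn, nrow(M), ncol(M)))
  for (f in seq_len(Fn)) arr[f, , ] <- w[f] * M + b[f]
  arr
}

checkEpochMatrix <- function(M) {
  if (!is.matrix(M) || !is.numeric(M)) stop("M must be a numeric matrix")
  if (!all(is.finite(M))) stop("M contains non-finite values")
}

#' Spatial (channel-wise) self-attention
#'
#' Projects the raw epoch M (H x W) into two F-map images via 1x1 convolutions,
#' reshapes them to H x (F W) and (F W) x H, forms the channel-similarity
#' scores by their matrix product, row-softmaxes the scores into the spatial
#' attention weight map s3 (H x H, rows sum to 1), computes the predicted
#' signal s4 = s3 M (each channel a convex combination of all channels), and
#' returns the residual feature S = lambda * s4 + M.
#'
#' @param M epoch matrix (channels x samples).
#' @param params output of \code{\link{attentionParams}}.
#' @return List with elements `feature` (S), `predicted` (s4), `map` (s3),
#'   and intermediates `s11`, `s12`, `s21`, `s22`, `scores`.
#' @export
spatialAttention <- function(M, params) {
  checkEpochMatrix(M)
  if (nrow(M) == 1) warning("single-channel epoch: spatial attention map is [[1]]")
  s11 <- project1x1(M, params$w1, params$b1)
  s12 <- project1x1(M, params$w2, params$b2)
  Fn <- length(params$w1)
  sl <- function(a, f) matrix(a[f, , ], nrow = nrow(M))
  # s21[i, (f-1)W + w] = s11[f, i, w];  s22[(f-1)W + w, j] = s12[f, j, w]
  s21 <- do.call(cbind, lapply(seq_len(Fn), function(f) sl(s11, f)))
  s22 <- do.call(rbind, lapply(seq_len(Fn), function(f) t(sl(s12, f))))
  scores <- s21 %*% s22
  s3 <- rowSoftmax(scores)
  s4 <- s3 %*% M
  list(feature = params$lam * s4 + M, predicted = s4, map = s3,
       s11 = s11, s12 = s12, s21 = s21, s22 = s22, scores = scores)
}

#' Temporal (time-step-wise) self-attention
#'
#' Mirrors \code{\link{spatialAttention}} on the time axis: the projections are
#' reshaped to W x (F H) and (F H) x W, the softmaxed scores give the temporal
#' attention weight map t3 (W x W, row p sums to 1 over q), and each output
#' time step is the t3-weighted convex combination of all input time steps,
#' t4[c, p] = sum_q t3[p, q] M[c, q]. Returns T = lambda * t4 + M.
#'
#' @inheritParams spatialAttention
#' @return List with `feature` (T), `predicted` (t4), `map` (t3), and
#'   intermediates `t11`, `t12`, `t21`, `t22`, `scores`.
#' @export
temporalAttention <- function(M, params) {
  checkEpochMatrix(M)
  if (ncol(M) == 1) warning("single-sample epoch: temporal attention map is [[1]]")
  t11 <- project1x1(M, params$w1, params$b1)
  t12 <- project1x1(M, params$w2, params$b2)
  Fn <- length(params$w1)
  sl <- function(a, f) matrix(a[f, , ], nrow = nrow(M))
  # t21[p, (f-1)H + c] = t11[f, c, p];  t22[(f-1)H + c, q] = t12[f, c, q]
  t21 <- do.call(cbind, lapply(seq_len(Fn), function(f) t(sl(t11, f))))
  t22 <- do.call(rbind, lapply(seq_len(Fn), function(f) sl(t12, f)))
  scores <- t21 %*% t22
  t3 <- rowSoftmax(scores)
  t4 <- M %*% t(t3)
  list(feature = params$lam * t4 + M, predicted = t4, map = t3,
       t11 = t11, t12 = t12, t21 = t21, t22 = t22, scores = scores)
}
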