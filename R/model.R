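# Model assembly: parameter initialization, the reference forward pass, shape
# tracing, prediction, and parameter accounting.
#
# Parameter tensor layout (shared with the compiled core):
#   sw1/sb1/sw2/sb2, tw1/tb1/tw2/tb2  length-F 1x1 projection weights/biases
#   lam1, lam2                        residual scalars
#   W2 [K x 3*tk] with W2[m, (i-1)*tk + k]; b2 [K]
#   W3 [K x K*H]  with W3[m, (m'-1)*H + c]  (no bias: absorbed by batch norm)
#   gamma, beta [K]                   batch-norm affine parameters
#   W4 [ncls x K*P] with W4[cls, (m-1)*P + j]; b4 [ncls]
#   bn_rmean, bn_rvar [K]             running statistics (not trainable)

cfgList <- function(config) {
  list(H = config@nChannels, W = config@nSamples, F = config@attMaps,
       K = config@headMaps, tk = config@temporalKernel, pk = config@poolKernel,
       ps = config@poolStride, ncls = config@nClasses,
       dropout_p = config@dropoutP, bn_eps = config@bnEps, eps_log = config@epsLog)
}

convOutWidth <- function(config) config@nSamples - config@temporalKernel + 1L

poolOutWidth <- function(config)
  (convOutWidth(config) - config@poolKernel) %/% config@poolStride + 1L

xavierUniform <- function(n, fanIn, fanOut) {
  b <- sqrt(6 / (fanIn + fanOut))
  runif(n, -b, b)
}

#' Initialize model parameters
#'
#' All convolution weights are drawn Xavier-uniform (bound
#' sqrt(6 / (fanIn + fanOut))); biases, the batch-norm shift, and both
#' attention residual scalars start at 0 (so each attention module is the
#' identity at initialization); the batch-norm scale starts at 1.
#'
#' @param model an \linkS4class{STSAModel}.
#' @param seed integer seed; the same seed reproduces the same parameters.
#' @return The model with populated `params`.
#' @export
initParameters <- function(model, seed = 1) {
  cfg <- model@config
  set.seed(seed)
  H <- cfg@nChannels; Fn <- cfg@attMaps; K <- cfg@headMaps
  tk <- cfg@temporalKernel; P <- poolOutWidth(cfg); ncls <- cfg@nClasses
  p <- list(
    sw1 = xavierUniform(Fn, 1, Fn), sb1 = numeric(Fn),
    sw2 = xavierUniform(Fn, 1, Fn), sb2 = numeric(Fn),
    tw1 = xavierUniform(Fn, 1, Fn), tb1 = numeric(Fn),
    tw2 = xavierUniform(Fn, 1, Fn), tb2 = numeric(Fn),
    lam1 = 0, lam2 = 0,
    W2 = matrix(xavierUniform(K * 3 * tk, 3 * tk, K * tk), K, 3 * tk),
    b2 = numeric(K),
    W3 = matrix(xavierUniform(K * K * H, K * H, K * H), K, K * H),
    gamma = rep(1, K), beta = numeric(K),
    W4 = matrix(xavierUniform(ncls * K * P, K * P, ncls * P), ncls, K * P),
    b4 = numeric(ncls),
    bn_rmean = numeric(K), bn_rvar = rep(1, K))
  model@params <- p
  model
}

modelAttentionParams <- function(params, which = c("spatial", "temporal")) {
  which <- match.arg(which)
  if (which == "spatial")
    attentionParams(length(params$sw1), params$sw1, params$sb1,
                    params$sw2, params$sb2, params$lam1)
  else
    attentionParams(length(params$tw1), params$tw1, params$tb1,
                    params$tw2, params$tb2, params$lam2)
}

#' Stack raw and attention features
#'
#' Stacks the raw epoch and the two attention features into the (3, H, W)
#' input of the classification head, in the fixed order (M, S, T).
#'
#' @param M,S,T H x W matrices.
#' @return Array of dimension (3, H, W).
#' @export
concatFeatures <- function(M, S, T) {
  if (!identical(dim(M), dim(S)) || !identical(dim(M), dim(T)))
    stop("M, S, T must share dimensions")
  arr <- array(0, c(3, nrow(M), ncol(M)))
  arr[1, , ] <- M; arr[2, , ] <- S; arr[3, , ] <- T
  arr
}

logSoftmax <- function(z) {
  z <- z - max(z)
  z - log(sum(exp(z)))
}

# Classification head, reference implementation (evaluation mode: running
# batch-norm statistics, no dropout). Returns log-probabilities plus every
# intermediate stage for shape tracing.
headForwardR <- function(C1, params, config) {
  H <- config@nChannels; W <- config@nSamples; K <- config@headMaps
  tk <- config@temporalKernel; pk <- config@poolKernel; ps <- config@poolStride
  Wc <- convOutWidth(config); P <- poolOutWidth(config)

  # temporal convolution (1 x tk over the 3 stacked maps), via im2col
  col <- matrix(0, H * Wc, 3 * tk)
  for (i in 1:3) for (k in 1:tk)
    col[, (i - 1) * tk + k] <- as.vector(t(matrix(C1[i, , ], H)[, k:(k + Wc - 1)]))
  Y2 <- col %*% t(params$W2)
  Y2 <- sweep(Y2, 2, params$b2, "+")                      # (H*Wc) x K
  C2 <- array(0, c(K, H, Wc))
  for (m in seq_len(K)) C2[m, , ] <- t(matrix(Y2[, m], Wc, H))

  # spatial convolution (H x 1 across all maps), a dense map per time step
  Yr <- matrix(0, K * H, Wc)
  for (m in seq_len(K)) Yr[(m - 1) * H + seq_len(H), ] <- t(matrix(Y2[, m], Wc, H))
  C3 <- params$W3 %*% Yr                                  # K x Wc

  bn <- (C3 - params$bn_rmean) / sqrt(params$bn_rvar + config@bnEps)
  bn <- bn * params$gamma + params$beta
  sq <- bn^2
  C4 <- matrix(0, K, P)
  for (j in seq_len(P)) C4[, j] <- rowMeans(sq[, (j - 1) * ps + seq_len(pk), drop = FALSE])
  Lg <- log(pmax(C4, config@epsLog))
  f <- as.vector(t(Lg))                                   # f[(m-1)*P + j] = Lg[m, j]
  C5 <- as.vector(params$W4 %*% f + params$b4)
  list(logp = logSoftmax(C5), C2 = C2, C3 = C3, bn = bn, C4 = C4, Lg = Lg, C5 = C5)
}

#' Reference forward pass of the full model on one epoch
#'
#' Runs both attention modules, stacks C1 = (M, S, T), and applies the
#' classification head in evaluation mode (running batch-norm statistics,
#' dropout off). This is the plain-R reference used for introspection and for
#' validating the compiled training path; `predict` uses the fast path.
#'
#' @param model an initialized \linkS4class{STSAModel}.
#' @param M epoch matrix (channels x samples) matching the model geometry.
#' @return List with `logp` (log-probabilities), `spatial` and `temporal`
#'   attention outputs, `C1`, and all head intermediates.
#' @export
modelForward <- function(model, M) {
  requireInitialized(model)
  cfg <- model@config
  if (!identical(dim(M), c(cfg@nChannels, cfg@nSamples)))
    stop(sprintf("epoch is %d x %d but model expects %d x %d",
                 nrow(M), ncol(M), cfg@nChannels, cfg@nSamples))
  sp <- spatialAttention(M, modelAttentionParams(model@params, "spatial"))
  te <- temporalAttention(M, modelAttentionParams(model@params, "temporal"))
  C1 <- concatFeatures(M, sp$feature, te$feature)
  head <- headForwardR(C1, model@params, cfg)
  c(list(spatial = sp, temporal = te, C1 = C1), head)
}

requireInitialized <- function(model) {
  if (!length(model@params))
    stop("model has not been fitted or initialized; call initParameters() or a training function")
  invisible(TRUE)
}

#' Batched log-probabilities (fast path)
#'
#' @param model an initialized \linkS4class{STSAModel}.
#' @param X (H, W, n) array or an \linkS4class{EEGEpochs}.
#' @return n x nClasses matrix of log-probabilities.
#' @export
forwardLogProb <- function(model, X) {
  requireInitialized(model)
  if (is(X, "EEGEpochs")) X <- epochArray(X)
  if (length(dim(X)) == 2) X <- array(X, c(dim(X), 1))
  cpp_eval_forward(model@params, X, cfgList(model@config))
}

#' Predict class labels for epochs
#'
#' Deterministic evaluation-mode prediction (dropout off, running batch-norm
#' statistics): the argmax of the log-probabilities, ties resolved toward the
#' lowest class index.
#'
#' @param object a trained \linkS4class{STSAModel}.
#' @param newdata an \linkS4class{EEGEpochs} or (H, W, n) array.
#' @param type "class" for labels, "logprob" for the log-probability matrix.
#' @param ... unused.
#' @return Factor of predicted labels (or the log-probability matrix).
#' @export
setMethod("predict", "STSAModel", function(object, newdata, type = c("class", "logprob"), ...) {
  type <- match.arg(type)
  logp <- forwardLogProb(object, newdata)
  if (type == "logprob") return(logp)
  lv <- if (length(object@classLevels) == object@config@nClasses) object@classLevels
        else as.character(seq_len(object@config@nClasses) - 1L)
  classFromLogProb(logp, lv)
})

# argmax with ties resolved toward the lowest class index
classFromLogProb <- function(logp, classLevels) {
  idx <- apply(logp, 1, which.max)
  factor(classLevels[idx], levels = classLevels)
}

#' Per-layer trainable parameter counts
#'
#' @param config a \linkS4class{ModelConfig} (or an \linkS4class{STSAModel}).
#' @return data.frame with columns `layer` and `parameters`; the total is the
#'   column sum (see \code{\link{totalParameters}}).
#' @export
countParameters <- function(config) {
  if (is(config, "STSAModel")) config <- config@config
  H <- config@nChannels; Fn <- config@attMaps; K <- config@headMaps
  tk <- config@temporalKernel; P <- poolOutWidth(config); ncls <- config@nClasses
  data.frame(
    layer = c("spatialProjections", "temporalProjections", "lambda",
              "conv2", "conv3", "batchNorm", "conv4"),
    parameters = c(4L * Fn, 4L * Fn, 2L,
                   K * 3L * tk + K, K * K * H, 2L * K,
                   ncls * K * P + ncls))
}

#' @rdname countParameters
#' @export
totalParameters <- function(config) sum(countParameters(config)$parameters)

#' Architecture shape trace
#'
#' Computes the output dimensions of every stage of the two attention modules
#' and the classification head from the configuration arithmetic (nothing is
#' hard-coded), in the layout of the published architecture tables.
#'
#' @param config a \linkS4class{ModelConfig} (or an \linkS4class{STSAModel}).
#' @return data.frame with columns `module`, `stage`, `output` (dim string).
#' @export
shapeTrace <- function(config = modelConfig()) {
  if (is(config, "STSAModel")) config <- config@config
  H <- config@nChannels; W <- config@nSamples; Fn <- config@attMaps
  K <- config@headMaps; Wc <- convOutWidth(config); P <- poolOutWidth(config)
  ncls <- config@nClasses
  d <- function(...) paste0("(", paste(c(...), collapse = ", "), ")")
  rbind(
    data.frame(module = "spatial", stage = c("s11", "s12", "s21", "s22", "s3", "s4", "S"),
               output = c(d(Fn, H, W), d(Fn, H, W), d(H, Fn * W), d(Fn * W, H),
                          d(H, H), d(H, W), d(H, W))),
    data.frame(module = "temporal", stage = c("t11", "t12", "t21", "t22", "t3", "t4", "T"),
               output = c(d(Fn, H, W), d(Fn, H, W), d(W, Fn * H), d(Fn * H, W),
                          d(W, W), d(H, W), d(H, W))),
    data.frame(module = "head",
               stage = c("C1", "C2", "C3", "batchNorm", "square", "avgPool",
                         "log", "C5", "logSoftmax"),
               output = c(d(3, H, W), d(K, H, Wc), d(K, 1, Wc), d(K, 1, Wc),
                          d(K, 1, Wc), d(K, 1, P), d(K, 1, P), d(ncls, 1, 1),
                          d(ncls, 1, 1))))
}
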