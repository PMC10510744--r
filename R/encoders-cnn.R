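## Dilated convolutional encoding model, implemented directly on BLAS
## matrix operations: causal 1-D convolutions with ReLU activations and no
## hidden biases, plus a final linear projection (one head per electrode,
## the only biased layer). Hidden biases are omitted so the network's local
## linearization equals its input gradient exactly (see dstrf.R).

#' Construct a CNN architecture description
#'
#' Defaults reproduce the reference architecture: 5 layers, 128 kernels of
#' size 5, stride 1, no padding, dilations 1, 1, 2, 4, 8, giving a 65-sample
#' (650 ms at 100 Hz) receptive field.
#'
#' @param nLayers,nKernels,kernelSize,dilations,nFreq Architecture fields.
#' @return A [CnnConfig-class].
#' @export
cnnConfig <- function(nLayers = 5, nKernels = 128, kernelSize = 5,
                      dilations = c(1, 1, 2, 4, 8), nFreq = 23) {
  methods::new("CnnConfig", nLayers = as.integer(nLayers),
               nKernels = as.integer(nKernels),
               kernelSize = as.integer(kernelSize),
               dilations = as.integer(dilations), nFreq = as.integer(nFreq))
}

#' Receptive field of a dilated convolution stack
#'
#' Closed form: 1 + sum over layers of (kernelSize - 1) * dilation.
#'
#' @param config A [CnnConfig-class].
#' @return Receptive field length in input samples.
#' @export
receptiveField <- function(config) {
  1L + sum((config@kernelSize - 1L) * config@dilations)
}

#' Empirical receptive field by input perturbation
#'
#' Independently verifies the closed-form receptive field: using a network
#' with strictly positive weights (so every path is active under a positive
#' input), perturb single input samples increasingly far in the past and
#' find the farthest one that changes the output at a fixed time.
#'
#' @param config A [CnnConfig-class].
#' @param seed Seed for the probe network weights.
#' @return Receptive field length in samples, measured empirically.
#' @export
receptiveFieldProbe <- function(config, seed = 1) {
  set.seed(deriveSeed(seed, "rf-probe"))
  model <- initCnn(config, nElectrodes = 1L, seed = seed)
  model@convW <- lapply(model@convW, abs)
  model@outW <- abs(model@outW)
  maxRf <- receptiveField(config) + 8L
  X <- matrix(1, config@nFreq, maxRf + 4L)
  tOut <- ncol(X)
  y0 <- .cnnForward(model, X)$Y[1, tOut]
  influences <- vapply(0:(maxRf - 1L), function(k) {
    Xp <- X
    Xp[, tOut - k] <- Xp[, tOut - k] + 1
    abs(.cnnForward(model, Xp)$Y[1, tOut] - y0) > 1e-9
  }, TRUE)
  max(which(influences))
}

#' Initialize an untrained CNN
#'
#' He-scaled Gaussian weights, deterministic in the seed.
#'
#' @param config A [CnnConfig-class].
#' @param nElectrodes Number of output heads.
#' @param seed Integer seed.
#' @return A [CnnModel-class].
#' @export
initCnn <- function(config, nElectrodes, seed = 0) {
  set.seed(deriveSeed(seed, "cnn-init"))
  K <- config@nKernels
  ks <- config@kernelSize
  convW <- vector("list", config@nLayers)
  for (l in seq_len(config@nLayers)) {
    nin <- if (l == 1) config@nFreq else K
    convW[[l]] <- array(stats::rnorm(K * nin * ks, 0, sqrt(2 / (nin * ks))),
                        c(K, nin, ks))
  }
  outW <- matrix(stats::rnorm(nElectrodes * K, 0, sqrt(1 / K)),
                 nElectrodes, K)
  methods::new("CnnModel", config = config, convW = convW, outW = outW,
               outB = numeric(nElectrodes),
               inputCenter = numeric(config@nFreq),
               inputScale = rep(1, config@nFreq),
               trainLog = data.frame(), seed = as.integer(seed))
}

## Forward pass on a freq x time matrix (one contiguous chunk).
## Returns predictions and, optionally, per-layer activations and ReLU
## masks. The first receptiveField-1 columns are only valid as context.
.cnnForward <- function(model, X, withActs = FALSE, normalize = TRUE) {
  cfg <- model@config
  ks <- cfg@kernelSize
  H <- if (normalize) (X - model@inputCenter) / model@inputScale else X
  L <- ncol(H)
  acts <- if (withActs) vector("list", cfg@nLayers) else NULL
  Hs <- if (withActs) vector("list", cfg@nLayers + 1L) else NULL
  if (withActs) Hs[[1]] <- H
  for (l in seq_len(cfg@nLayers)) {
    d <- cfg@dilations[l]
    W <- model@convW[[l]]
    Z <- W[, , 1] %*% H
    for (j in seq_len(ks - 1L)) {
      sh <- j * d
      if (sh < L)
        .shiftAddRight(Z, W[, , j + 1L] %*% H, sh)
    }
    M <- Z > 0
    H <- Z * M
    if (withActs) {
      acts[[l]] <- M
      Hs[[l + 1L]] <- H
    }
  }
  Y <- model@outW %*% H + model@outB
  list(Y = Y, masks = acts, H = Hs)
}

#' Predict responses with a trained CNN
#'
#' @param model A [CnnModel-class].
#' @param stim [Spectrogram-class] or time x freq matrix.
#' @param chunks Optional list of contiguous sample-index vectors to predict
#'   separately (convolution does not cross chunk boundaries); default one
#'   chunk spanning the whole stimulus.
#' @return Electrodes x time matrix; samples without a full receptive field
#'   inside their chunk are NA.
#' @export
predictCnn <- function(model, stim, chunks = NULL) {
  X <- if (methods::is(stim, "Spectrogram")) t(stim@values) else
    t(as.matrix(stim))
  rf <- receptiveField(model@config)
  if (is.null(chunks)) chunks <- list(seq_len(ncol(X)))
  out <- matrix(NA_real_, nrow(model@outW), ncol(X))
  for (idx in chunks) {
    Y <- .cnnForward(model, X[, idx, drop = FALSE])$Y
    valid <- seq_along(idx) >= rf
    out[, idx[valid]] <- Y[, valid, drop = FALSE]
  }
  out
}

## Merge block index vectors into maximal contiguous chunks so that
## convolution context is preserved across adjacent training blocks.
.mergeChunks <- function(blocks) {
  idx <- sort(unique(unlist(blocks)))
  if (!length(idx)) return(list())
  brk <- c(0L, which(diff(idx) > 1L), length(idx))
  lapply(seq_len(length(brk) - 1L), function(i)
    idx[(brk[i] + 1L):brk[i + 1L]])
}

## One RAdam step over a flat list of parameter arrays.
.radamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  rhoInf <- 2 / (1 - beta2) - 1
  rhoT <- rhoInf - 2 * t * beta2^t / (1 - beta2^t)
  for (i in seq_along(params)) {
    g <- grads[[i]]
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * g
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * g^2
    mhat <- state$m[[i]] / (1 - beta1^t)
    if (rhoT > 5) {
      r <- sqrt(((rhoT - 4) * (rhoT - 2) * rhoInf) /
                  ((rhoInf - 4) * (rhoInf - 2) * rhoT))
      vhat <- sqrt(state$v[[i]] / (1 - beta2^t)) + eps
      params[[i]] <- params[[i]] - lr * r * mhat / vhat
    } else {
      params[[i]] <- params[[i]] - lr * mhat
    }
  }
  list(params = params, state = state)
}

#' Train the CNN encoder
#'
#' Minibatch training on contiguous time windows with mean-squared-error
#' loss averaged across electrodes, RAdam updates, an exponential
#' learning-rate schedule and L2 weight decay (conv and projection
#' weights; the bias is not decayed). Each minibatch is one `batchLen`
#' stretch of training samples together with its receptive-field context;
#' window order is reshuffled every epoch (deterministically in the seed).
#' When a validation block is supplied, early stopping keeps the
#' parameters of the best validation epoch.
#'
#' @param stim [Spectrogram-class] or time x freq matrix.
#' @param resp [ResponseMatrix-class] or electrodes x time matrix.
#' @param trainBlocks List of sample-index vectors used for training.
#' @param valBlock Optional sample-index vector for early stopping.
#' @param config A [CnnConfig-class].
#' @param lr Base learning rate (default 2e-3).
#' @param lrDecay Multiplicative per-epoch learning-rate decay
#'   (default 0.996).
#' @param weightDecay L2 weight decay coefficient (default 0.03).
#' @param epochs Maximum epochs (default 60).
#' @param patience Early-stopping patience in epochs (default 10).
#' @param batchLen Minibatch window length in samples (default 500).
#' @param emaDecay Per-epoch decay of the exponential moving average of
#'   the weights; the averaged weights (with bias correction) are what is
#'   validated and returned, which removes last-iterate minibatch jitter
#'   from the learned function. Set to 0 to return the raw final iterate.
#' @param seed Integer seed (initialization is deterministic in it).
#' @return A [CnnModel-class] with the training log attached.
#' @export
trainCnn <- function(stim, resp, trainBlocks, valBlock = NULL,
                     config = cnnConfig(), lr = 2e-3, lrDecay = 0.996,
                     weightDecay = 0.03, epochs = 60, patience = 10,
                     batchLen = 500, emaDecay = 0.9, seed = 0) {
  Xfull <- if (methods::is(stim, "Spectrogram")) t(stim@values) else
    t(as.matrix(stim))
  Y <- if (methods::is(resp, "ResponseMatrix")) resp@values else
    as.matrix(resp)
  rf <- receptiveField(config)
  chunks <- .mergeChunks(trainBlocks)
  if (!length(chunks)) stop("no training samples")

  trainIdx <- unlist(chunks)
  center <- rowMeans(Xfull[, trainIdx, drop = FALSE])
  scale <- pmax(apply(Xfull[, trainIdx, drop = FALSE], 1, stats::sd), 1e-6)

  model <- initCnn(config, nrow(Y), seed)
  model@inputCenter <- center
  model@inputScale <- scale
  ## start the output bias at the training-set mean response
  model@outB <- rowMeans(Y[, trainIdx, drop = FALSE])

  nL <- config@nLayers
  ks <- config@kernelSize
  params <- c(model@convW, list(model@outW, model@outB))
  state <- list(t = 0L, m = lapply(params, function(p) p * 0),
                v = lapply(params, function(p) p * 0))
  nE <- nrow(Y)

  ## minibatch windows: (chunk, loss-start, loss-end), context added below
  wins <- list()
  for (ci in seq_along(chunks)) {
    L <- length(chunks[[ci]])
    if (L < rf) next
    starts <- seq(rf, L, by = batchLen)
    for (st in starts) {
      wins[[length(wins) + 1L]] <- c(ci, st, min(st + batchLen - 1L, L))
    }
  }
  if (!length(wins)) stop("training chunks shorter than the receptive field")

  Xc <- lapply(chunks, function(ch) (Xfull[, ch, drop = FALSE] - center) / scale)
  Yc <- lapply(chunks, function(ch) Y[, ch, drop = FALSE])
  valChunk <- NULL
  if (!is.null(valBlock)) {
    vb <- sort(valBlock)
    valChunk <- list(X = (Xfull[, vb, drop = FALSE] - center) / scale,
                     Y = Y[, vb, drop = FALSE])
  }

  asModel <- function(params) {
    m <- model
    m@convW <- params[seq_len(nL)]
    m@outW <- params[[nL + 1L]]
    m@outB <- params[[nL + 2L]]
    m
  }
  evalLoss <- function(params, Xn, Yn) {
    fw <- .cnnForward(asModel(params), Xn, normalize = FALSE)
    valid <- seq_len(ncol(Xn)) >= rf
    mean((fw$Y[, valid, drop = FALSE] - Yn[, valid, drop = FALSE])^2)
  }

  best <- list(loss = Inf, params = params, epoch = 0L)
  log <- data.frame(epoch = integer(0), train = numeric(0), val = numeric(0))
  lrE <- lr
  ema <- lapply(params, function(p) p * 0)
  set.seed(deriveSeed(seed, "cnn-batches"))
  for (epoch in seq_len(epochs)) {
    sse <- 0
    nSeen <- 0L
    for (w in sample(wins)) {
      ci <- w[1]
      ctx0 <- w[2] - rf + 1L
      Xn <- Xc[[ci]][, ctx0:w[3], drop = FALSE]
      Yn <- Yc[[ci]][, ctx0:w[3], drop = FALSE]
      L <- ncol(Xn)
      nOut <- w[3] - w[2] + 1L
      fw <- .cnnForward(asModel(params), Xn, withActs = TRUE,
                        normalize = FALSE)
      err <- fw$Y - Yn
      err[, seq_len(L - nOut)] <- 0
      sse <- sse + sum(err^2)
      nSeen <- nSeen + nOut
      dY <- 2 * err / (nOut * nE)
      grads <- vector("list", nL + 2L)
      grads[[nL + 1L]] <- dY %*% t(fw$H[[nL + 1L]])
      grads[[nL + 2L]] <- rowSums(dY)
      dH <- crossprod(params[[nL + 1L]], dY)
      for (l in rev(seq_len(nL))) {
        d <- config@dilations[l]
        dZ <- dH * fw$masks[[l]]
        Hprev <- fw$H[[l]]
        W <- params[[l]]
        dHprev <- crossprod(W[, , 1], dZ)
        gW <- array(0, dim(W))
        gW[, , 1] <- tcrossprod(dZ, Hprev)
        for (j in seq_len(ks - 1L)) {
          sh <- j * d
          if (sh >= L) next
          dZs <- dZ[, (sh + 1L):L, drop = FALSE]
          gW[, , j + 1L] <- tcrossprod(dZs, Hprev[, 1:(L - sh), drop = FALSE])
          .shiftAddLeft(dHprev, crossprod(W[, , j + 1L], dZ), sh)
        }
        grads[[l]] <- gW
        dH <- dHprev
      }
      ## coupled L2 weight decay on weights (not the bias)
      for (i in seq_len(nL + 1L)) grads[[i]] <- grads[[i]] +
          weightDecay * params[[i]]
      upd <- .radamStep(params, grads, state, lrE)
      params <- upd$params
      state <- upd$state
    }
    trainLoss <- sse / (nSeen * nE)
    if (!is.finite(trainLoss))
      stop(sprintf("training diverged at epoch %d (loss = %g); lower lr",
                   epoch, trainLoss))
    lrE <- lrE * lrDecay

    ## bias-corrected EMA of the weights: the candidate model
    cand <- params
    if (emaDecay > 0) {
      for (i in seq_along(params)) {
        ema[[i]] <- emaDecay * ema[[i]] + (1 - emaDecay) * params[[i]]
      }
      corr <- 1 - emaDecay^epoch
      cand <- lapply(ema, function(p) p / corr)
    }

    valLoss <- NA_real_
    stopNow <- FALSE
    if (!is.null(valChunk)) {
      valLoss <- evalLoss(cand, valChunk$X, valChunk$Y)
      if (valLoss < best$loss - 1e-9) {
        best <- list(loss = valLoss, params = cand, epoch = epoch)
      } else if (epoch - best$epoch >= patience) {
        stopNow <- TRUE
      }
    }
    log <- rbind(log, data.frame(epoch = epoch, train = trainLoss,
                                 val = valLoss))
    if (stopNow) break
  }
  finalParams <- if (!is.null(valChunk) && is.finite(best$loss)) best$params
                 else cand
  model@convW <- finalParams[seq_len(nL)]
  model@outW <- finalParams[[nL + 1L]]
  model@outB <- finalParams[[nL + 2L]]
  model@trainLog <- log
  model
}
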