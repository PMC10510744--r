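## Linear STRF estimation: ridge regression on the lagged spectrogram
## design with block-wise cross-validated regularization. Per-block Gram
## matrices are computed once and summed per training subset, which makes
## the jackknife (many overlapping subsets) cheap.

#' Sample indices of each cross-validation block
#'
#' @param schedule A [NoiseSchedule-class].
#' @param rate Sampling rate in Hz.
#' @return List of integer vectors, one per block.
#' @export
blockIndices <- function(schedule, rate = 100) {
  b <- blockBounds(schedule)
  lapply(seq_len(length(b) - 1), function(i)
    (round(b[i] * rate) + 1L):round(b[i + 1] * rate))
}

## Lagged design matrix for the given absolute sample rows of X
## (time x freq). Column order is freq-major with lag fastest:
## col (f-1)*nLag + l holds X[row - l + 1, f]; lag 1 = current sample.
.laggedDesign <- function(X, rows, nLag) {
  nFreq <- ncol(X)
  D <- matrix(0, length(rows), nFreq * nLag)
  for (l in seq_len(nLag)) {
    D[, seq(l, by = nLag, length.out = nFreq)] <- X[rows - l + 1L, ]
  }
  D
}

## Valid training rows for one block: the full lag window must lie inside
## the block and, when a condition mask is given, inside that condition.
.validRows <- function(blockIdx, nLag, condVec = NULL, cond = NULL) {
  rows <- blockIdx[blockIdx >= blockIdx[1] + nLag - 1L]
  if (!is.null(cond)) {
    keep <- vapply(rows, function(t)
      all(condVec[(t - nLag + 1L):t] == cond), TRUE)
    rows <- rows[keep]
  }
  rows
}

## Per-block Gram matrices (with an unpenalized intercept column) and
## cross-products with the responses.
.strfBlockGrams <- function(X, Y, blocks, nLag, condVec = NULL, cond = NULL) {
  lapply(blocks, function(idx) {
    rows <- .validRows(idx, nLag, condVec, cond)
    if (length(rows) < nLag)
      stop("a block has fewer valid samples than the lag span")
    D <- cbind(1, .laggedDesign(X, rows, nLag))
    list(G = crossprod(D), C = crossprod(D, t(Y[, rows, drop = FALSE])),
         n = length(rows), rows = rows)
  })
}

## argmax of the CV curve; a flat/undefined curve (e.g. an all-zero
## response) falls back to the middle of the grid
.pickLambda <- function(lambdas, cvCorr) {
  idx <- which.max(cvCorr)
  if (!length(idx)) idx <- ceiling(length(lambdas) / 2)
  lambdas[idx]
}

.strfSolve <- function(grams, include, lambda) {
  G <- Reduce(`+`, lapply(grams[include], `[[`, "G"))
  C <- Reduce(`+`, lapply(grams[include], `[[`, "C"))
  p <- nrow(G)
  pen <- c(0, rep(lambda, p - 1L))  # intercept unpenalized
  ch <- chol(G + diag(pen))
  backsolve(ch, forwardsolve(t(ch), C))  # p x nElectrodes
}

.strfPredictRows <- function(X, rows, nLag, beta) {
  D <- cbind(1, .laggedDesign(X, rows, nLag))
  D %*% beta
}

#' Fit ridge STRFs with block-wise cross-validated regularization
#'
#' Regresses each electrode's response on the lagged spectrogram (the last
#' `nLag` samples of all bands) with an L2 penalty, the regularized
#' linear-Gaussian estimator family that normalized reverse correlation
#' also belongs to. The penalty is chosen by leave-one-block-out
#' cross-validated prediction correlation, averaged over electrodes. When
#' `condition` is given, only samples whose full lag window lies inside
#' that background condition are used (per-condition STRFs).
#'
#' @param stim [Spectrogram-class] or time x freq matrix.
#' @param resp [ResponseMatrix-class] or electrodes x time matrix.
#' @param blocks List of sample-index vectors (e.g. [blockIndices()]).
#' @param nLag Lag span in samples (default 65 = 650 ms at 100 Hz).
#' @param lambdas Candidate ridge penalties.
#' @param condition Optional condition label restricting the samples.
#' @param schedule Required with `condition`: the session's schedule.
#' @return A [StrfModel-class] for all electrodes.
#' @export
fitStrf <- function(stim, resp, blocks, nLag = 65,
                    lambdas = 10^seq(0, 4, by = 1), condition = NULL,
                    schedule = NULL) {
  X <- if (methods::is(stim, "Spectrogram")) stim@values else as.matrix(stim)
  Y <- if (methods::is(resp, "ResponseMatrix")) resp@values else as.matrix(resp)
  if (nrow(X) < nLag) stop("fewer samples than the lag span")
  rate <- if (methods::is(stim, "Spectrogram")) stim@rate else 100
  condVec <- NULL
  if (!is.null(condition)) {
    if (is.null(schedule)) stop("'schedule' is required with 'condition'")
    condVec <- conditionAt(schedule, (seq_len(nrow(X)) - 1) / rate)
  }
  grams <- .strfBlockGrams(X, Y, blocks, nLag, condVec, condition)
  nB <- length(grams)

  cvCorr <- vapply(lambdas, function(lam) {
    rs <- vapply(seq_len(nB), function(v) {
      beta <- .strfSolve(grams, setdiff(seq_len(nB), v), lam)
      pred <- .strfPredictRows(X, grams[[v]]$rows, nLag, beta)
      obs <- t(Y[, grams[[v]]$rows, drop = FALSE])
      mean(diag(suppressWarnings(stats::cor(pred, obs))), na.rm = TRUE)
    }, 0)
    mean(rs, na.rm = TRUE)
  }, 0)
  lambda <- .pickLambda(lambdas, cvCorr)
  beta <- .strfSolve(grams, seq_len(nB), lambda)
  .strfFromBeta(beta, ncol(X), nLag, lambda, lambdas, cvCorr)
}

.strfFromBeta <- function(beta, nFreq, nLag, lambda, lambdaGrid = lambda,
                          cvCorr = NA_real_) {
  nE <- ncol(beta)
  W <- array(0, c(nFreq, nLag, nE))
  for (e in seq_len(nE)) {
    W[, , e] <- t(matrix(beta[-1, e], nLag, nFreq))
  }
  methods::new("StrfModel", weights = W, bias = beta[1, ],
               lambda = lambda, lambdaGrid = lambdaGrid, cvCorr = cvCorr)
}

#' Predict responses from a fitted STRF model
#'
#' @param model A [StrfModel-class].
#' @param stim [Spectrogram-class] or time x freq matrix.
#' @return Electrodes x time prediction matrix (samples whose lag window
#'   precedes the stimulus use implicit zero padding).
#' @export
predictStrf <- function(model, stim) {
  X <- if (methods::is(stim, "Spectrogram")) stim@values else as.matrix(stim)
  nE <- dim(model@weights)[3]
  out <- matrix(0, nE, nrow(X))
  for (e in seq_len(nE)) {
    out[e, ] <- .lagDrive(X, model@weights[, , e]) + model@bias[e]
  }
  out
}
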