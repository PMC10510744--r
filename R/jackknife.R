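## Cross-validated jackknifing: for each held-out test block, B - 1 member
## models are trained, member m excluding the test block plus one further
## block; held-out predictions are the member mean. Model predictions may
## use stimulus context from before a block boundary (the stimulus is
## always observable; only responses are partitioned).

#' Jackknife-fit an encoding model family over all blocks
#'
#' @param stim [Spectrogram-class] (or time x freq matrix).
#' @param resp [ResponseMatrix-class] (or electrodes x time matrix).
#' @param blocks List of sample-index vectors (see [blockIndices()]).
#' @param fitter One of `"strf"`, `"cnn"`, `"stp"`.
#' @param seed Integer seed; member seeds are derived from it.
#' @param nLag STRF/STP lag span.
#' @param lambdas Ridge grid for the STRF (the penalty is selected once by
#'   block-wise cross-validation, then reused by every member).
#' @param config [CnnConfig-class] for the CNN fitter.
#' @param ... Further arguments passed to [trainCnn()] or [fitStp()].
#' @return A [JackknifeSet-class].
#' @export
jackknifeFit <- function(stim, resp, blocks, fitter = c("strf", "cnn", "stp"),
                         seed = 0, nLag = 65, lambdas = 10^seq(0, 4, by = 1),
                         config = cnnConfig(), ...) {
  fitter <- match.arg(fitter)
  nB <- length(blocks)
  if (nB < 3) stop("jackknifing needs at least 3 blocks")
  X <- if (methods::is(stim, "Spectrogram")) stim@values else as.matrix(stim)
  Y <- if (methods::is(resp, "ResponseMatrix")) resp@values else
    as.matrix(resp)
  nE <- nrow(Y)
  predictions <- matrix(NA_real_, nE, nrow(X))

  grams <- NULL
  lambda <- NULL
  if (fitter %in% c("strf", "stp")) {
    grams <- .strfBlockGrams(X, Y, blocks, nLag)
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
  }

  ensembles <- vector("list", nB)
  for (v in seq_len(nB)) {
    others <- setdiff(seq_len(nB), v)
    members <- vector("list", length(others))
    memberPred <- 0
    for (mi in seq_along(others)) {
      m <- others[mi]
      trainSet <- setdiff(others, m)
      mSeed <- deriveSeed(seed, sprintf("jk-%s-test%d-member%d", fitter, v, m))
      model <- switch(fitter,
        strf = {
          beta <- .strfSolve(grams, trainSet, lambda)
          .strfFromBeta(beta, ncol(X), nLag, lambda, lambdas, NA_real_)
        },
        cnn = trainCnn(X, Y, trainBlocks = blocks[trainSet],
                       valBlock = blocks[[m]], config = config,
                       seed = mSeed, ...),
        stp = {
          beta <- .strfSolve(grams, trainSet, lambda)
          init <- .strfFromBeta(beta, ncol(X), nLag, lambda)
          fitStp(X, Y, blocks[trainSet], nLag = nLag, seed = mSeed,
                 strfInit = init, ...)
        })
      members[[mi]] <- model
      memberPred <- memberPred +
        .predictOnBlock(model, fitter, X, blocks[[v]], nLag, config)
    }
    ensembles[[v]] <- methods::new("JackknifeEnsemble",
                                   testBlock = as.integer(v),
                                   members = members,
                                   heldOutBlocks = as.integer(others),
                                   fitter = fitter)
    predictions[, blocks[[v]]] <- memberPred / length(others)
  }
  methods::new("JackknifeSet", ensembles = ensembles,
               predictions = predictions, fitter = fitter, blocks = blocks)
}

## Predict one model on the sample rows of a block, using pre-block
## stimulus context so every block sample is scored.
.predictOnBlock <- function(model, fitter, X, idx, nLag, config) {
  switch(fitter,
    strf = t(.strfPredictRows(X, idx, nLag,
                              rbind(model@bias,
                                    .strfBetaFromModel(model)))),
    cnn = {
      rf <- receptiveField(model@config)
      ctx <- max(1L, idx[1] - rf + 1L):idx[length(idx)]
      pred <- .cnnForward(model, t(X[ctx, , drop = FALSE]))$Y
      keep <- match(idx, ctx)
      pred[, keep, drop = FALSE]
    },
    stp = {
      do.call(rbind, lapply(model, function(mm)
        stpForward(mm, X)[idx]))
    })
}

.strfBetaFromModel <- function(model) {
  d <- dim(model@weights)
  vapply(seq_len(d[3]), function(e) as.numeric(t(model@weights[, , e])),
         numeric(d[1] * d[2]))
}

#' Ensemble prediction for one held-out block
#'
#' The test-block prediction is defined as the arithmetic mean of the
#' member model predictions.
#'
#' @param ensemble A [JackknifeEnsemble-class].
#' @param stim Stimulus [Spectrogram-class] or matrix.
#' @param idx Sample indices of the ensemble's test block.
#' @param nLag Lag span for STRF/STP members.
#' @return Electrodes x length(idx) prediction matrix.
#' @export
ensemblePredict <- function(ensemble, stim, idx, nLag = 65) {
  X <- if (methods::is(stim, "Spectrogram")) stim@values else as.matrix(stim)
  preds <- lapply(ensemble@members, function(m)
    .predictOnBlock(m, ensemble@fitter, X, idx, nLag, NULL))
  Reduce(`+`, preds) / length(preds)
}

#' Correlation split into adaptation period and remainder
#'
#' Pearson correlation between prediction and response per electrode,
#' computed over (a) all scored samples, (b) the adaptation period (the
#' first `adaptationWindow` seconds after any background transition, the
#' transition sample included), and (c) the complement, overall and within
#' each background condition (samples belong to the post-transition
#' condition).
#'
#' @param pred,actual Electrodes x time matrices (NA-prediction samples are
#'   excluded from scoring).
#' @param schedule A [NoiseSchedule-class].
#' @param adaptationWindow Adaptation window length in seconds
#'   (default 0.65).
#' @param rate Sampling rate in Hz.
#' @return data.frame with electrode, condition (`"all"` plus each
#'   condition present), `full_r`, `adaptation_r`, `remainder_r` and sample
#'   counts.
#' @export
evaluateSplitCorrelation <- function(pred, actual, schedule,
                                     adaptationWindow = 0.65, rate = 100) {
  stopifnot(all(dim(pred) == dim(actual)))
  nT <- ncol(pred)
  tSec <- (seq_len(nT) - 1) / rate
  condVec <- conditionAt(schedule, tSec)
  scored <- !is.na(condVec) & apply(!is.na(pred), 2, all)

  winLen <- round(adaptationWindow * rate)
  adapt <- logical(nT)
  trIdx <- round(transitions(schedule)$time * rate) + 1L
  for (s in trIdx) {
    adapt[s:min(nT, s + winLen - 1L)] <- TRUE
  }

  safeCor <- function(a, b) {
    if (length(a) < 3) return(NA_real_)
    suppressWarnings(stats::cor(a, b))
  }
  if (sum(scored & adapt) < 3 && any(scored))
    stop("adaptation window holds fewer than 3 scored samples")

  conds <- c("all", sort(unique(condVec[scored])))
  out <- do.call(rbind, lapply(seq_len(nrow(pred)), function(e) {
    do.call(rbind, lapply(conds, function(cc) {
      inC <- scored & (cc == "all" | (!is.na(condVec) & condVec == cc))
      data.frame(electrode = e, condition = cc,
                 full_r = safeCor(pred[e, inC], actual[e, inC]),
                 adaptation_r = safeCor(pred[e, inC & adapt],
                                        actual[e, inC & adapt]),
                 remainder_r = safeCor(pred[e, inC & !adapt],
                                       actual[e, inC & !adapt]),
                 n_adaptation = sum(inC & adapt),
                 n_remainder = sum(inC & !adapt),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}
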