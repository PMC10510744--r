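## Dynamic STRF extraction. A ReLU network without hidden biases is
## piecewise linear: for each input window it implements one exact linear
## filter, equal to the gradient of the output with respect to the input.
## The gradient is computed here by reverse-mode accumulation through the
## frozen ReLU activation pattern, vectorized over many time frames at
## once: the backward state is kept per (layer, time-offset) so that each
## weight-matrix product applies to all requested frames simultaneously.

## Offsets (in samples, relative to the output time) reachable at the
## pre-activation of each layer, walking down from the output.
.dstrfOffsets <- function(config) {
  offs <- list()
  cur <- 0L
  for (l in rev(seq_len(config@nLayers))) {
    offs[[l + 1L]] <- cur  # offsets at z_{l} level before stepping down
    cur <- sort(unique(as.integer(outer(cur,
      (0:(config@kernelSize - 1L)) * config@dilations[l], `+`))))
  }
  offs[[1L]] <- cur  # input-level offsets (= 0 .. RF-1)
  offs
}

## Member dSTRF frames for selected electrodes at selected output samples.
## X is the raw stimulus (freq x time); masks are taken from one forward
## pass under the model's own input normalization. Returns a list (one
## entry per electrode) of arrays (frame x freq x lag); lag 1 = current
## sample. `rawUnits` converts from normalized-input to raw spectrogram
## units (divide by the per-band training scale).
.dstrfMemberFrames <- function(model, X, frames, electrodes,
                               rawUnits = TRUE, masks = NULL) {
  cfg <- model@config
  rf <- receptiveField(cfg)
  ks <- cfg@kernelSize
  nL <- cfg@nLayers
  frames <- as.integer(frames)
  if (any(frames < rf) || any(frames > ncol(X)))
    stop("frames must lie in [receptiveField, nSamples]")
  if (is.null(masks))
    masks <- .cnnForward(model, X, withActs = TRUE)$masks
  Wt <- lapply(seq_len(nL), function(l)
    lapply(seq_len(ks), function(j) t(model@convW[[l]][, , j])))
  nFq <- cfg@nFreq
  nFr <- length(frames)

  out <- vector("list", length(electrodes))
  for (ei in seq_along(electrodes)) {
    e <- electrodes[ei]
    G <- list(`0` = model@outW[e, ] * masks[[nL]][, frames, drop = FALSE])
    for (l in rev(seq_len(nL))) {
      d <- cfg@dilations[l]
      acc <- list()
      for (oName in names(G)) {
        o <- as.integer(oName)
        Go <- G[[oName]]
        for (j in seq_len(ks)) {
          o2 <- as.character(o + (j - 1L) * d)
          contrib <- Wt[[l]][[j]] %*% Go
          if (is.null(acc[[o2]])) acc[[o2]] <- contrib
          else acc[[o2]] <- acc[[o2]] + contrib
        }
      }
      if (l > 1L) {
        Ml <- masks[[l - 1L]]
        G <- lapply(stats::setNames(names(acc), names(acc)), function(o2) {
          acc[[o2]] * Ml[, frames - as.integer(o2), drop = FALSE]
        })
      } else {
        D <- array(0, c(nFr, nFq, rf))
        for (o2 in names(acc)) {
          D[, , as.integer(o2) + 1L] <- t(acc[[o2]])
        }
        if (rawUnits) {
          D <- sweep(D, 2L, model@inputScale, `/`)
        }
        out[[ei]] <- D
      }
    }
  }
  out
}

#' Instantaneous equivalent linear filter (dSTRF) of a CNN at one window
#'
#' Computes the exact input gradient of each electrode's output for the
#' given input window, which for a bias-free ReLU network is the complete
#' local linearization: sum(dSTRF * input) + final bias reproduces the
#' forward output exactly (up to floating-point error).
#'
#' @param model A [CnnModel-class] (hidden layers must be bias-free; this
#'   architecture enforces that).
#' @param xWindow Input window, freq x receptiveField matrix (raw stimulus
#'   units), whose last column is the predicted sample.
#' @param electrodes Electrode indices (default all).
#' @param rawUnits If TRUE (default FALSE), return the gradient with
#'   respect to the raw spectrogram; by default it is with respect to the
#'   network's normalized input, the units in which the linearity identity
#'   sum(dSTRF * normalizedInput) + bias == output holds exactly.
#' @return A freq x lag matrix (lag 1 = the current sample, increasing into
#'   the past) for one electrode, or a list of them.
#' @export
computeDstrf <- function(model, xWindow, electrodes = NULL,
                         rawUnits = FALSE) {
  rf <- receptiveField(model@config)
  xWindow <- as.matrix(xWindow)
  if (ncol(xWindow) != rf)
    stop(sprintf("xWindow must have %d columns (the receptive field)", rf))
  if (is.null(electrodes)) electrodes <- seq_len(nrow(model@outW))
  fr <- .dstrfMemberFrames(model, xWindow, frames = rf,
                           electrodes = electrodes, rawUnits = rawUnits)
  ## frame arrays are (1 x freq x lag): time-into-past lag ordering
  out <- lapply(fr, function(D) {
    M <- D[1, , ]
    dim(M) <- dim(D)[2:3]
    M
  })
  if (length(out) == 1L) out[[1L]] else out
}

#' Verify the local-linearity identity of a dSTRF frame
#'
#' @param model A [CnnModel-class].
#' @param xWindow Freq x receptiveField input window (raw units).
#' @return data.frame per electrode with the forward output, the linearized
#'   reconstruction sum(dSTRF * normalizedInput) + bias, and their relative
#'   difference.
#' @export
dstrfLinearityCheck <- function(model, xWindow) {
  rf <- receptiveField(model@config)
  xn <- (as.matrix(xWindow) - model@inputCenter) / model@inputScale
  fw <- .cnnForward(model, xn, normalize = FALSE)
  y <- fw$Y[, rf]
  ## lagged view of the window: lag l = column rf - l + 1
  xLag <- xn[, rf:1, drop = FALSE]
  ds <- computeDstrf(model, xWindow)
  if (!is.list(ds)) ds <- list(ds)
  lin <- vapply(seq_along(ds), function(e)
    sum(ds[[e]] * xLag) + model@outB[e], 0)
  data.frame(electrode = seq_along(ds), forward = y, linearized = lin,
             relDiff = abs(lin - y) / pmax(abs(y), 1e-12))
}

#' Average member dSTRF frames under the sign-consistency mask
#'
#' Bin-wise: if at least `minAgree` members agree on a strict sign (zeros
#' count toward neither sign), the output is the mean over all members;
#' otherwise it is exactly zero.
#'
#' @param memberFrames List of equally-shaped arrays or matrices, one per
#'   jackknife member.
#' @param minAgree Minimum number of sign-agreeing members.
#' @return The masked average, same shape as the inputs.
#' @export
averageAndMask <- function(memberFrames, minAgree) {
  if (!length(memberFrames)) stop("empty member list")
  if (minAgree > length(memberFrames))
    stop("minAgree cannot exceed the number of members")
  avg <- Reduce(`+`, memberFrames) / length(memberFrames)
  pos <- Reduce(`+`, lapply(memberFrames, function(f) f > 0))
  neg <- Reduce(`+`, lapply(memberFrames, function(f) f < 0))
  avg * ((pos >= minAgree) | (neg >= minAgree))
}

#' Default sign-consistency threshold for an ensemble of M members
#'
#' Scales the reference rule (15 agreeing members out of 17) to reduced
#' ensembles: ceiling(M * 15 / 17).
#'
#' @param nMembers Number of jackknife members.
#' @return Integer threshold.
#' @export
defaultMaskThreshold <- function(nMembers) {
  as.integer(ceiling(nMembers * 15 / 17))
}

#' Masked jackknife-averaged dSTRF time course
#'
#' For each requested output sample of the ensemble's test block, computes
#' every member's dSTRF, averages them and applies the sign-consistency
#' mask, per electrode.
#'
#' @param ensemble A [JackknifeEnsemble-class] with CNN members.
#' @param stim Session stimulus ([Spectrogram-class] or time x freq
#'   matrix); member dSTRFs may use stimulus context from before the test
#'   block.
#' @param frames Integer sample indices (on the stimulus timeline) of the
#'   frames to compute; all must admit a full receptive field. Defaults to
#'   every valid sample of `blockIdx`.
#' @param blockIdx Sample indices of the ensemble's test block (used for
#'   the default `frames`).
#' @param electrodes Electrode indices (default all).
#' @param minAgree Sign-consistency threshold; default
#'   [defaultMaskThreshold()] of the member count.
#' @param rawUnits Return frames in raw spectrogram units (default TRUE;
#'   members are converted before averaging so their units agree).
#' @return List of [DstrfTensor-class] objects, one per electrode.
#' @export
dstrfTimecourse <- function(ensemble, stim, frames = NULL, blockIdx = NULL,
                            electrodes = NULL, minAgree = NULL,
                            rawUnits = TRUE) {
  if (ensemble@fitter != "cnn")
    stop("dSTRFs are defined for the CNN fitter")
  X <- if (methods::is(stim, "Spectrogram")) t(stim@values) else
    t(as.matrix(stim))
  members <- ensemble@members
  M <- length(members)
  rf <- receptiveField(members[[1L]]@config)
  if (is.null(frames)) {
    if (is.null(blockIdx)) stop("supply frames or blockIdx")
    frames <- blockIdx[blockIdx >= blockIdx[1] + rf - 1L]
  }
  frames <- as.integer(frames)
  if (is.null(electrodes)) electrodes <- seq_len(nrow(members[[1L]]@outW))
  if (is.null(minAgree)) minAgree <- defaultMaskThreshold(M)

  memberMasks <- lapply(members, function(m)
    .cnnForward(m, X, withActs = TRUE)$masks)

  out <- vector("list", length(electrodes))
  for (ei in seq_along(electrodes)) {
    e <- electrodes[ei]
    frs <- lapply(seq_len(M), function(mi)
      .dstrfMemberFrames(members[[mi]], X, frames, e, rawUnits = rawUnits,
                         masks = memberMasks[[mi]])[[1L]])
    masked <- averageAndMask(frs, minAgree)
    out[[ei]] <- methods::new("DstrfTensor", frames = masked,
                              times = frames, electrode = as.integer(e),
                              maskThreshold = as.integer(minAgree),
                              nMembers = as.integer(M))
  }
  names(out) <- as.character(electrodes)
  out
}
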