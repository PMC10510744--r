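## Adaptation quantities: stimulus contrast, dSTRF gain, noise-spectrum
## correlation, transition alignment, and the paired-t indices
## (gain-change, noise-filtering, adaptation).

#' Spectro-temporal contrast of a stimulus segment
#'
#' Defined as the (population) standard deviation of all time-frequency
#' bins of the segment, reported in dB (20 * log10), floored at -120 dB
#' for degenerate constant segments.
#'
#' @param segment [Spectrogram-class] or time x freq matrix.
#' @return Contrast in dB.
#' @export
stimulusContrast <- function(segment) {
  X <- if (methods::is(segment, "Spectrogram")) segment@values else
    as.matrix(segment)
  if (!length(X)) stop("empty segment")
  s <- .popSd(X)
  if (s <= 10^(-120 / 20)) return(-120)
  20 * log10(s)
}

#' Gain of a dSTRF frame
#'
#' Standard deviation of the lag-frequency filter bins; for the excitatory
#' (inhibitory) region all negative (positive) bins are set to zero first
#' and the zeros stay in the population.
#'
#' @param frame Freq x lag matrix (or any array of filter bins).
#' @param region `"full"`, `"excitatory"` or `"inhibitory"`.
#' @return Nonnegative gain value.
#' @export
dstrfGain <- function(frame, region = c("full", "excitatory", "inhibitory")) {
  region <- match.arg(region)
  x <- as.numeric(frame)
  x <- switch(region, full = x, excitatory = pmax(x, 0),
              inhibitory = pmin(x, 0))
  .popSd(x)
}

#' Correlation of a dSTRF frame's frequency profile with a target spectrum
#'
#' Averages the (region-zeroed) filter over lags and correlates the
#' resulting frequency profile with the target spectrum (e.g. the incoming
#' noise class's mean spectrum, or the clean-speech average spectrum for
#' transitions to clean). A constant lag-averaged profile (e.g. a fully
#' masked frame) yields NA, flagged rather than silently zeroed.
#'
#' @param frame Freq x lag matrix.
#' @param targetSpectrum Numeric vector over the frequency bands.
#' @param region `"full"`, `"excitatory"` or `"inhibitory"`.
#' @return Pearson correlation, or NA when undefined.
#' @export
noiseSpectrumCorrelation <- function(frame, targetSpectrum,
                                     region = c("full", "excitatory",
                                                "inhibitory")) {
  region <- match.arg(region)
  frame <- as.matrix(frame)
  if (length(targetSpectrum) != nrow(frame))
    stop("targetSpectrum length must equal the number of frequency bands")
  F <- switch(region, full = frame, excitatory = pmax(frame, 0),
              inhibitory = pmin(frame, 0))
  profile <- rowMeans(F)
  if (stats::sd(profile) < 1e-14 || stats::sd(targetSpectrum) < 1e-14)
    return(NA_real_)
  stats::cor(profile, targetSpectrum)
}

#' Session-average clean-speech spectrum
#'
#' Time-average of the foreground-only spectrogram over the stimulus part
#' of the session (the lead-in is excluded; silent gaps are included).
#' Used as the correlation target for transitions to a clean background.
#'
#' @param session A [SessionData-class].
#' @return Numeric vector over frequency bands.
#' @export
cleanSpeechSpectrum <- function(session) {
  rate <- session@foreground@rate
  lead <- round(session@schedule@leadIn * rate)
  X <- session@foreground@values
  colMeans(X[(lead + 1):nrow(X), , drop = FALSE])
}

#' Qualifying background transitions
#'
#' @param schedule A [NoiseSchedule-class].
#' @param filter `"clean_noise"` keeps clean-to-noise and noise-to-clean
#'   transitions only (the baseline-controlled set used for the gain and
#'   noise-filtering time courses); `"all"` keeps every transition;
#'   `"to_noise_from_clean"`, `"to_clean"` select one direction.
#' @return data.frame `time`, `from`, `to`.
#' @export
qualifyingTransitions <- function(schedule,
                                  filter = c("clean_noise", "all",
                                             "to_noise_from_clean",
                                             "to_clean")) {
  filter <- match.arg(filter)
  tr <- transitions(schedule)
  keep <- switch(filter,
    all = rep(TRUE, nrow(tr)),
    clean_noise = tr$from == "clean" | tr$to == "clean",
    to_noise_from_clean = tr$from == "clean" & tr$to != "clean",
    to_clean = tr$to == "clean")
  tr[keep, , drop = FALSE]
}

#' Align a time course to background transitions
#'
#' Extracts windows [-pre, +post) seconds around each qualifying
#' transition (the transition sample belongs to the post condition).
#' Windows that would extend beyond the adjoining segments (pre window
#' before the preceding segment's start, post window past the following
#' segment's end) are excluded so every aligned sample sits in the
#' condition it is attributed to.
#'
#' @param timecourse Numeric vector on the session timeline (NA allowed).
#' @param schedule A [NoiseSchedule-class].
#' @param filter Transition filter (see [qualifyingTransitions()]).
#' @param pre,post Window extent in seconds.
#' @param rate Sampling rate in Hz.
#' @param toCondition Optional single condition label: keep only
#'   transitions into it.
#' @return List with `values` (transitions x samples matrix), `time`
#'   (relative seconds per column), and the transition table; transitions
#'   x 0 matrix if none qualify.
#' @export
alignToTransitions <- function(timecourse, schedule, filter = "clean_noise",
                               pre = 0.5, post = 1.15, rate = 100,
                               toCondition = NULL) {
  tr <- qualifyingTransitions(schedule, filter)
  if (!is.null(toCondition)) tr <- tr[tr$to == toCondition, , drop = FALSE]
  segs <- segments(schedule)
  nPre <- round(pre * rate)
  nPost <- round(post * rate)
  keep <- logical(nrow(tr))
  for (i in seq_len(nrow(tr))) {
    t0 <- tr$time[i]
    segPre <- segs[abs(segs$end - t0) < 1e-9, , drop = FALSE]
    segPost <- segs[abs(segs$start - t0) < 1e-9, , drop = FALSE]
    okPre <- nrow(segPre) == 1 && (t0 - pre) >= segPre$start[1] - 1e-9
    okPost <- nrow(segPost) == 1 && (t0 + post) <= segPost$end[1] + 1e-9
    keep[i] <- okPre && okPost
  }
  tr <- tr[keep, , drop = FALSE]
  relIdx <- seq(-nPre, nPost - 1L)
  vals <- matrix(NA_real_, nrow(tr), length(relIdx))
  for (i in seq_len(nrow(tr))) {
    s0 <- round(tr$time[i] * rate) + 1L  # transition sample
    idx <- s0 + relIdx
    ok <- idx >= 1 & idx <= length(timecourse)
    vals[i, ok] <- timecourse[idx[ok]]
  }
  list(values = vals, time = relIdx / rate, transitions = tr)
}

#' Paired t statistic between positionally-paired windows
#'
#' The adaptation indices are paired t statistics over within-window
#' positions of a transition-averaged time course: position i of the
#' pre-transition window is paired with position i of the post-adaptation
#' window. Positive means post > pre. Pairs with a missing member are
#' dropped; if fewer than half the pairs remain (or fewer than 3), the
#' index is NA. A degenerate zero-variance nonzero difference is capped at
#' +/- 1e6.
#'
#' @param preValues,postValues Equal-length numeric vectors.
#' @return The paired t statistic (possibly NA or capped).
#' @export
indexTtest <- function(preValues, postValues) {
  if (length(preValues) != length(postValues))
    stop("pre and post windows must have equal length")
  ok <- is.finite(preValues) & is.finite(postValues)
  if (sum(ok) < max(3L, ceiling(length(preValues) / 2)))
    return(NA_real_)
  d <- postValues[ok] - preValues[ok]
  sdd <- stats::sd(d)
  if (sdd < 1e-12) {
    m <- mean(d)
    if (abs(m) < 1e-12) return(0)
    return(sign(m) * 1e6)
  }
  unname(stats::t.test(postValues[ok], preValues[ok], paired = TRUE)$statistic)
}

## Positional means over a window of a transition-aligned matrix.
.windowPositions <- function(aligned, from, to, rate = 100) {
  idx <- which(aligned$time >= from - 1e-9 & aligned$time < to - 1e-9)
  colMeans(aligned$values[, idx, drop = FALSE], na.rm = TRUE)
}

#' Gain-change index
#'
#' Paired t statistic between the transition-averaged dSTRF gain 0.5-0 s
#' before and 0.65-1.15 s after a transition (the first window after the
#' adaptation period). Positive = the gain increased.
#'
#' @param aligned Output of [alignToTransitions()] on a gain time course
#'   (window at least [-0.5, 1.15)).
#' @param rate Sampling rate in Hz.
#' @return The index (a t statistic), NA when coverage is insufficient.
#' @export
gainChangeIndex <- function(aligned, rate = 100) {
  pre <- .windowPositions(aligned, -0.5, 0, rate)
  post <- .windowPositions(aligned, 0.65, 1.15, rate)
  indexTtest(pre, post)
}

#' Noise-filtering index
#'
#' Same windows as [gainChangeIndex()], applied to the time course of
#' correlation between the (region-zeroed) lag-averaged dSTRF and the
#' incoming background spectrum, with the sign flipped: positive = the
#' correlation decreased, i.e. the filter steered away from the new noise.
#'
#' @param aligned Output of [alignToTransitions()] on a correlation time
#'   course.
#' @param rate Sampling rate in Hz.
#' @return The index (a t statistic), NA when coverage is insufficient.
#' @export
noiseFilteringIndex <- function(aligned, rate = 100) {
  pre <- .windowPositions(aligned, -0.5, 0, rate)
  post <- .windowPositions(aligned, 0.65, 1.15, rate)
  indexTtest(post, pre)  # flipped: positive = correlation dropped
}

#' Adaptation index of an electrode's response
#'
#' Paired t statistic comparing the transition-averaged neural response
#' 0-0.7 s versus 2-2.7 s after background transitions; positive = a
#' larger transient that falls back toward baseline. Transitions whose
#' following segment is shorter than 2.7 s (the 3-s segments) are excluded
#' and counted. The per-electrode summary is the mean over the four
#' to-conditions.
#'
#' @param response Numeric response vector on the session timeline.
#' @param schedule A [NoiseSchedule-class].
#' @param rate Sampling rate in Hz.
#' @return List with `byCondition` (named index per to-condition),
#'   `index` (their mean), and `nExcluded` (transitions lacking the late
#'   window).
#' @export
adaptationIndex <- function(response, schedule, rate = 100) {
  tr <- transitions(schedule)
  segs <- segments(schedule)
  segLen <- segs$end - segs$start
  postLen <- segLen[match(tr$time, segs$start)]
  ## 3-s segments are excluded: their late window would abut the next
  ## transition; in practice only the 6-s segments qualify
  usable <- postLen > 3 + 1e-9
  conds <- sort(unique(tr$to))
  byCond <- stats::setNames(rep(NA_real_, length(conds)), conds)
  for (cc in conds) {
    sel <- usable & tr$to == cc
    if (!any(sel)) next
    al <- list(time = seq(0, 2.7, by = 1 / rate)[-(round(2.7 * rate) + 1)],
               values = NULL)
    relIdx <- seq(0L, round(2.7 * rate) - 1L)
    vals <- matrix(NA_real_, sum(sel), length(relIdx))
    times <- tr$time[sel]
    for (i in seq_along(times)) {
      s0 <- round(times[i] * rate) + 1L
      idx <- s0 + relIdx
      ok <- idx <= length(response)
      vals[i, ok] <- response[idx[ok]]
    }
    al$values <- vals
    early <- .windowPositions(al, 0, 0.7, rate)
    late <- .windowPositions(al, 2, 2.7, rate)
    byCond[cc] <- indexTtest(late, early)  # positive = early > late
  }
  list(byCondition = byCond, index = mean(byCond, na.rm = TRUE),
       nExcluded = sum(!usable))
}

#' Gain and correlation time courses of a masked dSTRF tensor
#'
#' Expands a [DstrfTensor-class] into full-session time courses (NA where
#' no frame was computed): the three region gains and, per target
#' spectrum, the three region correlation series.
#'
#' @param tensor A [DstrfTensor-class].
#' @param nSamples Session length in samples.
#' @param targets Named list of target spectra (e.g. noise class mean
#'   spectra plus `clean`).
#' @return List with `gain` (nSamples x 3 matrix, columns
#'   full/excitatory/inhibitory) and `corr` (named list of such matrices,
#'   one per target).
#' @export
dstrfSeries <- function(tensor, nSamples, targets = list()) {
  regions <- c("full", "excitatory", "inhibitory")
  fr <- tensor@frames
  d <- dim(fr)
  nFr <- d[1]; nF <- d[2]; nL <- d[3]
  times <- tensor@times

  rowPopSd <- function(M) {
    mu <- rowMeans(M)
    sqrt(pmax(rowMeans(M^2) - mu^2, 0))
  }
  ## lag-averaged frequency profiles per frame, nFr x nF
  lagAvg <- function(arr) matrix(rowMeans(matrix(arr, nFr * nF, nL)),
                                 nFr, nF)
  rowCor <- function(P, target) {
    cen <- P - rowMeans(P)
    tc <- target - mean(target)
    den <- sqrt(rowSums(cen^2) * sum(tc^2))
    r <- as.numeric(cen %*% tc) / den
    r[den < 1e-14 | rowSums(cen^2) < 1e-24] <- NA_real_
    r
  }

  regionArr <- list(full = fr, excitatory = pmax(fr, 0),
                    inhibitory = pmin(fr, 0))
  gain <- matrix(NA_real_, nSamples, 3, dimnames = list(NULL, regions))
  corr <- lapply(targets, function(tt)
    matrix(NA_real_, nSamples, 3, dimnames = list(NULL, regions)))
  for (r in 1:3) {
    A <- regionArr[[r]]
    gain[times, r] <- rowPopSd(matrix(A, nFr, nF * nL))
    P <- lagAvg(A)
    for (nm in names(targets)) {
      corr[[nm]][times, r] <- rowCor(P, targets[[nm]])
    }
  }
  list(gain = gain, corr = corr)
}
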