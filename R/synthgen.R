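## Synthetic switching-noise sessions with ground-truth adaptive encoders.
## Everything is generated directly in the 23-band spectrogram domain at
## 100 Hz; there is no audio stage.

.CONDITIONS <- c("clean", "bar", "city", "jet")

## Smooth nonnegative spectral bump over the band axis.
.bandBump <- function(nFreq, center, width) {
  f <- seq_len(nFreq)
  exp(-(f - center)^2 / (2 * width^2))
}

#' Construct the three background-noise classes
#'
#' Returns three spectrally distinct noise classes modeled on typical
#' ambient categories: a low-frequency, speech-overlapping class (`bar`),
#' a broadband nonstationary class (`city`), and a high-frequency, highly
#' stationary class (`jet`, > 70% of its power in the top third of the
#' bands). Class spectra are jittered deterministically by the seed and
#' normalized to unit total power; pairwise spectral correlations are below
#' 0.8 by construction.
#'
#' @param seed Integer seed.
#' @param nFreq Number of frequency bands (default 23).
#' @return Named list of [NoiseClassSpec-class] objects
#'   (`bar`, `city`, `jet`).
#' @export
makeNoiseClasses <- function(seed = 0, nFreq = 23) {
  set.seed(deriveSeed(seed, "noise-classes"))
  jitter <- function(x) x * exp(stats::rnorm(nFreq, 0, 0.05))
  bar <- jitter(.bandBump(nFreq, center = 0.2 * nFreq, width = 0.13 * nFreq) +
                  0.05)
  city <- jitter(0.85 - 0.35 * (seq_len(nFreq) - 1) / (nFreq - 1) +
                   0.25 * .bandBump(nFreq, 0.55 * nFreq, 0.2 * nFreq))
  jet <- jitter(.bandBump(nFreq, center = 0.88 * nFreq, width = 0.08 * nFreq) +
                  0.02)
  norm1 <- function(x) x / sum(x)
  specs <- list(
    bar = methods::new("NoiseClassSpec", label = "bar",
                       meanSpectrum = norm1(bar), stationarity = 0.35),
    city = methods::new("NoiseClassSpec", label = "city",
                        meanSpectrum = norm1(city), stationarity = 0.2),
    jet = methods::new("NoiseClassSpec", label = "jet",
                       meanSpectrum = norm1(jet), stationarity = 0.95)
  )
  specs
}

#' Generate a speech-like foreground spectrogram
#'
#' Emulates the spectro-temporal statistics of read speech that matter for
#' the downstream models: two to three formant-like spectral peaks drifting
#' slowly in frequency, a temporal envelope whose modulation power is
#' concentrated in the syllabic 2-8 Hz range, and brief silent gaps
#' (< 300 ms) between phrase-like stretches. Values are nonnegative linear
#' magnitudes normalized to unit mean power over voiced frames.
#'
#' @param duration Duration in seconds (> 0).
#' @param seed Integer seed.
#' @param rate Sampling rate in Hz (default 100).
#' @param nFreq Number of bands (default 23).
#' @return A [Spectrogram-class].
#' @export
generateForeground <- function(duration, seed = 0, rate = 100, nFreq = 23) {
  .assertScalarNum(duration, "duration", positive = TRUE)
  set.seed(deriveSeed(seed, "foreground"))
  nT <- round(duration * rate)

  ## Formant-like drifting peaks: slow random walks around fixed centers.
  centers <- c(0.18, 0.42, 0.68) * nFreq
  widths <- c(0.09, 0.08, 0.07) * nFreq
  amps <- c(1, 0.8, 0.5)
  S <- matrix(0.03, nT, nFreq)  # broadband floor
  for (i in seq_along(centers)) {
    drift <- .bandpassNoise(nT, rate, 0.05, 0.5) * 0.08 * nFreq
    ctr <- centers[i] + drift
    f <- matrix(seq_len(nFreq), nT, nFreq, byrow = TRUE)
    S <- S + amps[i] * exp(-(f - ctr)^2 / (2 * widths[i]^2))
  }

  ## Syllabic-rate envelope: 2-8 Hz bandpassed noise, rectified.
  m <- .bandpassNoise(nT, rate, 2, 8)
  env <- pmax(0, 1 + 1.1 * m)

  ## Silent gaps < 300 ms with 30 ms raised-cosine edges.
  gate <- rep(1, nT)
  t <- 1
  repeat {
    t <- t + round(stats::rexp(1, rate = 1 / 1.6) * rate) + 1
    gapLen <- round(stats::runif(1, 0.10, 0.28) * rate)
    if (t + gapLen > nT) break
    gate[t:(t + gapLen - 1)] <- 0
    edge <- round(0.03 * rate)
    lo <- max(1, t - edge)
    gate[lo:t] <- pmin(gate[lo:t], seq(1, 0, length.out = t - lo + 1))
    hi <- min(nT, t + gapLen - 1 + edge)
    gate[(t + gapLen - 1):hi] <-
      pmin(gate[(t + gapLen - 1):hi], seq(0, 1, length.out = hi - t - gapLen + 2))
    t <- t + gapLen
  }

  X <- S * (env * gate)
  p <- mean(X[gate > 0.5, ]^2)
  if (p > 0) X <- X / sqrt(p)
  Spectrogram(X, rate = rate)
}

## One background-noise segment of a given class: the class mean spectrum
## carried by a stationarity-controlled temporal envelope plus mild
## spectro-temporal roughness. Unit mean power before SNR scaling.
.generateNoiseSegment <- function(spec, duration, seed, rate = 100) {
  set.seed(seed)
  nT <- round(duration * rate)
  nFreq <- length(spec@meanSpectrum)
  depth <- 1 - spec@stationarity
  ## modulation band 1-10 Hz: nonstationarity is expressed at sub-second
  ## scales, so class contrast differences are visible in short windows
  env <- pmax(0.05, 1 + 1.4 * depth * .bandpassNoise(nT, rate, 1, 10))
  rough <- matrix(1 + 0.2 * depth * stats::rnorm(nT * nFreq), nT, nFreq)
  X <- outer(env, spec@meanSpectrum) * pmax(rough, 0)
  X / sqrt(mean(X^2))
}

#' Mix a foreground and a background spectrogram at a target SNR
#'
#' Rescales the background so the realized power ratio
#' 10*log10(P_fore / P_back) equals `snrDb` over the mixed interval
#' (power = mean squared bin magnitude), then returns the sum.
#'
#' @param fore,back [Spectrogram-class] objects (or plain matrices) of the
#'   same shape and rate.
#' @param snrDb Target signal-to-noise ratio in dB.
#' @return A [Spectrogram-class] of the mixture.
#' @export
mixAtSnr <- function(fore, back, snrDb) {
  Xf <- if (methods::is(fore, "Spectrogram")) fore@values else as.matrix(fore)
  Xb <- if (methods::is(back, "Spectrogram")) back@values else as.matrix(back)
  if (!all(dim(Xf) == dim(Xb)))
    stop("foreground and background must have the same shape")
  if (methods::is(fore, "Spectrogram") && methods::is(back, "Spectrogram") &&
      fore@rate != back@rate)
    stop("foreground and background must share a sampling rate")
  pf <- mean(Xf^2)
  pb <- mean(Xb^2)
  if (pb <= 0) stop("background has zero power; cannot set an SNR")
  scale <- sqrt(pf / (pb * 10^(snrDb / 10)))
  rate <- if (methods::is(fore, "Spectrogram")) fore@rate else 100
  t0 <- if (methods::is(fore, "Spectrogram")) fore@t0 else 0
  Spectrogram(Xf + scale * Xb, rate = rate, t0 = t0)
}

## Draw a condition sequence with no immediate repeats, biased toward
## balancing total exposure; rejection-resampled until the per-class
## exposure spread is within tolerance.
.drawConditionSequence <- function(durations, tol = 0.2, maxTries = 400) {
  conds <- .CONDITIONS
  ## short sessions cannot balance finer than a few segment durations
  tol <- max(tol, 6 * max(durations) / sum(durations))
  for (try in seq_len(maxTries)) {
    expo <- stats::setNames(numeric(length(conds)), conds)
    seqc <- character(length(durations))
    prev <- ""
    ok <- TRUE
    for (i in seq_along(durations)) {
      avail <- setdiff(conds, prev)
      w <- exp(-6 * expo[avail] / max(mean(expo) + 1e-9, 1e-9))
      pick <- sample(avail, 1, prob = w / sum(w))
      seqc[i] <- pick
      expo[pick] <- expo[pick] + durations[i]
      prev <- pick
    }
    if ((max(expo) - min(expo)) / mean(expo) <= tol) return(seqc)
  }
  stop("could not draw a balanced condition sequence; relax the tolerance")
}

#' Build a switching-noise stimulus session
#'
#' Assembles the full session stimulus: a silent lead-in for baseline
#' normalization, then `nBlocks` blocks of speech-like foreground over a
#' background that switches between clean and the three noise classes every
#' 3 or 6 s, each noisy segment mixed at exactly `snrDb` dB SNR. The
#' condition sequence visits all four classes with no immediate repeats and
#' per-class total exposure balanced within 20%.
#'
#' @param nBlocks Number of blocks (>= 2; cross-validation units).
#' @param blockDuration Block duration in seconds (a multiple of 3).
#' @param segmentLengths Allowed segment durations in seconds.
#' @param snrDb Target SNR in dB (default 6).
#' @param seed Integer seed.
#' @param leadIn Silent lead-in duration in seconds (default 120).
#' @param nFreq,rate Spectrogram geometry.
#' @param noiseClasses Optional list from [makeNoiseClasses()].
#' @return A [SessionData-class] without responses (simulate them with
#'   [simulateResponses()]).
#' @export
buildSession <- function(nBlocks = 18, blockDuration = 60,
                         segmentLengths = c(3, 6), snrDb = 6, seed = 0,
                         leadIn = 120, nFreq = 23, rate = 100,
                         noiseClasses = NULL) {
  if (nBlocks < 2) stop("need at least 2 blocks for the jackknife")
  if (abs(blockDuration %% min(segmentLengths)) > 1e-9)
    stop("blockDuration must be a multiple of the shortest segment length")
  if (is.null(noiseClasses)) noiseClasses <- makeNoiseClasses(seed, nFreq)
  stimDur <- nBlocks * blockDuration

  ## Segment durations tiling the stimulus.
  set.seed(deriveSeed(seed, "schedule"))
  durs <- numeric(0)
  rem <- stimDur
  while (rem > 0) {
    opts <- segmentLengths[segmentLengths <= rem]
    d <- if (length(opts) == 1) opts else sample(opts, 1)
    durs <- c(durs, d)
    rem <- rem - d
  }
  condSeq <- .drawConditionSequence(durs)
  starts <- leadIn + cumsum(c(0, durs[-length(durs)]))
  segs <- data.frame(start = starts, end = starts + durs,
                     condition = condSeq, stringsAsFactors = FALSE)
  sched <- methods::new("NoiseSchedule", segments = segs,
                        blockBounds = leadIn + (0:nBlocks) * blockDuration,
                        leadIn = leadIn)

  ## Foreground over the stimulus part; silence during the lead-in.
  fg <- generateForeground(stimDur, seed = deriveSeed(seed, "fg"),
                           rate = rate, nFreq = nFreq)
  nLead <- round(leadIn * rate)
  Xfg <- rbind(matrix(0, nLead, nFreq), fg@values)

  ## Per-segment backgrounds mixed at exact SNR.
  X <- Xfg
  for (i in seq_len(nrow(segs))) {
    if (segs$condition[i] == "clean") next
    spec <- noiseClasses[[segs$condition[i]]]
    idx <- (round(segs$start[i] * rate) + 1):round(segs$end[i] * rate)
    back <- .generateNoiseSegment(spec, durs[i],
                                  seed = deriveSeed(seed, paste0("seg", i)),
                                  rate = rate)
    segFg <- Xfg[idx, , drop = FALSE]
    pf <- mean(segFg^2)
    pb <- mean(back^2)
    if (pf <= 0) pf <- mean(fg@values^2)  # fully silent segment fallback
    scale <- sqrt(pf / (pb * 10^(snrDb / 10)))
    X[idx, ] <- segFg + scale * back
  }

  methods::new("SessionData",
               stimulus = Spectrogram(X, rate = rate),
               foreground = Spectrogram(Xfg, rate = rate),
               schedule = sched, noiseClasses = noiseClasses,
               encoders = list(),
               responses = methods::new("ResponseMatrix",
                                        values = matrix(0, 0, 0),
                                        subjectIds = character(0),
                                        rate = rate,
                                        baselineWindow = c(0, leadIn),
                                        normalized = logical(0)),
               seed = as.integer(seed),
               config = list(nBlocks = nBlocks, blockDuration = blockDuration,
                             segmentLengths = segmentLengths, snrDb = snrDb,
                             leadIn = leadIn, nFreq = nFreq, rate = rate))
}

## Smooth, unit-calibrated random base filter: an excitatory Gabor-like
## lobe with a delayed inhibitory sideband, the classic STRF motif.
.randomBaseFilter <- function(nFreq, nLag, rate) {
  fc <- stats::runif(1, 0.2, 0.8) * nFreq
  fw <- stats::runif(1, 0.10, 0.18) * nFreq
  peakLag <- stats::runif(1, 0.05, 0.12) * rate
  lag <- seq_len(nLag) - 1
  tempEnv <- (lag / peakLag)^2 * exp(-lag / (peakLag / 2))
  tempEnv <- tempEnv / max(tempEnv)
  fprof <- .bandBump(nFreq, fc, fw)
  W <- outer(fprof, tempEnv)
  ## inhibitory sideband shifted in frequency and delayed in time
  fprof2 <- .bandBump(nFreq, fc + sample(c(-1, 1), 1) * 1.6 * fw, fw)
  temp2 <- (lag / (1.8 * peakLag))^2 * exp(-lag / (0.9 * peakLag))
  temp2 <- temp2 / max(temp2)
  W <- W - 0.55 * outer(fprof2, temp2)
  W / sqrt(sum(W^2))
}

#' Create a population of ground-truth encoders
#'
#' Builds `n` encoders of a given kind with randomized smooth base filters,
#' calibrated so the linear drive has unit-order variance on a reference
#' speech-like stimulus. Electrodes are assigned round-robin to
#' `nSubjects` synthetic subjects by [simulateResponses()].
#'
#' @param kind Encoder kind (see [GroundTruthEncoder-class]).
#' @param n Number of electrodes.
#' @param seed Integer seed.
#' @param nFreq,nLag Filter geometry (default 23 x 65).
#' @param rate Sampling rate (Hz).
#' @param outputNoiseSd Observation noise sd.
#' @param gainK,gainAlpha,suppressionDepth,suppressionMode,tauAdapt,stpU,
#'   stpTauRec,transientAmp,driveBias,rectifier Encoder parameters,
#'   recycled over electrodes.
#' @param labelPrefix Prefix for electrode labels.
#' @return List of [GroundTruthEncoder-class] objects.
#' @export
makeEncoderPopulation <- function(kind, n, seed = 0, nFreq = 23, nLag = 65,
                                  rate = 100, outputNoiseSd = 0.5,
                                  gainK = 0.85, gainAlpha = 1,
                                  suppressionDepth = 1,
                                  suppressionMode = "both", tauAdapt = 0.25,
                                  stpU = 0.4, stpTauRec = 0.2,
                                  transientAmp = 0, driveBias = 3,
                                  rectifier = "softplus",
                                  labelPrefix = kind) {
  set.seed(deriveSeed(seed, paste0("encoders-", kind)))
  ## reference drive calibration on a fixed speech-like stimulus
  ref <- generateForeground(20, seed = deriveSeed(seed, "calib"),
                            rate = rate, nFreq = nFreq)@values
  rec <- function(x, i) x[((i - 1) %% length(x)) + 1]
  out <- vector("list", n)
  for (i in seq_len(n)) {
    W <- .randomBaseFilter(nFreq, nLag, rate)
    d <- .lagDrive(ref, W)
    W <- W * (2 / max(stats::sd(d), 1e-9))
    ## anchor the operating point: driveBias is defined relative to the
    ## mean drive on the reference stimulus, so the rectifier sits at the
    ## same working point whatever the filter's net (suppressive) mass
    mDrive <- mean(.lagDrive(ref, W))
    out[[i]] <- methods::new("GroundTruthEncoder", kind = kind,
      baseFilter = W, gainK = rec(gainK, i), gainAlpha = rec(gainAlpha, i),
      suppressionDepth = rec(suppressionDepth, i),
      suppressionMode = rec(suppressionMode, i),
      tauAdapt = rec(tauAdapt, i), stpU = rec(stpU, i),
      stpTauRec = rec(stpTauRec, i), outputNoiseSd = rec(outputNoiseSd, i),
      transientAmp = rec(transientAmp, i),
      driveBias = rec(driveBias, i) - mDrive,
      rectifier = rec(rectifier, i),
      label = sprintf("%s_%02d", labelPrefix, i))
  }
  out
}

## Exponentially-decaying unit-sum lag kernel used to give the suppression
## component a temporal footprint (time constant 100 ms).
.suppressionLagKernel <- function(nLag, rate, tau = 0.1) {
  k <- exp(-(seq_len(nLag) - 1) / (tau * rate))
  k / sqrt(sum(k^2))
}

## Adaptive state target per sample for the noise-filtering encoder:
## rows = time, cols = freq; relaxes toward depth * unit-norm class spectrum
## during noise segments and toward zero in clean/lead-in.
.suppressionTarget <- function(session, depth, nT) {
  segs <- segments(session@schedule)
  rate <- session@stimulus@rate
  nFreq <- nFreq(session@stimulus)
  target <- matrix(0, nT, nFreq)
  for (i in seq_len(nrow(segs))) {
    if (segs$condition[i] == "clean") next
    spec <- session@noiseClasses[[segs$condition[i]]]@meanSpectrum
    shape <- spec / sqrt(sum(spec^2))
    idx <- (round(segs$start[i] * rate) + 1):round(segs$end[i] * rate)
    target[idx, ] <- matrix(depth * shape, length(idx), nFreq, byrow = TRUE)
  }
  target
}

## Transition-triggered exponential transient (time constant 0.3 s).
.transientSeries <- function(schedule, nT, rate, tau = 0.3) {
  tr <- transitions(schedule)
  imp <- numeric(nT)
  idx <- round(tr$time * rate) + 1
  imp[idx[idx >= 1 & idx <= nT]] <- 1
  a <- exp(-1 / (tau * rate))
  as.numeric(stats::filter(imp, a, method = "recursive"))
}

#' Simulate ground-truth electrode responses for a session
#'
#' Runs each encoder on the session stimulus and returns the stacked
#' response matrix, z-scored per electrode to the silent lead-in (skipped,
#' with a record, for electrodes whose baseline has zero variance, e.g.
#' noiseless static encoders).
#'
#' The generative mechanisms are: `static_linear`, r(t) =
#' softplus(base drive); `gain_adaptive`, the same premultiplied by a gain
#' g = k (c + 0.05)^(-alpha) of the trailing 1-s spectro-temporal contrast
#' c, relaxed with time constant `tauAdapt`; `noise_filtering`, the base
#' filter acquires an inhibitory component matched to the current noise
#' spectrum (exponential approach with `tauAdapt`); `ln_stp`, the rectified
#' drive is depressed by Tsodyks-Markram resource dynamics and passed
#' through a Gompertz nonlinearity. All kinds add the encoder's transition
#' transient and Gaussian observation noise.
#'
#' @param session A [SessionData-class] from [buildSession()].
#' @param encoders List of [GroundTruthEncoder-class] objects.
#' @param seed Integer seed for the observation noise.
#' @param nSubjects Number of synthetic subjects electrodes are assigned to.
#' @return The session with `responses` and `encoders` filled in.
#' @export
simulateResponses <- function(session, encoders, seed = 0, nSubjects = 4) {
  stopifnot(methods::is(session, "SessionData"), length(encoders) > 0)
  X <- session@stimulus@values
  rate <- session@stimulus@rate
  nT <- nrow(X)
  nE <- length(encoders)
  sched <- session@schedule

  contrast <- NULL       # computed lazily, shared across gain encoders
  suppTargetCache <- list()
  transient <- NULL

  R <- matrix(0, nE, nT)
  for (e in seq_len(nE)) {
    enc <- encoders[[e]]
    if (ncol(enc@baseFilter) > nT)
      stop("encoder lag span exceeds the stimulus length")
    drive <- .lagDrive(X, enc@baseFilter) + enc@driveBias
    rect <- if (enc@rectifier == "relu") function(v) pmax(v, 0) else .softplus
    r <- switch(enc@kind,
      static_linear = rect(drive),
      gain_adaptive = {
        if (is.null(contrast))
          contrast <- .trailingContrast(X, round(1 * rate))
        gTarget <- enc@gainK * (contrast + 0.3)^(-enc@gainAlpha)
        g <- .relaxTowards(gTarget, enc@tauAdapt, 1 / rate)
        g * rect(drive)
      },
      noise_filtering = {
        key <- sprintf("%s|%.4g", enc@suppressionMode, enc@suppressionDepth)
        lagK <- .suppressionLagKernel(ncol(enc@baseFilter), rate)
        target <- suppTargetCache[[key]]
        if (is.null(target)) {
          target <- .suppressionTarget(session, enc@suppressionDepth, nT)
          suppTargetCache[[key]] <- target
        }
        a <- (1 / rate) / enc@tauAdapt
        S <- apply(target, 2, function(col)
          as.numeric(stats::filter(a * col, 1 - a, method = "recursive")))
        kernels <- if (enc@suppressionMode == "inhibitory_only") {
          vapply(seq_len(nrow(enc@baseFilter)), function(f)
            lagK * (enc@baseFilter[f, ] <= 0), numeric(length(lagK)))
        } else {
          matrix(lagK, length(lagK), nrow(enc@baseFilter))
        }
        U <- .lagFilterBands(X, kernels)
        rect(drive - rowSums(S * U))
      },
      ln_stp = {
        p <- rect(drive)
        xres <- .stpResource(p, enc@stpU, enc@stpTauRec, 1 / rate)
        v <- enc@stpU * xres * p
        .gompertz(v, base = 0, amplitude = 2,
                  shift = stats::median(v[v > 0]), slope = 3)
      },
      stop(sprintf("unknown encoder kind '%s'", enc@kind)))
    if (enc@transientAmp != 0) {
      if (is.null(transient))
        transient <- .transientSeries(sched, nT, rate)
      r <- r + enc@transientAmp * transient
    }
    if (enc@outputNoiseSd > 0) {
      set.seed(deriveSeed(seed, paste0("obsnoise-", e)))
      r <- r + stats::rnorm(nT, 0, enc@outputNoiseSd)
    }
    R[e, ] <- r
  }

  ## z-score to the silent lead-in
  bw <- c(0, sched@leadIn)
  bIdx <- seq_len(round(sched@leadIn * rate))
  normalized <- logical(nE)
  for (e in seq_len(nE)) {
    mu <- mean(R[e, bIdx])
    sdv <- .popSd(R[e, bIdx])
    if (sdv > 1e-12) {
      R[e, ] <- (R[e, ] - mu) / sdv
      normalized[e] <- TRUE
    }
  }

  subjects <- sprintf("S%d", ((seq_len(nE) - 1) %% nSubjects) + 1)
  session@responses <- methods::new("ResponseMatrix", values = R,
                                    subjectIds = subjects, rate = rate,
                                    baselineWindow = bw,
                                    normalized = normalized)
  session@encoders <- encoders
  session
}

#' Subset a session to a set of electrodes
#'
#' Returns the same session with responses and encoders restricted to the
#' given electrodes (e.g. one synthetic subject's population, to be fit
#' with its own model).
#'
#' @param session A [SessionData-class] with simulated responses.
#' @param electrodes Integer indices.
#' @return A [SessionData-class].
#' @export
subsetElectrodes <- function(session, electrodes) {
  r <- session@responses
  session@responses <- methods::new("ResponseMatrix",
    values = r@values[electrodes, , drop = FALSE],
    subjectIds = r@subjectIds[electrodes], rate = r@rate,
    baselineWindow = r@baselineWindow,
    normalized = r@normalized[electrodes])
  if (length(session@encoders)) {
    session@encoders <- session@encoders[electrodes]
  }
  session
}

#' Export a schedule as a BED-like TSV
#'
#' Writes `start_s`, `end_s`, `condition` columns for inspection with
#' standard text tools.
#'
#' @param schedule A [NoiseSchedule-class].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
scheduleToTsv <- function(schedule, path) {
  s <- segments(schedule)
  utils::write.table(
    data.frame(start_s = s$start, end_s = s$end, condition = s$condition),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
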