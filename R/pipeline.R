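## End-to-end orchestration: session analysis (dSTRF time courses around
## transitions, index tables, improvement and coupling summaries), a
## config-driven experiment runner with stage caching, and a reduced-scale
## validation suite.

#' Frame indices needed for transition-window dSTRF analyses
#'
#' The adaptation indices only consume dSTRF frames in the pre-transition
#' window [-0.5, 0) s and the post-adaptation window [0.65, 1.15) s, so
#' only those frames are computed. Frames without a full receptive field
#' are dropped.
#'
#' @param schedule A [NoiseSchedule-class].
#' @param rate Sampling rate in Hz.
#' @param rf Receptive field in samples.
#' @param nSamples Session length in samples.
#' @return Sorted integer vector of sample indices.
#' @export
transitionFrameIndices <- function(schedule, rate = 100, rf = 65,
                                   nSamples = Inf) {
  tr <- transitions(schedule)
  s0 <- round(tr$time * rate) + 1L
  rel <- c(seq(-round(0.5 * rate), -1L),
           seq(round(0.65 * rate), round(1.15 * rate) - 1L))
  frames <- sort(unique(as.integer(outer(s0, rel, `+`))))
  frames[frames >= rf & frames <= nSamples]
}

#' Analyze adaptation of a jackknife-fitted CNN on a session
#'
#' Computes masked dSTRF frames around every background transition,
#' expands them into gain and noise-correlation time courses, and derives
#' the per-electrode adaptation quantities: gain-change indices,
#' noise-filtering indices per receptive-field region, adaptation indices,
#' CNN-over-STRF improvement, and the stimulus-contrast / dSTRF-gain
#' coupling across transitions.
#'
#' @param session A [SessionData-class] with simulated responses.
#' @param jkCnn A [JackknifeSet-class] from the `"cnn"` fitter.
#' @param jkStrf Optional [JackknifeSet-class] from the `"strf"` fitter
#'   (enables the improvement column).
#' @param electrodes Electrode indices to analyze (default all).
#' @param minAgree Sign-consistency threshold (default scaled 15/17 rule).
#' @return List with `indexTable` (tidy data.frame: electrode, subject,
#'   condition, region, index_kind, value, n_transitions), `improvement`
#'   (per-electrode data.frame), `adaptation` (per-electrode indices),
#'   `coupling` (contrast/gain deltas and their correlation), `gainSeries`
#'   and `corrSeries` (full/exc/inh series per electrode), and
#'   `splitCorrelation` (adaptation-window vs remainder improvement).
#' @export
analyzeAdaptation <- function(session, jkCnn, jkStrf = NULL,
                              electrodes = NULL, minAgree = NULL) {
  stopifnot(methods::is(session, "SessionData"),
            methods::is(jkCnn, "JackknifeSet"), jkCnn@fitter == "cnn")
  rate <- session@stimulus@rate
  sched <- session@schedule
  X <- session@stimulus@values
  nT <- nrow(X)
  rf <- receptiveField(jkCnn@ensembles[[1]]@members[[1]]@config)
  if (is.null(electrodes)) electrodes <- seq_len(nElectrodes(session))
  nE <- length(electrodes)

  targets <- lapply(session@noiseClasses, function(sp) sp@meanSpectrum)
  targets$clean <- cleanSpeechSpectrum(session)

  frames <- transitionFrameIndices(sched, rate, rf, nT)
  gainSeries <- lapply(seq_len(nE), function(i)
    matrix(NA_real_, nT, 3, dimnames = list(NULL, c("full", "excitatory",
                                                    "inhibitory"))))
  corrSeries <- lapply(seq_len(nE), function(i)
    lapply(targets, function(tt) gainSeries[[1]]))

  for (ens in jkCnn@ensembles) {
    idx <- jkCnn@blocks[[ens@testBlock]]
    fr <- frames[frames %in% idx]
    if (!length(fr)) next
    tensors <- dstrfTimecourse(ens, session@stimulus, frames = fr,
                               electrodes = electrodes, minAgree = minAgree)
    for (i in seq_len(nE)) {
      ser <- dstrfSeries(tensors[[i]], nT, targets)
      put <- !is.na(ser$gain[, 1])
      for (r in 1:3) {
        gainSeries[[i]][put, r] <- ser$gain[put, r]
        for (nm in names(targets)) {
          corrSeries[[i]][[nm]][put, r] <- ser$corr[[nm]][put, r]
        }
      }
    }
  }

  ## --- index table -------------------------------------------------------
  subjects <- subjectIds(session)
  noiseConds <- names(session@noiseClasses)
  rows <- list()
  for (i in seq_len(nE)) {
    e <- electrodes[i]
    for (cc in c(noiseConds, "clean")) {
      filt <- if (cc == "clean") "to_clean" else "to_noise_from_clean"
      alG <- alignToTransitions(gainSeries[[i]][, "full"], sched,
                                filter = filt, toCondition = cc,
                                rate = rate)
      nTr <- nrow(alG$values)
      rows[[length(rows) + 1L]] <- data.frame(
        electrode = e, subject = subjects[e], condition = cc,
        region = "full", index_kind = "gain_change",
        value = if (nTr) gainChangeIndex(alG, rate) else NA_real_,
        n_transitions = nTr, stringsAsFactors = FALSE)
      for (r in c("full", "excitatory", "inhibitory")) {
        alC <- alignToTransitions(corrSeries[[i]][[cc]][, r], sched,
                                  filter = filt, toCondition = cc,
                                  rate = rate)
        rows[[length(rows) + 1L]] <- data.frame(
          electrode = e, subject = subjects[e], condition = cc,
          region = r, index_kind = "noise_filtering",
          value = if (nrow(alC$values)) noiseFilteringIndex(alC, rate)
                  else NA_real_,
          n_transitions = nrow(alC$values), stringsAsFactors = FALSE)
      }
    }
  }
  indexTable <- do.call(rbind, rows)

  ## --- adaptation indices ------------------------------------------------
  Y <- respValues(session)
  adaptation <- do.call(rbind, lapply(seq_len(nE), function(i) {
    ai <- adaptationIndex(Y[electrodes[i], ], sched, rate)
    data.frame(electrode = electrodes[i], subject = subjects[electrodes[i]],
               index = ai$index, nExcluded = ai$nExcluded,
               stringsAsFactors = FALSE)
  }))

  ## --- improvement and split correlations --------------------------------
  improvement <- NULL
  splitCorrelation <- NULL
  if (!is.null(jkStrf)) {
    splitCnn <- evaluateSplitCorrelation(jkCnn@predictions, Y, sched,
                                         rate = rate)
    splitStrf <- evaluateSplitCorrelation(jkStrf@predictions, Y, sched,
                                          rate = rate)
    m <- merge(splitCnn, splitStrf,
               by = c("electrode", "condition"), suffixes = c("_cnn", "_strf"))
    m$improvement_full <- m$full_r_cnn - m$full_r_strf
    m$improvement_adaptation <- m$adaptation_r_cnn - m$adaptation_r_strf
    m$improvement_remainder <- m$remainder_r_cnn - m$remainder_r_strf
    splitCorrelation <- m[m$electrode %in% electrodes, ]
    allRows <- splitCorrelation[splitCorrelation$condition == "all", ]
    improvement <- data.frame(electrode = allRows$electrode,
                              subject = subjects[allRows$electrode],
                              improvement = allRows$improvement_full,
                              stringsAsFactors = FALSE)
  }

  ## --- contrast / gain coupling over all transitions ---------------------
  tr <- transitions(sched)
  segs <- segments(sched)
  s0 <- round(tr$time * rate) + 1L
  preIdx <- lapply(s0, function(s) (s - round(0.5 * rate)):(s - 1L))
  postIdx <- lapply(s0, function(s)
    (s + round(0.65 * rate)):(s + round(1.15 * rate) - 1L))
  dContrast <- vapply(seq_len(nrow(tr)), function(k) {
    segPre <- segs[abs(segs$end - tr$time[k]) < 1e-9, ]
    segPost <- segs[abs(segs$start - tr$time[k]) < 1e-9, ]
    cPre <- stimulusContrast(X[(round(segPre$start[1] * rate) + 1L):
                                 round(segPre$end[1] * rate), , drop = FALSE])
    cPost <- stimulusContrast(X[(round(segPost$start[1] * rate) + 1L):
                                  round(segPost$end[1] * rate), , drop = FALSE])
    cPost - cPre
  }, 0)
  meanGain <- function(idx) {
    g <- vapply(seq_len(nE), function(i) {
      v <- gainSeries[[i]][idx[idx >= 1 & idx <= nT], "full"]
      mean(v, na.rm = TRUE)
    }, 0)
    mean(g, na.rm = TRUE)
  }
  dGain <- vapply(seq_len(nrow(tr)), function(k)
    meanGain(postIdx[[k]]) - meanGain(preIdx[[k]]), 0)
  okTr <- is.finite(dContrast) & is.finite(dGain)
  coupling <- list(dContrast = dContrast, dGain = dGain,
                   transitions = tr,
                   correlation = if (sum(okTr) >= 3)
                     stats::cor(dContrast[okTr], dGain[okTr]) else NA_real_)

  list(indexTable = indexTable, improvement = improvement,
       adaptation = adaptation, coupling = coupling,
       gainSeries = gainSeries, corrSeries = corrSeries,
       splitCorrelation = splitCorrelation, electrodes = electrodes,
       frames = frames)
}

#' Build the electrodes x 8 noise-filtering feature matrix
#'
#' Excitatory and inhibitory noise-filtering indices for the four
#' to-conditions, the feature space in which the two electrode groups are
#' clustered.
#'
#' @param indexTable The `indexTable` from [analyzeAdaptation()].
#' @return Numeric matrix with rownames = electrode ids and columns
#'   `exc_<cond>`, `inh_<cond>`.
#' @export
noiseFilteringFeatures <- function(indexTable) {
  d <- indexTable[indexTable$index_kind == "noise_filtering" &
                    indexTable$region %in% c("excitatory", "inhibitory"), ]
  d$col <- paste0(ifelse(d$region == "excitatory", "exc_", "inh_"),
                  d$condition)
  elecs <- sort(unique(d$electrode))
  cols <- sort(unique(d$col))
  M <- matrix(NA_real_, length(elecs), length(cols),
              dimnames = list(elecs, cols))
  for (k in seq_len(nrow(d))) {
    M[as.character(d$electrode[k]), d$col[k]] <- d$value[k]
  }
  M
}

#' Default experiment configurations
#'
#' `"paper"` mirrors the reference study design (18 one-minute blocks,
#' 128-kernel CNN, 17-member jackknife, mask 15/17); `"demo"` is a
#' reduced-scale configuration sized for a single CPU (4 blocks of 45 s,
#' 24 kernels, 3-member jackknife, mask ceiling(3 * 15/17) = 3).
#'
#' @param scale `"paper"` or `"demo"`.
#' @return Named list of parameters accepted by [runExperiment()].
#' @export
defaultConfig <- function(scale = c("demo", "paper")) {
  scale <- match.arg(scale)
  if (scale == "paper") {
    list(nBlocks = 18, blockDuration = 60, snrDb = 6, leadIn = 120,
         nKernels = 128, epochs = 150, lr = 2e-3,
         encoders = list(gain_adaptive = 20, noise_filtering = 10,
                         static_linear = 6),
         outputNoiseSd = 0.5, nSubjects = 6, seed = 1)
  } else {
    list(nBlocks = 4, blockDuration = 45, snrDb = 6, leadIn = 120,
         nKernels = 24, epochs = 120, lr = 2e-3,
         encoders = list(gain_adaptive = 8, noise_filtering = 6,
                         static_linear = 4),
         outputNoiseSd = 0.5, nSubjects = 4, seed = 1)
  }
}

.stageCache <- function(dir, name, compute, manifest, force = FALSE) {
  path <- file.path(dir, paste0(name, ".rds"))
  if (!force && file.exists(path)) {
    cached <- readRDS(path)
    if (identical(cached$hash, manifest$configHash)) {
      message(sprintf("[%s] cached", name))
      return(cached$value)
    }
  }
  t0 <- Sys.time()
  value <- compute()
  elapsed <- as.numeric(Sys.time() - t0, units = "secs")
  saveRDS(list(value = value, hash = manifest$configHash), path)
  message(sprintf("[%s] done in %.1f s", name, elapsed))
  value
}

#' Run the full synthetic experiment
#'
#' Sequences session generation, STRF and CNN jackknife fitting, dSTRF
#' extraction with transition-window metrics, and population statistics,
#' writing plain-text artifacts (schedule TSV, index CSV, report JSON) and
#' a manifest into `outDir`. Completed stages are cached as RDS files and
#' skipped on re-runs with an unchanged configuration.
#'
#' @param config Named list (see [defaultConfig()]).
#' @param outDir Output directory.
#' @param force Recompute even when cached stages exist.
#' @return Invisible list with the session, fits, analysis and report.
#' @export
runExperiment <- function(config = defaultConfig("demo"),
                          outDir = tempfile("dstrfadapt-run"),
                          force = FALSE) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(configHash = .contentHash(config), config = config,
                   started = format(Sys.time()),
                   rVersion = as.character(getRversion()))
  seed <- config$seed

  session <- .stageCache(outDir, "01-session", function() {
    s <- buildSession(nBlocks = config$nBlocks,
                      blockDuration = config$blockDuration,
                      snrDb = config$snrDb, seed = seed,
                      leadIn = config$leadIn)
    encs <- list()
    for (kind in names(config$encoders)) {
      encs <- c(encs, makeEncoderPopulation(
        kind, config$encoders[[kind]], seed = deriveSeed(seed, kind),
        outputNoiseSd = config$outputNoiseSd))
    }
    simulateResponses(s, encs, seed = deriveSeed(seed, "responses"),
                      nSubjects = config$nSubjects)
  }, manifest, force)
  scheduleToTsv(session@schedule, file.path(outDir, "schedule.tsv"))

  blocks <- blockIndices(session@schedule, session@stimulus@rate)
  jkStrf <- .stageCache(outDir, "02-strf", function()
    jackknifeFit(session@stimulus, session@responses, blocks, "strf",
                 seed = deriveSeed(seed, "strf")), manifest, force)
  jkCnn <- .stageCache(outDir, "03-cnn", function()
    jackknifeFit(session@stimulus, session@responses, blocks, "cnn",
                 seed = deriveSeed(seed, "cnn"),
                 config = cnnConfig(nKernels = config$nKernels),
                 epochs = config$epochs, lr = config$lr), manifest, force)

  analysis <- .stageCache(outDir, "04-metrics", function()
    analyzeAdaptation(session, jkCnn, jkStrf), manifest, force)
  utils::write.csv(analysis$indexTable,
                   file.path(outDir, "indices.csv"), row.names = FALSE)

  report <- .stageCache(outDir, "05-popstats", function() {
    idx <- analysis$indexTable
    imp <- analysis$improvement
    gain <- idx[idx$index_kind == "gain_change", ]
    nf <- idx[idx$index_kind == "noise_filtering" &
                idx$region == "inhibitory", ]
    tbl <- merge(merge(
      stats::setNames(gain[, c("electrode", "subject", "condition", "value")],
                      c("electrode", "subject", "condition", "gain_change")),
      stats::setNames(nf[, c("electrode", "condition", "value")],
                      c("electrode", "condition", "noise_filtering")),
      by = c("electrode", "condition")), imp, by = c("electrode", "subject"))
    improvementModel <- tryCatch(fitImprovementModel(tbl),
                                 warning = function(w) NULL,
                                 error = function(err) NULL)
    feats <- noiseFilteringFeatures(idx)
    clust <- tryCatch(clusterNoiseFiltering(feats), error = function(e) NULL)
    groupComparison <- NULL
    if (!is.null(clust)) {
      adaptIdx <- analysis$adaptation$index[match(as.integer(names(clust$groups)),
                                                  analysis$adaptation$electrode)]
      al <- lapply(analysis$electrodes, function(e)
        colMeans(alignToTransitions(respValues(session)[e, ],
                                    session@schedule, "clean_noise",
                                    pre = 0.5, post = 3)$values, na.rm = TRUE))
      alM <- do.call(rbind, al)[clust$kept, , drop = FALSE]
      tgrid <- seq(-0.5, 3 - 0.01, by = 0.01)
      groupComparison <- tryCatch(
        compareGroups(clust$groups, adaptIdx, alM, tgrid),
        error = function(e) NULL)
    }
    list(improvementModel = improvementModel, clustering = clust,
         groupComparison = groupComparison,
         coupling = analysis$coupling["correlation"])
  }, manifest, force)

  manifest$finished <- format(Sys.time())
  manifest$stages <- list(session = .contentHash(respValues(session)),
                          indices = .contentHash(analysis$indexTable))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  reportOut <- list(
    couplingCorrelation = analysis$coupling$correlation,
    medianImprovement = if (!is.null(analysis$improvement))
      stats::median(analysis$improvement$improvement) else NULL,
    groupComparison = if (!is.null(report$groupComparison))
      report$groupComparison$adaptationTest else NULL)
  jsonlite::write_json(reportOut, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)

  invisible(list(session = session, jkStrf = jkStrf, jkCnn = jkCnn,
                 analysis = analysis, report = report, outDir = outDir))
}

#' Reduced-scale validation of the package's core invariants
#'
#' Executes the module-level oracle checks at small scale -- generator
#' determinism and SNR conservation, baseline normalization, the
#' convolution oracle for the static encoder, the dSTRF linearity
#' identity, jackknife bookkeeping, the STP steady state, and the masking
#' fixed point -- and returns one row per check.
#'
#' @param seed Integer seed.
#' @return data.frame with check name, measured value and pass flag.
#' @export
validateSuite <- function(seed = 1) {
  checks <- list()
  add <- function(name, value, pass)
    checks[[length(checks) + 1L]] <<- data.frame(
      check = name, value = value, pass = pass, stringsAsFactors = FALSE)

  ## generator determinism + SNR
  s1 <- buildSession(nBlocks = 2, blockDuration = 15, seed = seed,
                     leadIn = 10)
  s2 <- buildSession(nBlocks = 2, blockDuration = 15, seed = seed,
                     leadIn = 10)
  add("session determinism",
      as.numeric(identical(s1@stimulus@values, s2@stimulus@values)),
      identical(s1@stimulus@values, s2@stimulus@values))
  segs <- segments(s1@schedule)
  rate <- s1@stimulus@rate
  snrErr <- 0
  for (i in which(segs$condition != "clean")) {
    idx <- (round(segs$start[i] * rate) + 1L):round(segs$end[i] * rate)
    pf <- mean(s1@foreground@values[idx, ]^2)
    pb <- mean((s1@stimulus@values[idx, ] - s1@foreground@values[idx, ])^2)
    snrErr <- max(snrErr, abs(10 * log10(pf / pb) - s1@config$snrDb))
  }
  add("max SNR error (dB)", snrErr, snrErr < 0.1)

  ## convolution oracle for the static encoder
  enc <- makeEncoderPopulation("static_linear", 1, seed = seed,
                               outputNoiseSd = 0)
  sim <- simulateResponses(s1, enc, seed = seed)
  X <- sim@stimulus@values
  W <- enc[[1]]@baseFilter
  nT <- nrow(X)
  oracle <- numeric(nT)
  for (t in seq_len(nT)) {
    lagMax <- min(t, ncol(W))
    acc <- enc[[1]]@driveBias
    for (l in seq_len(lagMax)) acc <- acc + sum(W[, l] * X[t - l + 1, ])
    oracle[t] <- log1p(exp(min(acc, 30))) + max(acc - 30, 0)
  }
  err <- max(abs(oracle - respValues(sim)[1, ]))
  add("static-encoder convolution oracle (max abs err)", err, err < 1e-8)

  ## baseline normalization
  encN <- makeEncoderPopulation("static_linear", 2, seed = seed,
                                outputNoiseSd = 0.5)
  simN <- simulateResponses(s1, encN, seed = seed)
  bIdx <- seq_len(round(s1@schedule@leadIn * rate))
  mu <- max(abs(rowMeans(respValues(simN)[, bIdx])))
  v <- max(abs(apply(respValues(simN)[, bIdx], 1, .popSd) - 1))
  add("baseline mean (max abs)", mu, mu < 1e-6)
  add("baseline sd deviation (max abs)", v, v < 1e-6)

  ## dSTRF linearity identity on a random CNN
  cfg <- cnnConfig(nKernels = 12)
  model <- initCnn(cfg, 2, seed = seed)
  set.seed(deriveSeed(seed, "val-lin"))
  relErr <- max(vapply(1:20, function(i) {
    xw <- matrix(stats::rexp(cfg@nFreq * 65), cfg@nFreq, 65)
    max(dstrfLinearityCheck(model, xw)$relDiff)
  }, 0))
  add("dSTRF linearity identity (max rel err)", relErr, relErr < 1e-4)

  ## masking fixed point
  set.seed(deriveSeed(seed, "val-mask"))
  frames <- lapply(1:5, function(i) array(stats::rnorm(60), c(3, 4, 5)))
  m1 <- averageAndMask(frames, 4)
  m2 <- averageAndMask(list(m1, m1, m1, m1, m1), 4)
  fixedPoint <- isTRUE(all.equal(ifelse(m1 == 0, 0, m1), m2)) ||
    max(abs(m2 - m1 * (m1 != 0))) < 1e-12
  add("mask fixed point", as.numeric(fixedPoint), fixedPoint)

  ## STP steady state
  d <- rep(5, 2000)
  xr <- .stpResource(d, u = 0.4, tauRec = 0.2, dt = 0.01)
  target <- (1 / 0.2) / (1 / 0.2 + 0.4 * 5)
  ssErr <- abs(xr[length(xr)] - target) / target
  add("STP steady state (rel err)", ssErr, ssErr < 0.01)

  do.call(rbind, checks)
}
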