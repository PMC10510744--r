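## Shared fixtures, built once per test run and memoised across files.
## Sizes are chosen so the whole suite stays single-CPU friendly: short
## blocks, a narrow CNN, and dSTRF frames restricted to the transition
## windows the indices consume.

.fixtureEnv <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtureEnv)) {
    assign(name, build(), envir = .fixtureEnv)
  }
  get(name, envir = .fixtureEnv)
}

## Tiny session for cheap structural tests.
tinySession <- function() {
  fixture("tiny", function() {
    s <- buildSession(nBlocks = 2, blockDuration = 15, seed = 101,
                      leadIn = 20)
    enc <- makeEncoderPopulation("static_linear", 2, seed = 102,
                                 outputNoiseSd = 0.3)
    simulateResponses(s, enc, seed = 103)
  })
}

## Static-only session: three noiseless electrodes (linear-recovery
## checks) plus five noisy ones (the static null for the adaptation
## indices), with STRF + CNN jackknife fits and the adaptation analysis.
linearFixture <- function() {
  fixture("linear", function() {
    s <- buildSession(nBlocks = 4, blockDuration = 45, seed = 201,
                      leadIn = 60)
    enc <- c(makeEncoderPopulation("static_linear", 3, seed = 202,
                                   outputNoiseSd = 0, labelPrefix = "lin"),
             makeEncoderPopulation("static_linear", 5, seed = 206,
                                   outputNoiseSd = 0.5,
                                   labelPrefix = "static"))
    sim <- simulateResponses(s, enc, seed = 203)
    blocks <- blockIndices(sim@schedule)
    jkStrf <- jackknifeFit(sim@stimulus, sim@responses, blocks, "strf",
                           seed = 204)
    jkCnn <- jackknifeFit(sim@stimulus, sim@responses, blocks, "cnn",
                          seed = 205, config = cnnConfig(nKernels = 24),
                          epochs = 150, batchLen = 250, weightDecay = 0.07,
                          lrDecay = 0.98, patience = 50)
    analysis <- analyzeAdaptation(sim, jkCnn, jkStrf)
    list(session = sim, blocks = blocks, jkStrf = jkStrf, jkCnn = jkCnn,
         analysis = analysis, encoders = enc)
  })
}

## Masked dSTRF tensors for the linear fixture (subsampled frames of the
## first test block).
linearDstrf <- function() {
  fixture("linearDstrf", function() {
    fx <- linearFixture()
    idx <- fx$blocks[[1]]
    frames <- idx[idx >= idx[1] + 64L]
    frames <- frames[seq(1, length(frames), by = 8)]
    dstrfTimecourse(fx$jkCnn@ensembles[[1]], fx$session@stimulus,
                    frames = frames, electrodes = 1:3)
  })
}

## Adaptation session: contrast-gain electrodes and two planted
## noise-filtering populations (A: whole-filter suppression, small
## transient; B: inhibitory-only suppression, large transient). Each
## population is fit with its own jackknife models (as electrodes from
## different subjects would be), avoiding cross-population coupling
## through a shared CNN trunk.
adaptFixture <- function() {
  fixture("adapt", function() {
    ## gain-control session
    sG <- buildSession(nBlocks = 4, blockDuration = 45, seed = 301,
                       leadIn = 60)
    encG <- makeEncoderPopulation("gain_adaptive", 20, seed = 302,
                                  outputNoiseSd = 0.5, gainAlpha = 1.5,
                                  labelPrefix = "gain")
    simG <- simulateResponses(sG, encG, seed = 306)
    ## noise-filtering session (longer: the index features are
    ## transition-count limited)
    sN <- buildSession(nBlocks = 4, blockDuration = 60, seed = 311,
                       leadIn = 60)
    encN <- c(
      makeEncoderPopulation("noise_filtering", 12, seed = 303,
                            outputNoiseSd = 0.5, suppressionDepth = 2,
                            suppressionMode = "both", transientAmp = 0.3,
                            labelPrefix = "nfA"),
      makeEncoderPopulation("noise_filtering", 12, seed = 304,
                            outputNoiseSd = 0.5, suppressionDepth = 2.2,
                            suppressionMode = "inhibitory_only",
                            transientAmp = 1.5, labelPrefix = "nfB"))
    simN <- simulateResponses(sN, encN, seed = 316)

    fitGroup <- function(sim, tag, epochs) {
      blocks <- blockIndices(sim@schedule)
      jkStrf <- jackknifeFit(sim@stimulus, sim@responses, blocks, "strf",
                             seed = deriveSeed(307, tag))
      jkCnn <- jackknifeFit(sim@stimulus, sim@responses, blocks, "cnn",
                            seed = deriveSeed(308, tag),
                            config = cnnConfig(nKernels = 24),
                            epochs = epochs, batchLen = 250,
                            weightDecay = 0.07, lrDecay = 0.985,
                            patience = 50)
      list(session = sim, blocks = blocks, jkStrf = jkStrf, jkCnn = jkCnn,
           analysis = analyzeAdaptation(sim, jkCnn, jkStrf))
    }
    gain <- fitGroup(simG, "gain", 100)
    nf <- fitGroup(simN, "nf", 100)
    list(session = simG, gain = gain, nf = nf,
         gainIdx = 1:20, nfAIdx = 1:12, nfBIdx = 13:24)
  })
}

cosineSim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
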