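test_that("noise classes are spectrally distinct and deterministic", {
  nc <- makeNoiseClasses(0)
  expect_named(nc, c("bar", "city", "jet"))
  ## jet concentrates its power in the top third of the bands
  jet <- nc$jet@meanSpectrum
  expect_gt(sum(jet[16:23]) / sum(jet), 0.7)
  ## bar overlaps the speech spectrum more than jet does
  speech <- colMeans(generateForeground(20, seed = 5)@values)
  expect_gt(cor(nc$bar@meanSpectrum, speech), cor(jet, speech))
  ## pairwise spectral correlations below 0.8
  M <- cbind(nc$bar@meanSpectrum, nc$city@meanSpectrum, jet)
  cors <- cor(M)[upper.tri(diag(3))]
  expect_true(all(cors < 0.8))
  ## unit total power, determinism
  expect_equal(vapply(nc, function(x) sum(x@meanSpectrum), 0),
               c(bar = 1, city = 1, jet = 1))
  nc2 <- makeNoiseClasses(0)
  expect_identical(lapply(nc, function(x) x@meanSpectrum),
                   lapply(nc2, function(x) x@meanSpectrum))
})

test_that("foreground spectrogram is speech-like", {
  fg <- generateForeground(10, seed = 1)
  expect_equal(dim(fg@values), c(1000, 23))
  expect_true(all(fg@values >= 0))
  ## modulation spectrum of the band-summed envelope peaks inside 2-8 Hz
  fg2 <- generateForeground(60, seed = 2)
  env <- rowSums(fg2@values)
  sp <- Mod(stats::fft(env - mean(env)))^2
  fr <- (seq_along(sp) - 1) / length(sp) * 100
  idx <- which(fr > 0.5 & fr < 50)
  peak <- fr[idx][which.max(sp[idx])]
  expect_gte(peak, 2)
  expect_lte(peak, 8)
  expect_error(generateForeground(-1), "duration")
})

test_that("mixAtSnr hits the requested SNR exactly", {
  set.seed(1)
  f <- Spectrogram(matrix(rexp(500 * 23), 500, 23))
  b <- Spectrogram(matrix(rexp(500 * 23), 500, 23))
  mix <- mixAtSnr(f, b, 0)
  back <- mix@values - f@values
  expect_equal(10 * log10(mean(f@values^2) / mean(back^2)), 0,
               tolerance = 1e-10)
  mix6 <- mixAtSnr(f, b, 6)
  back6 <- mix6@values - f@values
  expect_equal(10 * log10(mean(f@values^2) / mean(back6^2)), 6,
               tolerance = 0.1)
  ## equal-power inputs at 0 dB use a scale factor of 1
  bEq <- Spectrogram(b@values * sqrt(mean(f@values^2) / mean(b@values^2)))
  mixEq <- mixAtSnr(f, bEq, 0)
  expect_equal(mixEq@values, f@values + bEq@values, tolerance = 1e-12)
  expect_error(mixAtSnr(f, Spectrogram(matrix(0, 500, 23)), 6), "zero power")
})

test_that("buildSession produces a valid balanced schedule", {
  s <- buildSession(nBlocks = 4, blockDuration = 30, seed = 7, leadIn = 30)
  segs <- segments(s@schedule)
  ## segment durations in {3, 6}, tiling the stimulus
  durs <- segs$end - segs$start
  expect_true(all(durs %in% c(3, 6)))
  expect_equal(sum(durs), 120)
  expect_equal(segs$start[1], 30)
  ## no immediate repeats; all four classes present
  expect_true(all(segs$condition[-1] != segs$condition[-nrow(segs)]))
  expect_setequal(unique(segs$condition), c("clean", "bar", "city", "jet"))
  ## exposure balanced within 20%
  expo <- tapply(durs, segs$condition, sum)
  expect_lte((max(expo) - min(expo)) / mean(expo), 0.2)
  ## transition count = segments - 1
  expect_equal(nrow(transitions(s@schedule)), nrow(segs) - 1L)
  ## total duration example: 18 x 60 would give 1080 s of stimulus
  expect_error(buildSession(nBlocks = 1), "2 blocks")
  ## determinism
  s2 <- buildSession(nBlocks = 4, blockDuration = 30, seed = 7, leadIn = 30)
  expect_identical(s@stimulus@values, s2@stimulus@values)
  expect_identical(segments(s@schedule), segments(s2@schedule))
})

test_that("every noisy segment realizes the requested SNR within 0.1 dB", {
  s <- tinySession()
  segs <- segments(s@schedule)
  rate <- s@stimulus@rate
  for (i in which(segs$condition != "clean")) {
    idx <- (round(segs$start[i] * rate) + 1):round(segs$end[i] * rate)
    pf <- mean(s@foreground@values[idx, ]^2)
    pb <- mean((s@stimulus@values[idx, ] - s@foreground@values[idx, ])^2)
    expect_lt(abs(10 * log10(pf / pb) - 6), 0.1)
  }
})

test_that("static encoder responses equal an independent convolution oracle", {
  s <- buildSession(nBlocks = 2, blockDuration = 9, seed = 31, leadIn = 6)
  enc <- makeEncoderPopulation("static_linear", 1, seed = 32,
                               outputNoiseSd = 0)
  sim <- simulateResponses(s, enc, seed = 33)
  X <- sim@stimulus@values
  W <- enc[[1]]@baseFilter
  b0 <- enc[[1]]@driveBias
  ## plain double-loop convolution oracle
  oracle <- vapply(seq_len(nrow(X)), function(t) {
    acc <- b0
    for (l in seq_len(min(t, ncol(W)))) acc <- acc + sum(W[, l] * X[t - l + 1, ])
    log1p(exp(min(acc, 30))) + max(acc - 30, 0)
  }, 0)
  expect_equal(respValues(sim)[1, ], oracle, tolerance = 1e-12)
})

test_that("responses are z-scored to the silent lead-in", {
  s <- tinySession()
  bIdx <- seq_len(round(s@schedule@leadIn * s@stimulus@rate))
  base <- respValues(s)[, bIdx]
  expect_lt(max(abs(rowMeans(base))), 1e-6)
  popSd <- function(x) sqrt(mean((x - mean(x))^2))
  expect_lt(max(abs(apply(base, 1, popSd) - 1)), 1e-6)
})

test_that("gain encoder matches its closed-form steady-state gain ratio", {
  ## constant-contrast stretches: steady-state gain = k (c + 0.3)^-alpha,
  ## so response ratio between stretches equals the gain ratio
  s <- buildSession(nBlocks = 2, blockDuration = 15, seed = 41, leadIn = 20)
  encG <- makeEncoderPopulation("gain_adaptive", 1, seed = 42,
                                outputNoiseSd = 0)
  encS <- makeEncoderPopulation("static_linear", 1, seed = 42,
                                outputNoiseSd = 0)
  ## same base filter by construction (same seed)
  expect_equal(encG[[1]]@baseFilter, encS[[1]]@baseFilter)
  simG <- simulateResponses(s, encG, seed = 43)
  simS <- simulateResponses(s, encS, seed = 43)
  rate <- s@stimulus@rate
  X <- s@stimulus@values
  ## the raw (unnormalized) responses obey rG = g(t) * rS with
  ## g relaxing toward k (c + 0.3)^-alpha
  contrast <- dstrfadapt:::.trailingContrast(X, rate)
  gTarget <- encG[[1]]@gainK * (contrast + 0.3)^(-encG[[1]]@gainAlpha)
  g <- dstrfadapt:::.relaxTowards(gTarget, encG[[1]]@tauAdapt, 1 / rate)
  expect_equal(respValues(simG)[1, ], g * respValues(simS)[1, ],
               tolerance = 1e-10)
})

test_that("unknown encoder kinds and oversize lags are rejected", {
  s <- tinySession()
  enc <- makeEncoderPopulation("static_linear", 1, seed = 1)
  expect_error(methods::new("GroundTruthEncoder", kind = "nope",
                            baseFilter = enc[[1]]@baseFilter),
               "unknown encoder kind")
})
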