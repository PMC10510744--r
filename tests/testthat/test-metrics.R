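test_that("stimulus contrast matches hand-computed values", {
  ## constant segment floors at -120 dB
  expect_equal(stimulusContrast(matrix(3, 10, 23)), -120)
  ## half zeros / half twos: population sd = 1 -> 0 dB
  seg <- matrix(c(0, 2), 10, 22)
  expect_equal(stimulusContrast(seg), 0, tolerance = 1e-12)
  ## doubling all bins adds 20 log10(2) = 6.02 dB
  set.seed(1)
  seg2 <- matrix(rexp(200), 10, 20)
  expect_equal(stimulusContrast(2 * seg2) - stimulusContrast(seg2),
               20 * log10(2), tolerance = 1e-10)
})

test_that("dSTRF gain decomposes by region and is homogeneous", {
  f <- matrix(c(1, 1, -1, -1), 2, 2)  # [[1,-1],[1,-1]]
  expect_equal(dstrfGain(f, "full"), 1)
  expect_equal(dstrfGain(f, "excitatory"), 0.5)
  expect_equal(dstrfGain(f, "inhibitory"), 0.5)
  expect_equal(dstrfGain(matrix(0, 3, 3), "full"), 0)
  set.seed(2)
  g <- matrix(rnorm(20), 4, 5)
  expect_equal(dstrfGain(-3 * g), 3 * dstrfGain(g), tolerance = 1e-12)
})

test_that("noise-spectrum correlation hits its fixed points", {
  set.seed(3)
  target <- rexp(23)
  ## profile proportional to the target
  frame <- outer(target, rep(0.2, 65))
  expect_equal(noiseSpectrumCorrelation(frame, target, "full"), 1)
  expect_equal(noiseSpectrumCorrelation(-frame, target, "full"), -1)
  ## profile orthogonalized against the target (Gram-Schmidt)
  v <- rnorm(23)
  tc <- target - mean(target)
  vc <- v - mean(v)
  orth <- vc - sum(vc * tc) / sum(tc^2) * tc
  frameO <- outer(orth, rep(1, 65))
  expect_lt(abs(noiseSpectrumCorrelation(frameO, target, "full")), 1e-10)
  ## fully masked frame -> NA flag
  expect_true(is.na(noiseSpectrumCorrelation(matrix(0, 23, 65), target)))
  ## region profiles sum to the full profile exactly
  f <- matrix(rnorm(23 * 65), 23, 65)
  expect_equal(rowMeans(pmax(f, 0)) + rowMeans(pmin(f, 0)), rowMeans(f),
               tolerance = 1e-12)
})

test_that("transition alignment counts and filters are correct", {
  segs <- data.frame(start = c(0, 3, 6, 12, 15),
                     end = c(3, 6, 12, 15, 21),
                     condition = c("clean", "bar", "clean", "jet", "city"))
  sched <- methods::new("NoiseSchedule", segments = segs,
                        blockBounds = c(0, 21), leadIn = 0)
  x <- seq_len(2100) * 0.001
  ## clean->noise from clean only: clean->bar at 3, clean->jet at 12
  al <- alignToTransitions(x, sched, "to_noise_from_clean",
                           pre = 0.5, post = 1.15)
  expect_identical(nrow(al$values), 2L)
  expect_identical(al$transitions$to, c("bar", "jet"))
  ## noise-to-noise transitions never pass the clean_noise filter
  alc <- alignToTransitions(x, sched, "clean_noise", pre = 0.5, post = 1.15)
  expect_false(any(alc$transitions$from != "clean" &
                     alc$transitions$to != "clean"))
  ## the output grid spans exactly (pre + post) * rate samples
  expect_identical(ncol(al$values), as.integer(round((0.5 + 1.15) * 100)))
  ## the transition sample belongs to the post condition
  expect_equal(al$time[which(al$time == 0)], 0)
  ## windows extending beyond the adjoining segments are excluded
  alLong <- alignToTransitions(x, sched, "to_noise_from_clean",
                               pre = 0.5, post = 4)
  expect_identical(nrow(alLong$values), 0L)  # 3 s segments cannot hold 4 s
})

test_that("paired index t-test matches the textbook formula", {
  ## pre [1,2,3], post [2,4,3]: differences (1,2,0) -> t = sqrt(3)
  expect_equal(indexTtest(c(1, 2, 3), c(2, 4, 3)), sqrt(3),
               tolerance = 1e-12)
  ## antisymmetry and null
  expect_equal(indexTtest(c(2, 4, 3), c(1, 2, 3)), -sqrt(3),
               tolerance = 1e-12)
  expect_equal(indexTtest(c(1, 2, 3), c(1, 2, 3)), 0)
  ## degenerate equal nonzero shift is capped, not infinite
  expect_equal(indexTtest(c(1, 2, 3), c(2, 3, 4)), 1e6)
  expect_error(indexTtest(1:3, 1:4), "equal length")
  ## indices are invariant to adding a constant to the whole time course
  set.seed(4)
  a <- rnorm(50); b <- rnorm(50)
  expect_equal(indexTtest(a, b), indexTtest(a + 7, b + 7),
               tolerance = 1e-9)
})

test_that("gain-change and noise-filtering indices use the stated windows", {
  ## build an aligned object directly: flat time course -> both zero
  tgrid <- seq(-0.5, 1.15 - 0.01, by = 0.01)
  flat <- list(values = matrix(5, 4, length(tgrid)), time = tgrid,
               transitions = NULL)
  expect_equal(gainChangeIndex(flat), 0)
  expect_equal(noiseFilteringIndex(flat), 0)
  ## a step increase after the transition: positive gain-change index,
  ## negative (sign-flipped) noise-filtering index
  step <- list(values = matrix(rep(ifelse(tgrid >= 0, 6, 5) +
                                     seq_along(tgrid) * 1e-3, each = 4),
                               4, length(tgrid), byrow = FALSE),
               time = tgrid, transitions = NULL)
  step$values <- matrix(rep(ifelse(tgrid >= 0, 6, 5), each = 4), 4,
                        length(tgrid), byrow = FALSE) +
    matrix(rnorm(4 * length(tgrid), 0, 0.01), 4)
  expect_gt(gainChangeIndex(step), 0)
  expect_lt(noiseFilteringIndex(step), 0)
  ## the pre and post windows hold 50 positional pairs each
  pre <- dstrfadapt:::.windowPositions(flat, -0.5, 0)
  post <- dstrfadapt:::.windowPositions(flat, 0.65, 1.15)
  expect_length(pre, 50L)
  expect_length(post, 50L)
})

test_that("adaptation index detects decaying transients and uses 70-sample windows", {
  segs <- data.frame(start = c(0, 6, 12, 18, 24),
                     end = c(6, 12, 18, 24, 30),
                     condition = c("clean", "bar", "clean", "jet", "clean"))
  sched <- methods::new("NoiseSchedule", segments = segs,
                        blockBounds = c(0, 30), leadIn = 0)
  n <- 3000
  tr <- transitions(sched)
  ## flat response -> zero index
  flatIdx <- adaptationIndex(rep(2, n), sched)
  expect_equal(unname(flatIdx$index), 0)
  ## exponential transient decaying to baseline -> positive index,
  ## increasing with transient amplitude
  mk <- function(amp) {
    r <- rnorm(n, 0, 0.8)
    for (t0 in round(tr$time * 100) + 1) {
      idx <- t0:min(n, t0 + 199)
      r[idx] <- r[idx] + amp * exp(-(seq_along(idx) - 1) / 30)
    }
    r
  }
  set.seed(5)
  i1 <- adaptationIndex(mk(0.5), sched)$index
  set.seed(5)
  i3 <- adaptationIndex(mk(2), sched)$index
  expect_gt(i1, 0)
  expect_gt(i3, i1)
  ## window membership: [0, 0.7) and [2, 2.7) are 70 samples each
  expect_length(seq(0, 0.7 - 0.01, by = 0.01), 70L)
  ## 3-s segments are excluded and counted
  segs3 <- data.frame(start = c(0, 3, 6), end = c(3, 6, 9),
                      condition = c("clean", "bar", "clean"))
  sched3 <- methods::new("NoiseSchedule", segments = segs3,
                         blockBounds = c(0, 9), leadIn = 0)
  res3 <- adaptationIndex(rep(1, 900), sched3)
  expect_identical(res3$nExcluded, 2L)
})
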