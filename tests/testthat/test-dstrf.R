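test_that("dSTRF of a purely linear network equals its weights", {
  ## one layer, kernel 1, linear path via positive input and abs weights
  cfg <- cnnConfig(nLayers = 1, nKernels = 4, kernelSize = 1, dilations = 1,
                   nFreq = 5)
  m <- initCnn(cfg, 1, seed = 1)
  m@convW[[1]] <- abs(m@convW[[1]])
  m@outW <- abs(m@outW)
  xw <- matrix(1, 5, 1)
  d <- computeDstrf(m, xw)
  ## with all ReLUs active the map is exactly outW %*% W1
  expected <- as.numeric(m@outW %*% m@convW[[1]][, , 1])
  expect_equal(as.numeric(d), expected, tolerance = 1e-12)
})

test_that("linearity identity holds for random ReLU networks", {
  set.seed(11)
  worst <- 0
  for (rep in 1:10) {
    cfg <- cnnConfig(nKernels = sample(6:14, 1))
    m <- initCnn(cfg, 3, seed = rep)
    for (i in 1:10) {
      xw <- matrix(rexp(23 * 65), 23, 65)
      worst <- max(worst, max(dstrfLinearityCheck(m, xw)$relDiff))
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("an input silencing the first layer yields an all-zero dSTRF", {
  cfg <- cnnConfig(nKernels = 6)
  m <- initCnn(cfg, 1, seed = 5)
  ## force all first-layer preactivations negative for a constant input:
  ## make every kernel tap strictly negative, input strictly positive
  m@convW[[1]] <- -abs(m@convW[[1]]) - 0.01
  xw <- matrix(1, 23, 65)
  d <- computeDstrf(m, xw)
  expect_true(all(d == 0))
})

test_that("sign-consistency masking follows the 15-of-17 rule", {
  ## 17 identical frames pass any threshold and reproduce the frame
  f <- matrix(rnorm(12), 3, 4)
  out <- averageAndMask(rep(list(f), 17), minAgree = 15)
  expect_equal(out, f)
  ## a bin positive in 14 of 17 members is masked to zero
  frames <- c(rep(list(matrix(1, 1, 1)), 14), rep(list(matrix(-1, 1, 1)), 3))
  expect_equal(averageAndMask(frames, 15)[1, 1], 0)
  ## {+1 x16, -1 x1} passes and averages to 15/17
  frames2 <- c(rep(list(matrix(1, 1, 1)), 16), list(matrix(-1, 1, 1)))
  expect_equal(averageAndMask(frames2, 15)[1, 1], 15 / 17)
  ## zeros count toward neither sign
  frames3 <- c(rep(list(matrix(1, 1, 1)), 14), rep(list(matrix(0, 1, 1)), 3))
  expect_equal(averageAndMask(frames3, 15)[1, 1], 0)
  expect_error(averageAndMask(list(), 1), "empty")
  expect_error(averageAndMask(frames2, 18), "exceed")
})

test_that("masking threshold scales as ceiling(M * 15/17)", {
  expect_identical(defaultMaskThreshold(17), 15L)
  expect_identical(defaultMaskThreshold(3), 3L)
  expect_identical(defaultMaskThreshold(8), 8L)
  expect_identical(defaultMaskThreshold(16), 15L)
})

test_that("lowering minAgree never zeroes more bins, and masking is a fixed point", {
  set.seed(21)
  frames <- lapply(1:5, function(i) array(rnorm(3 * 4 * 6), c(3, 4, 6)))
  zeroCount <- vapply(5:1, function(k)
    sum(averageAndMask(frames, k) == 0), 0)
  expect_true(all(diff(zeroCount) <= 0))
  ## fixed point: re-masking the masked average changes nothing
  m <- averageAndMask(frames, 4)
  expect_equal(averageAndMask(rep(list(m), 5), 4), m)
})

test_that("dSTRF frames are invariant to activation-preserving perturbations", {
  cfg <- cnnConfig(nKernels = 8)
  m <- initCnn(cfg, 2, seed = 9)
  set.seed(10)
  xw <- matrix(rexp(23 * 65) + 0.5, 23, 65)
  d1 <- computeDstrf(m, xw, electrodes = 1)
  ## a tiny perturbation cannot flip any ReLU far from its threshold;
  ## verify the activation pattern is unchanged, then the frame is
  ## bit-identical (exact local linearity)
  fw1 <- dstrfadapt:::.cnnForward(m, xw)
  eps <- 1e-9
  xw2 <- xw + eps
  fw2 <- dstrfadapt:::.cnnForward(m, xw2)
  d2 <- computeDstrf(m, xw2, electrodes = 1)
  expect_identical(d1, d2)
})

test_that("timecourse tensors cover exactly the valid samples of a block", {
  fx <- linearFixture()
  tens <- linearDstrf()
  idx <- fx$blocks[[1]]
  valid <- idx[idx >= idx[1] + 64L]
  expect_true(all(frameTimes(tens[[1]]) %in% valid))
  ## full-coverage bookkeeping: valid frames = block length - (RF - 1)
  expect_identical(length(valid), length(idx) - 64L)
  expect_identical(dim(dstrfFrames(tens[[1]]))[2:3], c(23L, 65L))
  expect_identical(tens[[1]]@nMembers, 3L)
  expect_identical(tens[[1]]@maskThreshold, 3L)
})
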