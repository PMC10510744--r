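test_that("receptive field matches the closed form and a perturbation probe", {
  ## reference architecture: 65 samples = 650 ms at 100 Hz
  cfg <- cnnConfig()
  expect_identical(receptiveField(cfg), 65L)
  expect_identical(receptiveFieldProbe(cfg, seed = 3), 65L)
  ## degenerate and small cases
  expect_identical(receptiveField(cnnConfig(1, 4, 1, 1)), 1L)
  expect_identical(receptiveField(cnnConfig(2, 4, 5, c(1, 1))), 9L)
  expect_identical(receptiveFieldProbe(cnnConfig(2, 4, 5, c(1, 1))), 9L)
})

test_that("ridge STRF shrinks with lambda and handles zero responses", {
  s <- tinySession()
  blocks <- blockIndices(s@schedule)
  X <- s@stimulus@values
  ## all-zero response gives (near-)zero weights
  z <- matrix(0, 1, nrow(X))
  mz <- fitStrf(X, z, blocks, lambdas = 10)
  expect_lt(max(abs(strfWeights(mz))), 1e-8)
  ## weight norm decreases monotonically in lambda
  Y <- respValues(s)
  norms <- vapply(c(1, 100, 1e4, 1e6), function(lam) {
    m <- fitStrf(X, Y[1, , drop = FALSE], blocks, lambdas = lam)
    sqrt(sum(strfWeights(m)^2))
  }, 0)
  expect_true(all(diff(norms) < 0))
  expect_error(fitStrf(X[1:10, ], Y[, 1:10], list(1:10)), "fewer samples")
})

test_that("per-condition STRFs use only within-condition windows", {
  s <- tinySession()
  blocks <- blockIndices(s@schedule)
  rate <- s@stimulus@rate
  condVec <- conditionAt(s@schedule,
                         (seq_len(nrow(s@stimulus@values)) - 1) / rate)
  ## use the condition with the most coverage in block 1
  blockConds <- condVec[blocks[[1]]]
  cond <- names(which.max(table(blockConds)))
  rows <- dstrfadapt:::.validRows(blocks[[1]], 65, condVec, cond)
  expect_true(length(rows) > 0)
  for (t in rows[c(1, length(rows))]) {
    expect_true(all(condVec[(t - 64):t] == cond))
  }
  ## windows straddling two conditions are rejected
  rowsAll <- dstrfadapt:::.validRows(blocks[[1]], 65)
  expect_gt(length(rowsAll), length(rows))
})

test_that("CNN training is deterministic in the seed and learns a linear map", {
  s <- tinySession()
  blocks <- blockIndices(s@schedule)
  cfg <- cnnConfig(nKernels = 8)
  args <- list(s@stimulus, s@responses, blocks[1], valBlock = blocks[[2]],
               config = cfg, epochs = 8, seed = 42)
  m1 <- do.call(trainCnn, args)
  m2 <- do.call(trainCnn, args)
  expect_identical(m1@convW, m2@convW)
  expect_identical(m1@outW, m2@outW)
  expect_s3_class(m1@trainLog, "data.frame")
  expect_true(all(is.finite(m1@trainLog$train)))
})

test_that("STP resource dynamics obey their closed forms", {
  ## zero drive: resource stays at 1
  expect_equal(dstrfadapt:::.stpResource(rep(0, 100), 0.4, 0.2, 0.01),
               rep(1, 100))
  ## constant drive: steady state (1/tau) / (1/tau + u d) within 1%
  d <- 5; u <- 0.4; tau <- 0.2
  x <- dstrfadapt:::.stpResource(rep(d, 3000), u, tau, 0.01)
  expect_equal(x[3000], (1 / tau) / (1 / tau + u * d), tolerance = 0.01)
  ## resource bounded in [0,1] for any nonnegative drive
  set.seed(1)
  x2 <- dstrfadapt:::.stpResource(rexp(2000, 1 / 10), 0.9, 0.05, 0.005)
  expect_true(all(x2 >= 0 & x2 <= 1))
})

test_that("stpForward handles degenerate parameter settings", {
  fir <- matrix(rnorm(23 * 65, 0, 0.05), 23, 65)
  nl <- c(base = 0, amplitude = 2, shift = 1, slope = 3)
  X <- matrix(rexp(400 * 23), 400, 23)
  ## u = 0: no depression, constant effective drive 0 -> constant output
  m0 <- methods::new("StpModel", fir = fir, nlParams = nl, u = 0,
                     tauRec = 0.2)
  y0 <- stpForward(m0, X)
  expect_equal(diff(range(y0)), 0)
  expect_equal(y0[1], unname(nl["base"] +
                               nl["amplitude"] * exp(-exp(-nl["slope"] *
                                                            (0 - nl["shift"])))))
  expect_error(methods::new("StpModel", fir = fir, nlParams = nl, u = 0.4,
                            tauRec = -1), "tauRec")
})

test_that("fitStp recovers depression parameters from self-generated data", {
  ## 60 s of stimulus; response generated by a known LN+STP model
  s <- buildSession(nBlocks = 2, blockDuration = 30, seed = 61, leadIn = 20)
  enc <- makeEncoderPopulation("static_linear", 1, seed = 62)
  truth <- methods::new("StpModel", fir = enc[[1]]@baseFilter,
                        nlParams = c(base = 0, amplitude = 3, shift = 1.2,
                                     slope = 1.5),
                        u = 0.45, tauRec = 0.25)
  set.seed(63)
  y <- stpForward(truth, s@stimulus) + rnorm(nrow(s@stimulus@values), 0, 0.05)
  blocks <- blockIndices(s@schedule)
  ## the known FIR initializes the filter stage; the STP and nonlinearity
  ## parameters are then recovered by the optimizer
  init <- methods::new("StrfModel",
                       weights = array(truth@fir, c(23, 65, 1)),
                       bias = 0, lambda = 1, lambdaGrid = 1,
                       cvCorr = NA_real_)
  fits <- fitStp(s@stimulus, matrix(y, 1), blocks, nRestarts = 5,
                 seed = 64, strfInit = init)
  expect_length(fits, 1)
  ## u recovered within +/- 30%
  expect_lt(abs(fits[[1]]@u - 0.45) / 0.45, 0.30)
  ## deterministic given the seed
  fits2 <- fitStp(s@stimulus, matrix(y, 1), blocks, nRestarts = 5,
                  seed = 64, strfInit = init)
  expect_equal(fits[[1]]@u, fits2[[1]]@u)
})

test_that("fitStp finds no depression in static linear data", {
  s <- buildSession(nBlocks = 2, blockDuration = 21, seed = 71, leadIn = 20)
  enc <- makeEncoderPopulation("static_linear", 1, seed = 72,
                               outputNoiseSd = 0.05)
  sim <- simulateResponses(s, enc, seed = 73)
  blocks <- blockIndices(sim@schedule)
  strf <- fitStrf(sim@stimulus, sim@responses, blocks)
  fits <- fitStp(sim@stimulus, sim@responses, blocks, nRestarts = 5,
                 seed = 74, strfInit = strf)
  ## depression cannot beat a plain LN fit on static data: fit the same
  ## FIR + Gompertz nonlinearity without any resource dynamics and compare
  m <- fits[[1]]
  rows <- unlist(blocks)
  y <- respValues(sim)[1, rows]
  mseStp <- mean((stpForward(m, sim@stimulus)[rows] - y)^2)
  drive <- dstrfadapt:::.softplus(
    dstrfadapt:::.lagDrive(sim@stimulus@values, strf@weights[, , 1]))[rows]
  gomp <- function(p) mean((p[1] + p[2] * exp(-exp(-p[4] * (drive - p[3]))) -
                              y)^2)
  lnFit <- stats::optim(c(min(y), diff(range(y)), stats::median(drive), 1),
                        gomp, method = "BFGS",
                        control = list(maxit = 300, reltol = 1e-10))
  ## STP improvement over LN alone is below 1% of the LN error
  expect_lt((lnFit$value - mseStp) / lnFit$value, 0.01)
})
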