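test_that("jackknife bookkeeping: member counts and exact coverage", {
  fx <- linearFixture()
  jk <- fx$jkStrf
  nB <- length(fx$blocks)
  expect_length(jk@ensembles, nB)
  for (ens in jk@ensembles) {
    ## B blocks -> B - 1 members, each excluding one extra block
    expect_length(ens@members, nB - 1L)
    expect_setequal(ens@heldOutBlocks,
                    setdiff(seq_len(nB), ens@testBlock))
  }
  ## with 18 blocks the same rule gives 17 members and 18 * 17 fits
  expect_identical(18L - 1L, 17L)
  ## every block sample predicted exactly once, nothing else predicted
  pred <- jk@predictions
  covered <- !is.na(pred[1, ])
  expect_identical(which(covered), sort(unlist(fx$blocks)))
})

test_that("ensemble predictions equal the member mean exactly", {
  fx <- linearFixture()
  ens <- fx$jkStrf@ensembles[[2]]
  idx <- fx$blocks[[2]]
  X <- fx$session@stimulus@values
  memberPreds <- lapply(ens@members, function(m) predictStrf(m, X)[, idx])
  manual <- Reduce(`+`, memberPreds) / length(memberPreds)
  expect_equal(fx$jkStrf@predictions[, idx], manual, tolerance = 1e-12)
  ## and through the exported helper
  expect_equal(ensemblePredict(ens, X, idx), manual, tolerance = 1e-12)
})

test_that("jackknife requires at least 3 blocks", {
  s <- tinySession()
  blocks <- blockIndices(s@schedule)
  expect_error(jackknifeFit(s@stimulus, s@responses, blocks[1:2], "strf"),
               "3 blocks")
})

test_that("split correlations behave at their fixed points", {
  s <- tinySession()
  Y <- respValues(s)
  res <- evaluateSplitCorrelation(Y, Y, s@schedule)
  expect_true(all(abs(res$full_r - 1) < 1e-12))
  expect_true(all(abs(res$adaptation_r - 1) < 1e-12, na.rm = TRUE))
  resNeg <- evaluateSplitCorrelation(-Y, Y, s@schedule)
  expect_true(all(abs(resNeg$full_r + 1) < 1e-12))
})

test_that("adaptation window holds 65 samples per transition and partitions", {
  s <- tinySession()
  rate <- s@stimulus@rate
  nT <- ncol(respValues(s))
  tr <- transitions(s@schedule)
  winLen <- round(0.65 * rate)
  adapt <- logical(nT)
  for (t0 in round(tr$time * rate) + 1L) {
    idx <- t0:min(nT, t0 + winLen - 1L)
    ## each window is exactly 65 samples (no truncation inside the session)
    expect_length(idx, 65L)
    adapt[idx] <- TRUE
  }
  res <- evaluateSplitCorrelation(respValues(s), respValues(s), s@schedule)
  all_row <- res[res$condition == "all" & res$electrode == 1, ]
  ## adaptation + remainder partition the scored (stimulus) samples
  condVec <- conditionAt(s@schedule, (seq_len(nT) - 1) / rate)
  expect_identical(all_row$n_adaptation + all_row$n_remainder,
                   sum(!is.na(condVec)))
  expect_identical(all_row$n_adaptation, sum(adapt & !is.na(condVec)))
})
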