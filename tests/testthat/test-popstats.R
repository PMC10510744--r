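test_that("responsive-electrode selection separates signal from null", {
  set.seed(31)
  rate <- 100
  n <- 50
  nT <- 400
  Y <- matrix(rnorm(20 * nT), 20, nT)
  onset <- 2  # seconds
  ## electrode 1: a 5-sd step at onset
  Y[1, (onset * rate + 1):nT] <- Y[1, (onset * rate + 1):nT] + 5
  sel <- selectResponsive(Y, onset = onset)
  expect_true(1 %in% sel$selected)
  ## an exactly unchanged electrode is never selected
  Y2 <- Y
  Y2[2, ] <- rep(c(0.3, -0.1, 0.7), length.out = nT)  # periodic, pre == post
  sel2 <- selectResponsive(Y2, onset = onset)
  expect_false(2 %in% sel2$selected)
})

test_that("BH selection keeps the null false-selection proportion at q", {
  ## 2000 replicates of 200 null electrodes, vectorized paired t-tests
  set.seed(32)
  q <- 0.01
  nEl <- 200
  nRep <- 2000
  n <- 50
  falsePicks <- 0
  for (r in seq_len(nRep)) {
    D <- matrix(rnorm(nEl * n), nEl, n)  # post - pre differences
    mu <- rowMeans(D)
    sdv <- sqrt((rowSums(D^2) - n * mu^2) / (n - 1))
    tt <- mu / (sdv / sqrt(n))
    p <- 2 * pt(-abs(tt), df = n - 1)
    falsePicks <- falsePicks + sum(p.adjust(p, "BH") < q)
  }
  prop <- falsePicks / (nEl * nRep)
  bound <- q + 2 * sqrt(q * (1 - q) / (nEl * nRep))
  expect_lte(prop, bound)
})

test_that("subject-controlled t-test collapses to one-sample t and absorbs offsets", {
  set.seed(33)
  x <- rnorm(20, mean = 0.5)
  ## single subject: identical to the ordinary one-sample t-test
  res <- subjectControlledTtest(x, rep("S1", 20))
  tt <- t.test(x)
  expect_equal(res$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(res$p, tt$p.value, tolerance = 1e-12)
  ## per-subject constant offsets are absorbed: the residual structure
  ## (hence the standard error) is governed by within-subject variation
  subj <- rep(c("S1", "S2", "S3", "S4"), each = 10)
  y <- rnorm(40, 0.3)
  offs <- c(S1 = -5, S2 = 2, S3 = 9, S4 = -1)[subj]
  r0 <- subjectControlledTtest(y, subj)
  r1 <- subjectControlledTtest(y + offs - mean(offs), subj)
  expect_equal(r0$t, r1$t, tolerance = 1e-8)
  ## all-zero values give t = 0
  expect_equal(subjectControlledTtest(rep(0, 12),
                                      rep(c("a", "b"), 6))$t, 0)
})

test_that("mixed-effects improvement model matches OLS without subject variance", {
  set.seed(34)
  n <- 60
  d <- data.frame(electrode = 1:n,
                  subject = rep(sprintf("S%d", 1:4), length.out = n),
                  condition = "bar",
                  gain_change = rnorm(n), noise_filtering = rnorm(n))
  d$improvement <- 0.2 + 0.5 * d$gain_change - 0.3 * d$noise_filtering +
    rnorm(n, 0, 0.05)
  res <- suppressWarnings(fitImprovementModel(d))
  ols <- lm(improvement ~ gain_change + noise_filtering, data = d)
  for (term in c("(Intercept)", "gain_change", "noise_filtering")) {
    expect_equal(res$estimate[res$term == term],
                 unname(coef(ols)[term]), tolerance = 1e-3)
  }
  ## true coefficient of 0.5 covered by the CI
  gc <- res[res$term == "gain_change", ]
  expect_lt(gc$ciLow, 0.5)
  expect_gt(gc$ciHigh, 0.5)
  expect_true(gc$significant)
})

test_that("mixed-effects model recovers planted coefficients with subject effects", {
  set.seed(35)
  n <- 100
  subj <- rep(sprintf("S%d", 1:5), length.out = n)
  subjEff <- c(S1 = -0.1, S2 = 0.05, S3 = 0.12, S4 = -0.02, S5 = 0)[subj]
  d <- data.frame(electrode = 1:n, subject = subj, condition = "jet",
                  gain_change = rnorm(n), noise_filtering = rnorm(n))
  d$improvement <- subjEff + 0.5 * d$gain_change + rnorm(n, 0, 0.1)
  res <- suppressWarnings(fitImprovementModel(d))
  gc <- res[res$term == "gain_change", ]
  expect_lt(gc$ciLow, 0.5)
  expect_gt(gc$ciHigh, 0.5)
})

test_that("null indices rarely produce significant fixed effects", {
  set.seed(36)
  covered <- 0
  nSim <- 100
  for (i in seq_len(nSim)) {
    n <- 40
    d <- data.frame(electrode = 1:n,
                    subject = rep(sprintf("S%d", 1:4), length.out = n),
                    condition = "city",
                    gain_change = rnorm(n), noise_filtering = rnorm(n),
                    improvement = rnorm(n, 0, 0.2))
    res <- suppressWarnings(fitImprovementModel(d))
    both <- res[res$term %in% c("gain_change", "noise_filtering"), ]
    covered <- covered + all(!both$significant)
  }
  ## both 95% CIs cover 0 jointly in the large majority of null
  ## simulations. Nominal joint coverage would be 0.95^2 = 0.903; Wald
  ## intervals from a random-intercept fit with only 4 subjects are known
  ## to be slightly anticonservative, so the realized joint coverage sits
  ## a few points below that.
  expect_gte(covered / nSim, 0.8)
})

test_that("Ward clustering recovers planted blobs and orders groups", {
  set.seed(37)
  blobA <- matrix(rnorm(10 * 8, mean = 3, sd = 0.4), 10, 8)
  blobB <- matrix(rnorm(12 * 8, mean = -1, sd = 0.4), 12, 8)
  X <- rbind(blobA, blobB)
  colnames(X) <- c(paste0("exc_", c("bar", "city", "jet", "clean")),
                   paste0("inh_", c("bar", "city", "jet", "clean")))
  res <- clusterNoiseFiltering(X)
  ## exact recovery, with group 1 = the high-excitatory blob
  expect_identical(unname(res$groups), rep(c(1L, 2L), c(10, 12)))
  ## permuting rows permutes labels consistently (same partition)
  perm <- sample(nrow(X))
  res2 <- clusterNoiseFiltering(X[perm, ])
  expect_identical(unname(res2$groups), unname(res$groups[perm]))
  ## rows with missing features are dropped and reported
  X2 <- X
  X2[3, 2] <- NA
  res3 <- clusterNoiseFiltering(X2)
  expect_identical(res3$dropped, 3L)
  ## identical rows are flagged degenerate
  X3 <- matrix(1, 6, 8, dimnames = list(NULL, colnames(X)))
  expect_true(clusterNoiseFiltering(X3)$degenerate)
  expect_error(clusterNoiseFiltering(X[1:3, ]), "at least 4")
})

test_that("rank-sum comparisons match exact enumeration and find planted bumps", {
  ## closed form for {1,2,3} vs {4,5,6}: all ranks in the second group,
  ## exact two-sided p = 2 / choose(6,3) = 0.1
  wt <- wilcox.test(c(4, 5, 6), c(1, 2, 3), exact = TRUE)
  expect_equal(unname(wt$statistic), 9)  # Mann-Whitney U
  expect_equal(wt$p.value, 0.1, tolerance = 1e-12)
  ## enumeration oracle for the U statistic
  allU <- combn(6, 3, function(ix) {
    g2 <- c(1, 2, 3, 4, 5, 6)[ix]
    sum(outer(g2, setdiff(c(1, 2, 3, 4, 5, 6), g2), ">"))
  })
  expect_equal(mean(allU >= 9) * 2, 0.1, tolerance = 1e-12)
  ## rank-sum is invariant under monotone transforms of pooled values
  set.seed(38)
  a <- rexp(15); b <- rexp(15) + 0.5
  p1 <- wilcox.test(a, b, exact = FALSE)$p.value
  p2 <- wilcox.test(log(a), log(b), exact = FALSE)$p.value
  expect_equal(p1, p2, tolerance = 1e-12)

  ## compareGroups: identical groups -> no signal; planted bump detected
  nEl <- 16
  tgrid <- seq(-0.5, 3 - 0.01, by = 0.01)
  base <- matrix(rnorm(nEl * length(tgrid), 0, 0.1), nEl)
  groups <- rep(c(1L, 2L), each = nEl / 2)
  adIdx <- rnorm(nEl)
  resNull <- compareGroups(groups, adIdx, base, tgrid)
  expect_gt(resNull$adaptationTest$p, 0.05)
  ## bump on group 2 between 0.1 and 0.4 s, plus higher adaptation indices
  bump <- base
  bumpWin <- tgrid >= 0.1 & tgrid < 0.4
  bump[groups == 2, bumpWin] <- bump[groups == 2, bumpWin] + 1
  adIdx2 <- adIdx + ifelse(groups == 2, 3, 0)
  res <- compareGroups(groups, adIdx2, bump, tgrid)
  expect_lt(res$adaptationTest$p, 0.01)
  expect_false(is.null(res$significantRegions))
  ## the detected region overlaps the planted bump
  overlap <- any(res$significantRegions$start < 0.4 &
                   res$significantRegions$end > 0.1)
  expect_true(overlap)
  expect_error(compareGroups(c(1, 1, 2), 1:3, base[1:3, ], tgrid),
               "at least 2")
})
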