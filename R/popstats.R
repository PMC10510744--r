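## Population-level statistics: responsive-electrode selection,
## subject-controlled tests, mixed-effects improvement models, Ward
## clustering of noise-filtering profiles, and group comparisons.

#' Select speech-responsive electrodes
#'
#' Paired t-test per electrode between the response in the half second
#' before the first speech onset and the half second after, followed by
#' Benjamini-Hochberg correction across electrodes at level `q`.
#'
#' @param resp [ResponseMatrix-class] or electrodes x time matrix.
#' @param onset Onset time in seconds (default: end of the lead-in).
#' @param window Window length in seconds on each side (default 0.5).
#' @param q FDR level (default 0.01).
#' @param rate Sampling rate in Hz.
#' @return List with `selected` (integer indices), `pValues` and
#'   `pAdjusted`.
#' @export
selectResponsive <- function(resp, onset = NULL, window = 0.5, q = 0.01,
                             rate = 100) {
  Y <- if (methods::is(resp, "ResponseMatrix")) resp@values else
    as.matrix(resp)
  if (methods::is(resp, "ResponseMatrix") && is.null(onset))
    onset <- resp@baselineWindow[2]
  if (is.null(onset)) stop("supply the speech onset time")
  n <- round(window * rate)
  s0 <- round(onset * rate)
  preIdx <- (s0 - n + 1L):s0
  postIdx <- (s0 + 1L):(s0 + n)
  p <- vapply(seq_len(nrow(Y)), function(e) {
    d <- Y[e, postIdx] - Y[e, preIdx]
    if (stats::sd(d) < 1e-12) return(1)
    stats::t.test(Y[e, postIdx], Y[e, preIdx], paired = TRUE)$p.value
  }, 0)
  padj <- stats::p.adjust(p, method = "BH")
  list(selected = which(padj < q), pValues = p, pAdjusted = padj)
}

#' Subject-controlled one-sample t-test
#'
#' Tests whether a per-electrode distribution is centered away from zero
#' while absorbing subject-level offsets: the values are regressed on an
#' intercept plus sum-coded subject indicators, and the intercept's t
#' statistic is reported. With a single subject this reduces exactly to
#' the ordinary one-sample t-test. For paired comparisons pass the
#' per-electrode differences.
#'
#' @param values Numeric vector, one value per electrode.
#' @param subjects Subject label per electrode.
#' @return List with `t`, `p`, `df` and `estimate` (the adjusted mean).
#' @export
subjectControlledTtest <- function(values, subjects) {
  stopifnot(length(values) == length(subjects))
  ok <- is.finite(values)
  values <- values[ok]
  subjects <- factor(subjects[ok])
  if (length(values) < 2) stop("need at least 2 electrodes")
  if (nlevels(subjects) == 1L) {
    tt <- stats::t.test(values)
    return(list(t = unname(tt$statistic), p = tt$p.value,
                df = unname(tt$parameter), estimate = mean(values)))
  }
  X <- stats::model.matrix(~subj,
    data = data.frame(subj = subjects),
    contrasts.arg = list(subj = "contr.sum"))
  fit <- stats::lm.fit(X, values)
  df <- length(values) - ncol(X)
  if (df < 1) stop("insufficient data for a subject-controlled test")
  sigma2 <- sum(fit$residuals^2) / df
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(sigma2 * XtXinv[1, 1])
  tval <- if (se == 0) {
    if (abs(fit$coefficients[1]) < 1e-12) 0 else sign(fit$coefficients[1]) * 1e6
  } else fit$coefficients[1] / se
  list(t = unname(tval), p = 2 * stats::pt(-abs(tval), df), df = df,
       estimate = unname(fit$coefficients[1]))
}

#' Mixed-effects prediction of model improvement from adaptation indices
#'
#' Per noise condition, fits improvement ~ gainChange + noiseFiltering +
#' (1 | subject): does an electrode's gain-change index and (inhibitory)
#' noise-filtering index in that condition predict how much the CNN
#' improves over the linear STRF? Falls back to ordinary least squares
#' with a warning when the random-effect fit is singular.
#'
#' @param indexTable data.frame with columns `electrode`, `subject`,
#'   `condition`, `gain_change`, `noise_filtering`, `improvement`.
#' @return data.frame per condition and term with estimate, 95% CI,
#'   significance flag, prediction correlation and the fit type.
#' @export
fitImprovementModel <- function(indexTable) {
  need <- c("electrode", "subject", "condition", "gain_change",
            "noise_filtering", "improvement")
  if (!all(need %in% names(indexTable)))
    stop("indexTable lacks required columns")
  out <- list()
  for (cc in sort(unique(indexTable$condition))) {
    d <- indexTable[indexTable$condition == cc, , drop = FALSE]
    d <- d[stats::complete.cases(d[, c("gain_change", "noise_filtering",
                                       "improvement")]), , drop = FALSE]
    if (nrow(d) < 10 || length(unique(d$subject)) < 2) {
      warning(sprintf("condition %s: insufficient data for the mixed model",
                      cc))
      next
    }
    fitType <- "lmer"
    fit <- tryCatch(
      lme4::lmer(improvement ~ gain_change + noise_filtering + (1 | subject),
                 data = d, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular =
                   lme4::.makeCC(action = "ignore", tol = 1e-4))),
      error = function(err) NULL)
    singular <- is.null(fit) || lme4::isSingular(fit, tol = 1e-4)
    if (singular) {
      if (!is.null(fit))
        warning(sprintf("condition %s: singular random effect; using OLS", cc))
      fitType <- "ols"
      fit <- stats::lm(improvement ~ gain_change + noise_filtering, data = d)
      cf <- summary(fit)$coefficients
      ci <- stats::confint(fit)
      est <- cf[, 1]
      pred <- stats::fitted(fit)
    } else {
      cf <- summary(fit)$coefficients
      ci <- stats::confint(fit, method = "Wald")
      ci <- ci[rownames(cf), , drop = FALSE]
      est <- cf[, 1]
      pred <- stats::predict(fit, re.form = NA)
    }
    predCorr <- suppressWarnings(stats::cor(pred, d$improvement))
    out[[cc]] <- data.frame(
      condition = cc, term = rownames(cf), estimate = unname(est),
      ciLow = ci[, 1], ciHigh = ci[, 2],
      significant = ci[, 1] > 0 | ci[, 2] < 0,
      predCorr = predCorr, n = nrow(d), fitType = fitType,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Ward clustering of electrodes by noise-filtering profile
#'
#' Hierarchical clustering (Ward's minimum-variance criterion, Euclidean
#' distance) of the electrodes' eight noise-filtering indices (excitatory
#' and inhibitory regions x four to-conditions), cut into two groups.
#' Columns can optionally be standardized before clustering; the default
#' follows the reference procedure (plain Euclidean distance on the raw
#' indices, which share the t-statistic scale). Group labels and
#' ordering are always derived from the raw features. Group 1
#' is the group with the higher mean excitatory index over to-noise
#' conditions (the population that recruits its excitatory field for
#' noise suppression).
#'
#' @param features Numeric matrix, electrodes x 8; column names of the
#'   form `exc_<cond>` / `inh_<cond>`. Rows with missing entries are
#'   dropped and reported.
#' @param standardize Standardize columns before clustering
#'   (default FALSE).
#' @return List with `groups` (1/2 per kept electrode, named by row),
#'   `linkage` (the hclust tree), `kept`, `dropped`, `degenerate` flag.
#' @export
clusterNoiseFiltering <- function(features, standardize = FALSE) {
  features <- as.matrix(features)
  complete <- stats::complete.cases(features)
  dropped <- which(!complete)
  X <- features[complete, , drop = FALSE]
  if (nrow(X) < 4) stop("need at least 4 complete electrodes to cluster")
  degenerate <- max(stats::dist(X)) < 1e-12
  Xc <- X
  if (standardize) {
    sdv <- apply(X, 2, stats::sd)
    sdv[!is.finite(sdv) | sdv < 1e-12] <- 1
    Xc <- sweep(sweep(X, 2, colMeans(X)), 2, sdv, `/`)
  }
  hc <- stats::hclust(stats::dist(Xc), method = "ward.D2")
  grp <- stats::cutree(hc, k = 2)
  excCols <- grepl("^exc", colnames(X)) &
    !grepl("clean", colnames(X))
  if (!any(excCols)) excCols <- grepl("^exc", colnames(X))
  m1 <- mean(X[grp == 1, excCols])
  m2 <- mean(X[grp == 2, excCols])
  if (m2 > m1) grp <- 3L - grp  # group 1 = higher excitatory to-noise index
  list(groups = grp, linkage = hc, kept = which(complete), dropped = dropped,
       degenerate = degenerate)
}

#' Compare the two electrode groups
#'
#' Wilcoxon rank-sum test on per-electrode mean adaptation indices, and a
#' timepoint-wise rank-sum comparison of baseline-normalized
#' transition-aligned responses (each electrode's mean over [2, 3) s after
#' the transition subtracted), reporting the contiguous region(s) of
#' p < 0.05 (uncorrected, as a caveat-flagged descriptive region).
#'
#' @param groups Integer vector (1/2) per electrode.
#' @param adaptationIndices Numeric vector per electrode.
#' @param alignedResponses Electrodes x timepoints matrix of
#'   transition-averaged responses.
#' @param time Relative time per column, in seconds.
#' @param alpha Pointwise significance level (default 0.05).
#' @return List with the rank-sum test on adaptation indices, the
#'   per-timepoint p-values, and the significant regions (start/end s).
#' @export
compareGroups <- function(groups, adaptationIndices, alignedResponses,
                          time, alpha = 0.05) {
  stopifnot(length(groups) == length(adaptationIndices))
  g1 <- groups == 1
  g2 <- groups == 2
  if (sum(g1) < 2 || sum(g2) < 2)
    stop("each group needs at least 2 electrodes")
  wt <- stats::wilcox.test(adaptationIndices[g2], adaptationIndices[g1],
                           exact = FALSE)
  base <- rowMeans(alignedResponses[, time >= 2 & time < 3, drop = FALSE],
                   na.rm = TRUE)
  norm <- alignedResponses - base
  pts <- vapply(seq_along(time), function(i) {
    a <- norm[g1, i]; b <- norm[g2, i]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) < 2 || length(b) < 2) return(NA_real_)
    stats::wilcox.test(b, a, exact = FALSE)$p.value
  }, 0)
  sig <- !is.na(pts) & pts < alpha
  regions <- NULL
  if (any(sig)) {
    r <- rle(sig)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    regions <- data.frame(start = time[starts[keep]],
                          end = time[ends[keep]])
  }
  list(adaptationTest = list(statistic = unname(wt$statistic),
                             p = wt$p.value,
                             medianGroup1 = stats::median(adaptationIndices[g1]),
                             medianGroup2 = stats::median(adaptationIndices[g2]),
                             n1 = sum(g1), n2 = sum(g2)),
       pointwiseP = pts, significantRegions = regions,
       multiplicityCorrected = FALSE)
}
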