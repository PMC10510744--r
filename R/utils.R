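## Internal numeric helpers shared across modules.

#' Derive a deterministic child seed from a base seed and a stage tag
#'
#' All randomness in the package flows from a single integer seed through
#' named substreams, so that pipeline stages can be re-run independently
#' while staying reproducible. The derivation is a small multiplicative
#' string hash folded into the 31-bit positive integer range.
#'
#' @param seed Integer base seed.
#' @param tag Character stage tag (e.g. `"foreground"`, `"cnn-member-3"`).
#' @return A positive integer seed, strictly below 2^31.
#' @export
deriveSeed <- function(seed, tag) {
  stopifnot(length(seed) == 1L, is.finite(seed), is.character(tag))
  h <- as.double(seed %% 2147483647)
  for (cc in utf8ToInt(tag)) {
    h <- (h * 31 + cc) %% 2147483629
  }
  as.integer(h %% 2147483562) + 1L
}

## Numerically stable softplus; the generators' smooth rectifier.
.softplus <- function(x) {
  out <- x
  idx <- x < 30
  out[idx] <- log1p(exp(x[idx]))
  out
}

## Population (divide-by-N) standard deviation over all elements.
.popSd <- function(x) {
  x <- as.numeric(x)
  sqrt(mean((x - mean(x))^2))
}

## One-pole low-pass relaxation toward a target series:
##   s[t] = s[t-1] + a * (target[t] - s[t-1]),  a = dt / tau
## Implemented with a recursive filter so long sessions stay fast.
.relaxTowards <- function(target, tau, dt, init = target[1]) {
  a <- dt / tau
  if (a >= 1) return(target)
  as.numeric(stats::filter(a * target, 1 - a, method = "recursive",
                           init = init))
}

## Bandpass a white-noise series in the frequency domain (hard brick-wall
## band, Hz). Used by the synthetic generators for modulation envelopes.
.bandpassNoise <- function(n, rate, fLow, fHigh, rng = NULL) {
  z <- stats::rnorm(n)
  fz <- stats::fft(z)
  freqs <- (seq_len(n) - 1) / n * rate
  freqs <- pmin(freqs, rate - freqs)  # two-sided
  keep <- freqs >= fLow & freqs <= fHigh
  fz[!keep] <- 0
  out <- Re(stats::fft(fz, inverse = TRUE)) / n
  s <- stats::sd(out)
  if (s > 0) out / s else out
}

## Lagged linear drive: sum_{f,l} W[f, l] * X[t - l + 1, f] for a
## time x freq spectrogram matrix and a freq x lag filter. Lag 1 is the
## current sample. Early samples use implicit zero padding.
.lagDrive <- function(X, W) {
  nT <- nrow(X)
  nLag <- ncol(W)
  drive <- numeric(nT)
  for (l in seq_len(nLag)) {
    v <- X %*% W[, l]
    if (l == 1) {
      drive <- drive + v
    } else {
      drive[l:nT] <- drive[l:nT] + v[seq_len(nT - l + 1)]
    }
  }
  as.numeric(drive)
}

## Per-band causal FIR filtering of a time x freq matrix with one kernel
## per band (kernel index 1 = current sample). Returns time x freq.
.lagFilterBands <- function(X, kernels) {
  nT <- nrow(X)
  out <- matrix(0, nT, ncol(X))
  for (f in seq_len(ncol(X))) {
    k <- kernels[, f]
    nz <- which(k != 0)
    if (!length(nz)) next
    acc <- numeric(nT)
    for (l in nz) {
      if (l == 1) acc <- acc + k[1] * X[, f]
      else acc[l:nT] <- acc[l:nT] + k[l] * X[seq_len(nT - l + 1), f]
    }
    out[, f] <- acc
  }
  out
}

## Rolling standard deviation of all spectrogram bins in a trailing window
## of `win` samples (the local spectro-temporal contrast context).
.trailingContrast <- function(X, win) {
  nT <- nrow(X)
  nF <- ncol(X)
  s1 <- cumsum(rowSums(X))
  s2 <- cumsum(rowSums(X^2))
  n <- pmin(seq_len(nT), win) * nF
  lagIdx <- seq_len(nT) - win
  s1w <- s1 - ifelse(lagIdx >= 1, s1[pmax(lagIdx, 1)], 0)
  s2w <- s2 - ifelse(lagIdx >= 1, s2[pmax(lagIdx, 1)], 0)
  m <- s1w / n
  v <- pmax(s2w / n - m^2, 0)
  sqrt(v)
}

## Simple deterministic content hash (FNV-1a over the serialized object),
## used for pipeline manifests. Not cryptographic.
.contentHash <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  h <- 2166136261
  for (b in as.integer(raw[seq(1, length(raw), by = max(1L, length(raw) %/% 4096))])) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", h)
}

.assertScalarNum <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(TRUE)
}
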