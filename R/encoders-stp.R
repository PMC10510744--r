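## LN + short-term-plasticity comparison model: FIR filter -> rectified
## drive -> Tsodyks-Markram synaptic-resource depression -> Gompertz
## ("double exponential") output nonlinearity.

## Discrete-time Tsodyks-Markram resource variable for a nonnegative drive:
##   x[t] = x[t-1] + dt * ((1 - x[t-1]) / tauRec - u * x[t-1] * d[t-1]),
## clipped to [0, 1], x[0] = 1. Steady state under constant drive d is
## (1/tauRec) / (1/tauRec + u d).
.stpResource <- function(drive, u, tauRec, dt) {
  nT <- length(drive)
  x <- numeric(nT)
  xr <- 1
  a <- dt / tauRec
  for (t in seq_len(nT)) {
    x[t] <- xr
    xr <- xr + a * (1 - xr) - dt * u * xr * drive[t]
    if (xr < 0) xr <- 0 else if (xr > 1) xr <- 1
  }
  x
}

.gompertz <- function(v, base, amplitude, shift, slope) {
  base + amplitude * exp(-exp(-slope * (v - shift)))
}

#' Run an LN+STP model forward on a stimulus
#'
#' @param model A [StpModel-class].
#' @param stim [Spectrogram-class] or time x freq matrix.
#' @return Numeric response trace (one electrode).
#' @export
stpForward <- function(model, stim) {
  X <- if (methods::is(stim, "Spectrogram")) stim@values else as.matrix(stim)
  rate <- if (methods::is(stim, "Spectrogram")) stim@rate else 100
  if (model@tauRec <= 0) stop("tauRec must be > 0")
  drive <- .softplus(.lagDrive(X, model@fir))
  xres <- .stpResource(drive, model@u, model@tauRec, 1 / rate)
  v <- model@u * xres * drive
  p <- model@nlParams
  .gompertz(v, p["base"], p["amplitude"], p["shift"], p["slope"])
}

#' Fit LN+STP models per electrode
#'
#' The FIR filter is initialized from a ridge STRF fit and held fixed; the
#' Tsodyks-Markram parameters (u, tauRec) and the four Gompertz
#' nonlinearity parameters are then optimized on mean-squared error by
#' multi-start quasi-Newton descent (best of `nRestarts` starts).
#'
#' @param stim [Spectrogram-class] or time x freq matrix.
#' @param resp [ResponseMatrix-class] or electrodes x time matrix.
#' @param blocks List of sample-index vectors used for fitting.
#' @param nLag FIR lag span (default 65).
#' @param nRestarts Number of optimizer restarts (>= 5 recommended).
#' @param seed Integer seed for the restart draws.
#' @param strfInit Optional precomputed [StrfModel-class] to initialize the
#'   FIR filters from.
#' @return List of [StpModel-class] objects, one per electrode.
#' @export
fitStp <- function(stim, resp, blocks, nLag = 65, nRestarts = 5, seed = 0,
                   strfInit = NULL) {
  X <- if (methods::is(stim, "Spectrogram")) stim@values else as.matrix(stim)
  rate <- if (methods::is(stim, "Spectrogram")) stim@rate else 100
  Y <- if (methods::is(resp, "ResponseMatrix")) resp@values else
    as.matrix(resp)
  if (is.null(strfInit)) strfInit <- fitStrf(stim, resp, blocks, nLag = nLag)
  rows <- sort(unlist(lapply(blocks, function(idx)
    idx[idx >= idx[1] + nLag - 1L])))
  dt <- 1 / rate

  out <- vector("list", nrow(Y))
  for (e in seq_len(nrow(Y))) {
    fir <- strfInit@weights[, , e]
    drive <- .softplus(.lagDrive(X, fir))[rows]
    y <- Y[e, rows]
    ySd <- stats::sd(y)

    ## parameters: logit(u), log(tauRec), base, amplitude, shift, slope
    objective <- function(par) {
      u <- stats::plogis(par[1])
      tauRec <- exp(par[2])
      xres <- .stpResource(drive, u, tauRec, dt)
      v <- u * xres * drive
      pred <- .gompertz(v, par[3], par[4], par[5], par[6])
      mean((pred - y)^2)
    }

    set.seed(deriveSeed(seed, paste0("stp-", e)))
    bestFit <- NULL
    nFailed <- 0
    ## deterministic init grid over the depression parameters, plus
    ## randomized restarts of the nonlinearity
    grid <- expand.grid(u = c(0.2, 0.5), tauRec = c(0.1, 0.3))
    nStarts <- max(nRestarts, nrow(grid) + 1L)
    for (r in seq_len(nStarts)) {
      if (r <= nrow(grid)) {
        start <- c(stats::qlogis(grid$u[r]), log(grid$tauRec[r]),
                   unname(stats::quantile(y, 0.05)),
                   diff(range(y)),
                   stats::median(drive), 2)
      } else {
        start <- c(stats::qlogis(stats::runif(1, 0.1, 0.7)),
                   log(stats::runif(1, 0.05, 0.8)),
                   unname(stats::quantile(y, 0.05)) +
                     stats::rnorm(1, 0, 0.1 * ySd),
                   diff(range(y)) * stats::runif(1, 0.6, 1.4),
                   stats::median(drive) * stats::runif(1, 0.3, 1.5),
                   stats::runif(1, 0.5, 4))
      }
      fit <- tryCatch(
        stats::optim(start, objective, method = "BFGS",
                     control = list(maxit = 200, reltol = 1e-9)),
        error = function(err) NULL)
      if (is.null(fit) || !is.finite(fit$value)) {
        nFailed <- nFailed + 1
        next
      }
      if (is.null(bestFit) || fit$value < bestFit$value) bestFit <- fit
    }
    if (is.null(bestFit))
      stop(sprintf("STP fitting failed for electrode %d: all %d restarts diverged",
                   e, nStarts))
    par <- bestFit$par
    out[[e]] <- methods::new("StpModel", fir = fir,
      nlParams = c(base = par[3], amplitude = par[4], shift = par[5],
                   slope = par[6]),
      u = stats::plogis(par[1]), tauRec = exp(par[2]),
      finalLoss = bestFit$value)
  }
  out
}
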