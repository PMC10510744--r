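## Core S4 containers. All time axes are uniformly sampled (default 100 Hz)
## and all spectro-temporal filters are freq x lag with lag 1 = the current
## sample, running back in time (display convention of STRFs).

#' Spectrogram container
#'
#' A nonnegative time-by-frequency magnitude spectrogram sampled uniformly
#' in time. The default geometry is 23 mel-like bands at 100 Hz, the input
#' representation consumed by every encoding model in the package.
#'
#' @slot values Numeric matrix, time x frequency, finite and nonnegative.
#' @slot rate Sampling rate in Hz.
#' @slot t0 Time of the first sample in seconds.
#' @export
setClass("Spectrogram",
  representation(values = "matrix", rate = "numeric", t0 = "numeric"),
  prototype(rate = 100, t0 = 0)
)

setValidity("Spectrogram", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("'values' must be numeric")
  if (any(!is.finite(v))) return("'values' must be finite")
  if (any(v < 0)) return("'values' must be nonnegative")
  if (length(object@rate) != 1L || object@rate <= 0)
    return("'rate' must be a positive scalar")
  TRUE
})

#' Construct a Spectrogram
#'
#' @param values Time x frequency nonnegative matrix.
#' @param rate Sampling rate in Hz (default 100).
#' @param t0 Time of the first sample in seconds.
#' @return A [Spectrogram-class] object.
#' @export
Spectrogram <- function(values, rate = 100, t0 = 0) {
  methods::new("Spectrogram", values = as.matrix(values), rate = rate, t0 = t0)
}

#' Background-condition schedule
#'
#' An ordered, gap-free tiling of the stimulus timeline into segments, each
#' labelled with one of the four background conditions (`clean` plus three
#' noise classes). Consecutive segments always differ in condition, so every
#' segment boundary is a background transition.
#'
#' @slot segments data.frame with columns `start`, `end` (seconds) and
#'   `condition` (character).
#' @slot blockBounds Numeric vector of block boundary times in seconds
#'   (length nBlocks + 1); blocks are the cross-validation units.
#' @slot leadIn Duration in seconds of the silent lead-in that precedes the
#'   first segment (used for baseline normalization).
#' @export
setClass("NoiseSchedule",
  representation(segments = "data.frame", blockBounds = "numeric",
                 leadIn = "numeric"),
  prototype(leadIn = 0)
)

setValidity("NoiseSchedule", function(object) {
  s <- object@segments
  need <- c("start", "end", "condition")
  if (!all(need %in% names(s))) return("segments needs start/end/condition")
  if (nrow(s) > 1) {
    if (any(abs(s$start[-1] - s$end[-nrow(s)]) > 1e-9))
      return("segments must tile the timeline without gaps or overlaps")
    if (any(s$condition[-1] == s$condition[-nrow(s)]))
      return("consecutive segments must differ in condition")
  }
  if (any(s$end <= s$start)) return("segment end must exceed start")
  TRUE
})

#' Noise class specification
#'
#' Parameterizes one background-noise class by its mean spectrum (normalized
#' to unit total power across the 23 bands) and its temporal stationarity
#' (1 = a perfectly steady envelope, 0 = strongly modulated).
#'
#' @slot label Class label, e.g. `"bar"`, `"city"`, `"jet"`.
#' @slot meanSpectrum Nonnegative vector over frequency bands, summing to 1.
#' @slot stationarity Scalar in [0, 1].
#' @export
setClass("NoiseClassSpec",
  representation(label = "character", meanSpectrum = "numeric",
                 stationarity = "numeric")
)

setValidity("NoiseClassSpec", function(object) {
  if (any(object@meanSpectrum < 0)) return("meanSpectrum must be nonnegative")
  if (abs(sum(object@meanSpectrum) - 1) > 1e-8)
    return("meanSpectrum must sum to 1")
  if (object@stationarity < 0 || object@stationarity > 1)
    return("stationarity must lie in [0, 1]")
  TRUE
})

#' Ground-truth encoder for synthetic responses
#'
#' A generative model of one synthetic electrode with known adaptive
#' structure. Four kinds are supported: `static_linear` (rectified linear
#' filter), `gain_adaptive` (output gain g = k * (c + c0)^(-alpha) tracking
#' local spectro-temporal contrast c with relaxation time `tauAdapt`),
#' `noise_filtering` (an inhibitory filter component matched to the current
#' noise spectrum grows in after each transition), and `ln_stp` (linear
#' drive through Tsodyks-Markram synaptic depression and a double-exponential
#' output nonlinearity).
#'
#' @slot kind One of `"static_linear"`, `"gain_adaptive"`,
#'   `"noise_filtering"`, `"ln_stp"`.
#' @slot baseFilter Frequency x lag filter matrix (default 23 x 65).
#' @slot gainK,gainAlpha Parameters of the contrast-gain law.
#' @slot suppressionDepth Magnitude of the noise-matched inhibitory
#'   component (noise_filtering kind).
#' @slot suppressionMode `"both"` (suppression acts on the whole filter) or
#'   `"inhibitory_only"` (restricted to bins where the base filter is <= 0).
#' @slot tauAdapt Relaxation time constant of the adaptive state, seconds.
#' @slot stpU,stpTauRec Tsodyks-Markram release fraction and recovery time.
#' @slot outputNoiseSd Additive Gaussian observation noise at the response
#'   stage, in pre-normalization response units.
#' @slot transientAmp Amplitude of an additive exponentially-decaying
#'   response transient (time constant 0.3 s) triggered at every background
#'   transition; controls the electrode's adaptation index.
#' @slot driveBias Constant added to the linear drive before rectification
#'   (a spontaneous-activity-like operating point; keeps the rectifier
#'   mostly in its linear range).
#' @slot rectifier `"softplus"` (smooth, default) or `"relu"`.
#' @slot label Optional electrode label.
#' @export
setClass("GroundTruthEncoder",
  representation(kind = "character", baseFilter = "matrix",
                 gainK = "numeric", gainAlpha = "numeric",
                 suppressionDepth = "numeric", suppressionMode = "character",
                 tauAdapt = "numeric", stpU = "numeric", stpTauRec = "numeric",
                 outputNoiseSd = "numeric", transientAmp = "numeric",
                 driveBias = "numeric", rectifier = "character",
                 label = "character"),
  prototype(gainK = 0.85, gainAlpha = 1, suppressionDepth = 0,
            suppressionMode = "both", tauAdapt = 0.25, stpU = 0.4,
            stpTauRec = 0.2, outputNoiseSd = 0, transientAmp = 0,
            driveBias = 3, rectifier = "softplus", label = "electrode")
)

setValidity("GroundTruthEncoder", function(object) {
  kinds <- c("static_linear", "gain_adaptive", "noise_filtering", "ln_stp")
  if (!object@kind %in% kinds)
    return(sprintf("unknown encoder kind '%s'", object@kind))
  if (object@tauAdapt <= 0) return("tauAdapt must be > 0")
  if (object@stpU <= 0 || object@stpU > 1) return("stpU must be in (0, 1]")
  if (object@stpTauRec <= 0) return("stpTauRec must be > 0")
  if (object@outputNoiseSd < 0) return("outputNoiseSd must be >= 0")
  if (object@suppressionDepth < 0) return("suppressionDepth must be >= 0")
  if (!object@suppressionMode %in% c("both", "inhibitory_only"))
    return("suppressionMode must be 'both' or 'inhibitory_only'")
  if (!object@rectifier %in% c("softplus", "relu"))
    return("rectifier must be 'softplus' or 'relu'")
  TRUE
})

#' Electrode response matrix
#'
#' Electrodes x time response matrix (synthetic high-gamma-like envelopes)
#' with per-electrode subject labels. Responses are z-scored to the silent
#' baseline window unless the baseline is noiseless (zero variance), in
#' which case they are left in raw units.
#'
#' @slot values Numeric matrix, electrodes x time.
#' @slot subjectIds Character vector, one label per electrode.
#' @slot rate Sampling rate in Hz.
#' @slot baselineWindow Two-element numeric, the silent interval (seconds,
#'   half-open) used for normalization.
#' @slot normalized Logical per electrode; FALSE where the baseline had zero
#'   variance and z-scoring was skipped.
#' @export
setClass("ResponseMatrix",
  representation(values = "matrix", subjectIds = "character",
                 rate = "numeric", baselineWindow = "numeric",
                 normalized = "logical"),
  prototype(rate = 100)
)

setValidity("ResponseMatrix", function(object) {
  if (nrow(object@values) != length(object@subjectIds))
    return("one subject label per electrode is required")
  if (length(object@baselineWindow) != 2L)
    return("baselineWindow must have length 2")
  TRUE
})

#' Synthetic session container
#'
#' Bundles everything one simulated recording session holds: the mixed
#' stimulus spectrogram (including the silent lead-in), the foreground-only
#' spectrogram (used for the clean-speech target spectrum), the condition
#' schedule, the noise class specs, the ground-truth encoders, the response
#' matrix, and the generating seed/configuration.
#'
#' @slot stimulus,foreground [Spectrogram-class] objects on the session
#'   timeline (t0 = 0; stimulus content starts after the lead-in).
#' @slot schedule A [NoiseSchedule-class].
#' @slot noiseClasses Named list of [NoiseClassSpec-class] objects.
#' @slot encoders List of [GroundTruthEncoder-class] objects (one per
#'   electrode; empty until responses are simulated).
#' @slot responses A [ResponseMatrix-class] (zero rows until simulated).
#' @slot seed Integer seed the session was generated from.
#' @slot config Named list of generation parameters.
#' @export
setClass("SessionData",
  representation(stimulus = "Spectrogram", foreground = "Spectrogram",
                 schedule = "NoiseSchedule", noiseClasses = "list",
                 encoders = "list", responses = "ResponseMatrix",
                 seed = "integer", config = "list")
)

#' Linear STRF model
#'
#' Ridge-regularized spectro-temporal receptive fields for a set of
#' electrodes, fit on a lagged (time x freq*lag) design matrix with
#' block-wise cross-validated regularization.
#'
#' @slot weights Array freq x lag x electrode.
#' @slot bias Numeric vector per electrode.
#' @slot lambda Chosen ridge penalty (scalar).
#' @slot lambdaGrid Candidate penalties searched.
#' @slot cvCorr Mean cross-validated correlation per candidate lambda.
#' @export
setClass("StrfModel",
  representation(weights = "array", bias = "numeric", lambda = "numeric",
                 lambdaGrid = "numeric", cvCorr = "numeric")
)

#' Convolutional encoder architecture
#'
#' The dilated 1-D convolutional architecture used as the nonlinear encoding
#' model: stacked ReLU convolution layers without hidden biases (required
#' for the exact gradient/dSTRF identity) and a final linear projection with
#' one output head per electrode, the only layer carrying a bias.
#'
#' @slot nLayers Number of convolution layers.
#' @slot nKernels Channels per hidden layer.
#' @slot kernelSize Taps per convolution kernel.
#' @slot dilations Integer dilation per layer.
#' @slot nFreq Input frequency bands.
#' @export
setClass("CnnConfig",
  representation(nLayers = "integer", nKernels = "integer",
                 kernelSize = "integer", dilations = "integer",
                 nFreq = "integer"),
  prototype(nLayers = 5L, nKernels = 128L, kernelSize = 5L,
            dilations = c(1L, 1L, 2L, 4L, 8L), nFreq = 23L)
)

setValidity("CnnConfig", function(object) {
  if (length(object@dilations) != object@nLayers)
    return("need one dilation per layer")
  if (any(object@dilations < 1L)) return("dilations must be >= 1")
  if (object@kernelSize < 1L) return("kernelSize must be >= 1")
  TRUE
})

#' Trained convolutional encoder
#'
#' @slot config A [CnnConfig-class].
#' @slot convW List of weight arrays, one per layer, dim (out, in, tap).
#' @slot outW Final projection matrix, electrodes x channels.
#' @slot outB Final bias per electrode.
#' @slot inputCenter,inputScale Per-band input normalization (training set).
#' @slot trainLog data.frame of per-epoch training/validation loss.
#' @slot seed Training seed.
#' @export
setClass("CnnModel",
  representation(config = "CnnConfig", convW = "list", outW = "matrix",
                 outB = "numeric", inputCenter = "numeric",
                 inputScale = "numeric", trainLog = "data.frame",
                 seed = "integer")
)

#' LN model with Tsodyks-Markram short-term plasticity
#'
#' A finite-impulse-response filter (freq x lag) whose rectified drive is
#' depressed by a two-parameter Tsodyks-Markram resource variable and then
#' passed through a double-exponential (Gompertz) output nonlinearity
#' y = base + amplitude * exp(-exp(-slope * (v - shift))).
#'
#' @slot fir Frequency x lag filter.
#' @slot nlParams Named numeric: base, amplitude, shift, slope.
#' @slot u Release fraction in (0, 1]; u = 0 disables depression.
#' @slot tauRec Resource recovery time constant in seconds.
#' @slot finalLoss Training MSE of the returned fit.
#' @export
setClass("StpModel",
  representation(fir = "matrix", nlParams = "numeric", u = "numeric",
                 tauRec = "numeric", finalLoss = "numeric"),
  prototype(finalLoss = NA_real_)
)

setValidity("StpModel", function(object) {
  if (object@tauRec <= 0) return("tauRec must be > 0")
  if (object@u < 0 || object@u > 1) return("u must be in [0, 1]")
  need <- c("base", "amplitude", "shift", "slope")
  if (!all(need %in% names(object@nlParams)))
    return("nlParams needs base/amplitude/shift/slope")
  TRUE
})

#' Jackknife ensemble for one held-out test block
#'
#' Holds the member models trained for one test block: with B blocks, each
#' ensemble has B - 1 members, member m being trained with the test block
#' and one additional block held out. Test predictions are the arithmetic
#' mean of the member predictions.
#'
#' @slot testBlock Integer id of the held-out block.
#' @slot members List of fitted models (StrfModel/CnnModel/StpModel).
#' @slot heldOutBlocks Integer vector, the extra block each member excluded.
#' @slot fitter `"strf"`, `"cnn"` or `"stp"`.
#' @export
setClass("JackknifeEnsemble",
  representation(testBlock = "integer", members = "list",
                 heldOutBlocks = "integer", fitter = "character")
)

setValidity("JackknifeEnsemble", function(object) {
  if (length(object@members) != length(object@heldOutBlocks))
    return("one held-out block id per member")
  TRUE
})

#' Full jackknife fit of one model family over all blocks
#'
#' One [JackknifeEnsemble-class] per block, plus the assembled held-out
#' predictions: every block's samples are predicted exactly once, by the
#' member average of the ensemble that held that block out.
#'
#' @slot ensembles List of [JackknifeEnsemble-class], one per block.
#' @slot predictions Electrodes x time matrix of held-out predictions
#'   (NA outside the scored region, e.g. the silent lead-in).
#' @slot fitter `"strf"`, `"cnn"` or `"stp"`.
#' @slot blocks The block sample-index list used.
#' @export
setClass("JackknifeSet",
  representation(ensembles = "list", predictions = "matrix",
                 fitter = "character", blocks = "list")
)

#' Masked jackknife-averaged dSTRF time course for one electrode
#'
#' Frames are the instantaneous equivalent linear filters of the trained
#' network, averaged over jackknife members with the sign-consistency mask
#' applied: a bin is kept (set to the member mean) only when at least
#' `maskThreshold` members agree on a strict sign, otherwise it is exactly 0.
#'
#' @slot frames Array, frame x freq x lag.
#' @slot times Integer sample indices (session timeline) of the frames.
#' @slot electrode Electrode index the frames belong to.
#' @slot maskThreshold Minimum number of sign-agreeing members.
#' @slot nMembers Number of jackknife members averaged.
#' @export
setClass("DstrfTensor",
  representation(frames = "array", times = "integer", electrode = "integer",
                 maskThreshold = "integer", nMembers = "integer")
)

setValidity("DstrfTensor", function(object) {
  if (length(dim(object@frames)) != 3L)
    return("frames must be a 3-d array (frame x freq x lag)")
  if (dim(object@frames)[1] != length(object@times))
    return("one time per frame")
  if (object@maskThreshold > object@nMembers)
    return("maskThreshold cannot exceed nMembers")
  TRUE
})
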