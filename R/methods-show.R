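## show() methods: compact one-glance summaries, Bioconductor style.

setMethod("show", "Spectrogram", function(object) {
  cat(sprintf("Spectrogram: %d samples x %d bands @ %g Hz (%.1f s)\n",
              nrow(object@values), ncol(object@values), object@rate,
              nrow(object@values) / object@rate))
})

setMethod("show", "NoiseSchedule", function(object) {
  s <- object@segments
  cat(sprintf("NoiseSchedule: %d segments over [%.1f, %.1f] s, %d blocks",
              nrow(s), min(s$start), max(s$end),
              max(0L, length(object@blockBounds) - 1L)))
  if (object@leadIn > 0) cat(sprintf(", %.0f s silent lead-in", object@leadIn))
  cat("\n")
  tab <- tapply(s$end - s$start, s$condition, sum)
  cat("  exposure (s):",
      paste(sprintf("%s=%.0f", names(tab), tab), collapse = ", "), "\n")
})

setMethod("show", "NoiseClassSpec", function(object) {
  pk <- which.max(object@meanSpectrum)
  cat(sprintf("NoiseClassSpec '%s': peak band %d/%d, stationarity %.2f\n",
              object@label, pk, length(object@meanSpectrum),
              object@stationarity))
})

setMethod("show", "GroundTruthEncoder", function(object) {
  cat(sprintf("GroundTruthEncoder '%s' (%s): filter %d x %d, noise sd %.2g\n",
              object@label, object@kind, nrow(object@baseFilter),
              ncol(object@baseFilter), object@outputNoiseSd))
})

setMethod("show", "ResponseMatrix", function(object) {
  cat(sprintf("ResponseMatrix: %d electrodes x %d samples @ %g Hz, %d subjects\n",
              nrow(object@values), ncol(object@values), object@rate,
              length(unique(object@subjectIds))))
})

setMethod("show", "SessionData", function(object) {
  cat("SessionData\n")
  cat("  stimulus: "); methods::show(object@stimulus)
  cat("  schedule: "); methods::show(object@schedule)
  if (nrow(object@responses@values) > 0) {
    cat("  responses: "); methods::show(object@responses)
    kinds <- table(vapply(object@encoders, function(e) e@kind, ""))
    cat("  encoders:",
        paste(sprintf("%s=%d", names(kinds), kinds), collapse = ", "), "\n")
  } else cat("  responses: none simulated yet\n")
})

setMethod("show", "StrfModel", function(object) {
  d <- dim(object@weights)
  cat(sprintf("StrfModel: %d electrodes, %d x %d filters, lambda = %.3g\n",
              d[3], d[1], d[2], object@lambda))
})

setMethod("show", "CnnConfig", function(object) {
  cat(sprintf("CnnConfig: %d layers x %d kernels (size %d), dilations %s, RF %d samples\n",
              object@nLayers, object@nKernels, object@kernelSize,
              paste(object@dilations, collapse = ","),
              receptiveField(object)))
})

setMethod("show", "CnnModel", function(object) {
  cat(sprintf("CnnModel: %d electrodes, ", nrow(object@outW)))
  methods::show(object@config)
})

setMethod("show", "StpModel", function(object) {
  cat(sprintf("StpModel: u = %.3f, tauRec = %.3f s, fir %d x %d\n",
              object@u, object@tauRec, nrow(object@fir), ncol(object@fir)))
})

setMethod("show", "JackknifeEnsemble", function(object) {
  cat(sprintf("JackknifeEnsemble (%s): test block %d, %d members\n",
              object@fitter, object@testBlock, length(object@members)))
})

setMethod("show", "DstrfTensor", function(object) {
  d <- dim(object@frames)
  zero <- mean(object@frames == 0, na.rm = TRUE)
  cat(sprintf("DstrfTensor: electrode %d, %d frames x %d x %d, mask %d/%d (%.0f%% zeroed)\n",
              object@electrode, d[1], d[2], d[3], object@maskThreshold,
              object@nMembers, 100 * zero))
})
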