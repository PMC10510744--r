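## Generics and accessors. Slot access from user code goes through these.

#' @name accessors
#' @title Accessors for dstrfadapt containers
#' @description Small accessor generics for the package's S4 containers.
#' @param x An object.
#' @param ... Further arguments (unused).
NULL

#' @rdname accessors
#' @export
setGeneric("specValues", function(x) standardGeneric("specValues"))
#' @rdname accessors
#' @export
setMethod("specValues", "Spectrogram", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))
#' @rdname accessors
#' @export
setMethod("sampleRate", "Spectrogram", function(x) x@rate)
#' @rdname accessors
#' @export
setMethod("sampleRate", "ResponseMatrix", function(x) x@rate)

#' @rdname accessors
#' @export
setGeneric("nFreq", function(x) standardGeneric("nFreq"))
#' @rdname accessors
#' @export
setMethod("nFreq", "Spectrogram", function(x) ncol(x@values))

#' Duration of a spectrogram in seconds
#' @param x A Spectrogram.
#' @export
setGeneric("duration", function(x) standardGeneric("duration"))
#' @rdname duration
#' @export
setMethod("duration", "Spectrogram", function(x) nrow(x@values) / x@rate)

#' @rdname accessors
#' @export
setGeneric("segments", function(x) standardGeneric("segments"))
#' @rdname accessors
#' @export
setMethod("segments", "NoiseSchedule", function(x) x@segments)

#' @rdname accessors
#' @export
setGeneric("blockBounds", function(x) standardGeneric("blockBounds"))
#' @rdname accessors
#' @export
setMethod("blockBounds", "NoiseSchedule", function(x) x@blockBounds)

#' Background transitions of a schedule
#'
#' @param x A [NoiseSchedule-class].
#' @return data.frame with columns `time` (s), `from`, `to`.
#' @export
setGeneric("transitions", function(x) standardGeneric("transitions"))
#' @rdname transitions
#' @export
setMethod("transitions", "NoiseSchedule", function(x) {
  s <- x@segments
  if (nrow(s) < 2) {
    return(data.frame(time = numeric(0), from = character(0),
                      to = character(0), stringsAsFactors = FALSE))
  }
  data.frame(time = s$start[-1], from = s$condition[-nrow(s)],
             to = s$condition[-1], stringsAsFactors = FALSE)
})

#' @rdname accessors
#' @export
setGeneric("respValues", function(x) standardGeneric("respValues"))
#' @rdname accessors
#' @export
setMethod("respValues", "ResponseMatrix", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("respValues", "SessionData", function(x) x@responses@values)

#' @rdname accessors
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))
#' @rdname accessors
#' @export
setMethod("subjectIds", "ResponseMatrix", function(x) x@subjectIds)
#' @rdname accessors
#' @export
setMethod("subjectIds", "SessionData", function(x) x@responses@subjectIds)

#' @rdname accessors
#' @export
setGeneric("nElectrodes", function(x) standardGeneric("nElectrodes"))
#' @rdname accessors
#' @export
setMethod("nElectrodes", "ResponseMatrix", function(x) nrow(x@values))
#' @rdname accessors
#' @export
setMethod("nElectrodes", "SessionData", function(x) nrow(x@responses@values))

#' @rdname accessors
#' @export
setGeneric("schedule", function(x) standardGeneric("schedule"))
#' @rdname accessors
#' @export
setMethod("schedule", "SessionData", function(x) x@schedule)

#' @rdname accessors
#' @export
setGeneric("stimulus", function(x) standardGeneric("stimulus"))
#' @rdname accessors
#' @export
setMethod("stimulus", "SessionData", function(x) x@stimulus)

#' @rdname accessors
#' @export
setGeneric("foreground", function(x) standardGeneric("foreground"))
#' @rdname accessors
#' @export
setMethod("foreground", "SessionData", function(x) x@foreground)

#' @rdname accessors
#' @export
setGeneric("noiseClasses", function(x) standardGeneric("noiseClasses"))
#' @rdname accessors
#' @export
setMethod("noiseClasses", "SessionData", function(x) x@noiseClasses)

#' @rdname accessors
#' @export
setGeneric("encoders", function(x) standardGeneric("encoders"))
#' @rdname accessors
#' @export
setMethod("encoders", "SessionData", function(x) x@encoders)

#' @rdname accessors
#' @export
setGeneric("strfWeights", function(x) standardGeneric("strfWeights"))
#' @rdname accessors
#' @export
setMethod("strfWeights", "StrfModel", function(x) x@weights)

#' @rdname accessors
#' @export
setGeneric("dstrfFrames", function(x) standardGeneric("dstrfFrames"))
#' @rdname accessors
#' @export
setMethod("dstrfFrames", "DstrfTensor", function(x) x@frames)

#' @rdname accessors
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))
#' @rdname accessors
#' @export
setMethod("frameTimes", "DstrfTensor", function(x) x@times)

#' Condition label at given times
#'
#' Looks up the background condition owning each time point; the transition
#' sample itself belongs to the post-transition condition (half-open
#' segments). Times in the silent lead-in (or outside the schedule) return
#' `NA`.
#'
#' @param x A [NoiseSchedule-class].
#' @param t Numeric vector of times in seconds.
#' @return Character vector of condition labels.
#' @export
setGeneric("conditionAt", function(x, t) standardGeneric("conditionAt"))
#' @rdname conditionAt
#' @export
setMethod("conditionAt", "NoiseSchedule", function(x, t) {
  s <- x@segments
  idx <- findInterval(t + 1e-9, s$start)
  out <- rep(NA_character_, length(t))
  ok <- idx >= 1 & idx <= nrow(s) & (t + 1e-9) < s$end[pmax(idx, 1L)]
  out[ok] <- s$condition[idx[ok]]
  out
})
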