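#' Accessors for sweep buffers, templates and averaged responses
#'
#' Slot access goes through these generics throughout the package.
#' \code{sweepData} returns the sweeps-by-samples matrix, \code{nSweeps} the
#' row count, \code{sweepTimes} the epoch timebase in ms,
#' \code{samplingRate} the rate in Hz, \code{amplitude} the waveform of an
#' averaged response or template, \code{composition} the per-(channel,
#' polarity) sweep counts of an average, and \code{peakRegistry} the labeled
#' peaks of a template.
#'
#' @param x A \linkS4class{SweepBuffer}, \linkS4class{AveragedResponse} or
#'   \linkS4class{ResponseTemplate}.
#' @return See the individual generic descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sweepData", function(x) standardGeneric("sweepData"))
#' @rdname accessors
#' @export
setGeneric("nSweeps", function(x) standardGeneric("nSweeps"))
#' @rdname accessors
#' @export
setGeneric("sweepTimes", function(x) standardGeneric("sweepTimes"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("amplitude", function(x) standardGeneric("amplitude"))
#' @rdname accessors
#' @export
setGeneric("composition", function(x) standardGeneric("composition"))
#' @rdname accessors
#' @export
setGeneric("peakRegistry", function(x) standardGeneric("peakRegistry"))

.timesFrom <- function(t0, n, rate) t0 + (seq_len(n) - 1L) / rate * 1000

#' @rdname accessors
setMethod("sweepData", "SweepBuffer", function(x) x@data)
#' @rdname accessors
setMethod("nSweeps", "SweepBuffer", function(x) nrow(x@data))
#' @rdname accessors
setMethod("sweepTimes", "SweepBuffer", function(x)
  .timesFrom(x@t0Offset, ncol(x@data), x@samplingRate))
#' @rdname accessors
setMethod("samplingRate", "SweepBuffer", function(x) x@samplingRate)

#' @rdname accessors
setMethod("amplitude", "AveragedResponse", function(x) x@amplitude)
#' @rdname accessors
setMethod("sweepTimes", "AveragedResponse", function(x)
  .timesFrom(x@t0Offset, length(x@amplitude), x@samplingRate))
#' @rdname accessors
setMethod("samplingRate", "AveragedResponse", function(x) x@samplingRate)
#' @rdname accessors
setMethod("composition", "AveragedResponse", function(x) x@composition)

#' @rdname accessors
setMethod("amplitude", "ResponseTemplate", function(x) x@amplitude)
#' @rdname accessors
setMethod("sweepTimes", "ResponseTemplate", function(x) x@timebase)
#' @rdname accessors
setMethod("samplingRate", "ResponseTemplate", function(x) x@samplingRate)
#' @rdname accessors
setMethod("peakRegistry", "ResponseTemplate", function(x) x@peakRegistry)

setMethod("show", "ResponseTemplate", function(object) {
  cat(sprintf("ResponseTemplate <%s>: %d samples @ %g Hz, %.1f..%.1f ms\n",
              object@stimulusKind, length(object@timebase),
              object@samplingRate, min(object@timebase), max(object@timebase)))
  if (length(object@f0)) cat(sprintf("  f0: %g Hz\n", object@f0))
  cat(sprintf("  peaks: %s\n",
              paste(object@peakRegistry$label, collapse = ", ")))
})

setMethod("show", "SweepBuffer", function(object) {
  cat(sprintf(
    "SweepBuffer: %d sweeps x %d samples (%s, channel %s, %s)\n",
    nrow(object@data), ncol(object@data), object@stimulusKind,
    object@channel, object@polarity))
  cat(sprintf("  participant %s, collection %d, %g Hz, t0 %.1f ms%s\n",
              object@participantId, object@collectionIndex,
              object@samplingRate, object@t0Offset,
              if (nzchar(object@filterApplied))
                paste0(", filter: ", object@filterApplied) else ""))
})

setMethod("show", "AveragedResponse", function(object) {
  cat(sprintf("AveragedResponse (%s, participant %s): %d samples @ %g Hz\n",
              object@stimulusKind, object@participantId,
              length(object@amplitude), object@samplingRate))
  comp <- object@composition
  if (nrow(comp))
    cat(sprintf("  composition: %s (total %d sweeps)\n",
                paste(sprintf("%s/%s=%d", comp$channel,
                              substr(comp$polarity, 1, 4), comp$n),
                      collapse = ", "),
                sum(comp$n)))
})

setMethod("show", "NoiseModel", function(object) {
  cat(sprintf(
    paste0("NoiseModel: noiseSd=%g uV, jitterSd=%g ms, ampCv=%g, ",
           "artifactRate=%g, polarityComponent=%g uV @ %g Hz\n"),
    object@noiseSd, object@jitterSd, object@ampCv, object@artifactRate,
    object@polarityComponentAmp, object@polarityComponentHz))
})

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf(
    "CohortSpec: n=%d, intercept=%g, betaTrait=%g, seed=%d\n",
    object@nParticipants, object@intercept, object@betaTrait, object@seed))
  cat("  component offsets: ",
      paste(sprintf("%s=%+.2f", names(object@componentOffsets),
                    object@componentOffsets), collapse = ", "), "\n")
})
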