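#' @import methods
NULL

.CHANNELS   <- c("A", "B")
.POLARITIES <- c("condensation", "rarefaction")
.STIMULI    <- c("click", "da40")
.COMPONENTS <- c("click", "full_sabr", "onset", "ffr", "offset")

#' Deterministic evoked-response template
#'
#' Holds the noise-free waveform a simulated brainstem response is built from:
#' a uniform millisecond timebase, the amplitude in microvolts at each sample,
#' and a registry of the hallmark peaks (click waves I/III/V; /da/ waves V, A,
#' C, D, E, F, O).  For the 40 ms /da/ template the fundamental frequency of
#' the sustained (frequency-following) portion is carried in \code{f0}.
#'
#' @slot stimulusKind \code{"click"} or \code{"da40"}.
#' @slot timebase Numeric vector of sample times in ms relative to stimulus
#'   onset (negative values are prestimulus); strictly increasing with a
#'   uniform step.
#' @slot amplitude Numeric vector of template amplitudes in microvolts, same
#'   length as \code{timebase}.
#' @slot samplingRate Sampling rate in Hz.
#' @slot peakRegistry \code{data.frame} with columns \code{label},
#'   \code{latency_ms}, \code{amplitude_uv}, \code{width_ms}.
#' @slot f0 Fundamental frequency in Hz (length-1 for \code{da40}, length-0
#'   for \code{click}).
#'
#' @seealso [makeTemplate()]
#' @export
setClass("ResponseTemplate",
  representation(
    stimulusKind = "character",
    timebase     = "numeric",
    amplitude    = "numeric",
    samplingRate = "numeric",
    peakRegistry = "data.frame",
    f0           = "numeric"
  )
)

setValidity("ResponseTemplate", function(object) {
  msg <- character()
  if (!object@stimulusKind %in% .STIMULI)
    msg <- c(msg, sprintf("unknown stimulusKind '%s'", object@stimulusKind))
  tb <- object@timebase
  if (length(tb) < 2L || any(diff(tb) <= 0))
    msg <- c(msg, "timebase must be strictly increasing")
  step <- diff(tb)
  if (length(step) && diff(range(step)) > 1e-9)
    msg <- c(msg, "timebase step must be uniform")
  if (length(object@amplitude) != length(tb))
    msg <- c(msg, "amplitude and timebase lengths differ")
  if (!all(is.finite(object@amplitude)))
    msg <- c(msg, "amplitude must be finite")
  pr <- object@peakRegistry
  need <- c("label", "latency_ms", "amplitude_uv", "width_ms")
  if (!all(need %in% names(pr)))
    msg <- c(msg, "peakRegistry lacks required columns")
  else if (nrow(pr) && (any(pr$latency_ms < min(tb)) || any(pr$latency_ms > max(tb))))
    msg <- c(msg, "peak latency outside the timebase")
  if (object@stimulusKind == "da40") {
    if (length(object@f0) != 1L || object@f0 <= 0)
      msg <- c(msg, "da40 template requires f0 > 0")
  } else if (length(object@f0))
    msg <- c(msg, "f0 must be absent for a click template")
  if (length(msg)) msg else TRUE
})

#' Trial-level noise and artifact model
#'
#' Parameterises the mechanisms that degrade single-trial responses:
#' additive band-limited Gaussian noise, whole-template latency jitter,
#' multiplicative amplitude variability, occasional large-excursion artifact
#' trials, and a deterministic sinusoidal component that flips sign with
#' stimulus polarity (mimicking cochlear-microphonic / stimulus artifact that
#' balanced subaveraging must cancel).
#'
#' @slot noiseSd SD of the additive band-limited noise, microvolts.
#' @slot jitterSd SD of the per-trial latency shift, ms.
#' @slot ampCv Coefficient of variation of the per-trial amplitude factor.
#' @slot artifactRate Probability per trial of a super-threshold excursion.
#' @slot polarityComponentAmp Amplitude (microvolts) of the polarity-locked
#'   sinusoid; 0 disables it.
#' @slot polarityComponentHz Frequency of that sinusoid, Hz.
#' @slot noiseBand Two-element band (Hz) the additive noise is limited to.
#'
#' @seealso [noiseModel()]
#' @export
setClass("NoiseModel",
  representation(
    noiseSd              = "numeric",
    jitterSd             = "numeric",
    ampCv                = "numeric",
    artifactRate         = "numeric",
    polarityComponentAmp = "numeric",
    polarityComponentHz  = "numeric",
    noiseBand            = "numeric"
  )
)

setValidity("NoiseModel", function(object) {
  msg <- character()
  nn <- c(object@noiseSd, object@jitterSd, object@ampCv,
          object@polarityComponentAmp, object@polarityComponentHz)
  if (any(!is.finite(nn)) || any(nn < 0))
    msg <- c(msg, "noise parameters must be finite and nonnegative")
  if (object@artifactRate < 0 || object@artifactRate > 1)
    msg <- c(msg, "artifactRate must lie in [0, 1]")
  if (length(object@noiseBand) != 2L || object@noiseBand[1] <= 0 ||
      diff(object@noiseBand) <= 0)
    msg <- c(msg, "noiseBand must be an increasing positive pair (Hz)")
  if (length(msg)) msg else TRUE
})

#' Cohort-level simulation design
#'
#' Ground truth for a simulated cohort on the Fisher-z stability scale.  The
#' per-observation model mirrors the random-intercept mixed model used for
#' inference: \deqn{Z_{ij} = \mu + \alpha_{j} + \beta\,AQ_i + b_i + e_{ij}}
#' with sum-to-zero component offsets \eqn{\alpha_j}, participant intercepts
#' \eqn{b_i \sim N(0, \sigma_b^2)} and residuals
#' \eqn{e_{ij} \sim N(0, \sigma_e^2)}.
#'
#' @slot nParticipants Number of participants (>= 2).
#' @slot intercept Grand mean on the Fisher-z scale.
#' @slot traitMean,traitSd Mean and SD of the simulated AQ totals.
#' @slot betaTrait Change in Fisher z per AQ point.
#' @slot componentOffsets Named numeric of length 5 (one per component),
#'   summing to zero (effects-coding ground truth).
#' @slot participantSd Random-intercept SD (Fisher z).
#' @slot residualSd Residual SD (Fisher z).
#' @slot betaSubscale Optional extra slope for one AQ subscale beyond the
#'   total (0 disables).
#' @slot subscaleName Subscale that carries \code{betaSubscale}.
#' @slot seed Integer seed; mandatory for reproducibility.
#'
#' @seealso [cohortSpec()], [simulateCohort()]
#' @export
setClass("CohortSpec",
  representation(
    nParticipants    = "integer",
    intercept        = "numeric",
    traitMean        = "numeric",
    traitSd          = "numeric",
    betaTrait        = "numeric",
    componentOffsets = "numeric",
    participantSd    = "numeric",
    residualSd       = "numeric",
    betaSubscale     = "numeric",
    subscaleName     = "character",
    seed             = "integer"
  )
)

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (object@nParticipants < 2L)
    msg <- c(msg, "nParticipants must be >= 2")
  off <- object@componentOffsets
  if (length(off) != 5L || !setequal(names(off), .COMPONENTS))
    msg <- c(msg, "componentOffsets must be named over the five components")
  else if (abs(sum(off)) > 1e-8)
    msg <- c(msg, "componentOffsets must sum to zero")
  if (object@traitSd < 0 || object@participantSd < 0 || object@residualSd < 0)
    msg <- c(msg, "SDs must be nonnegative")
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "seed is mandatory")
  if (length(msg)) msg else TRUE
})

#' Stimulus-locked single-trial sweep buffer
#'
#' A matrix of stimulus-locked epochs (sweeps x samples, microvolts) with the
#' recording metadata needed downstream: sampling rate, epoch start relative
#' to stimulus onset, recording channel, stimulus polarity, stimulus kind,
#' participant id, and the collection index (first or second run).
#'
#' @slot data Numeric matrix, one sweep per row, microvolts.
#' @slot samplingRate Sampling rate, Hz.
#' @slot t0Offset Time of the first sample in ms relative to stimulus onset
#'   (negative = prestimulus).
#' @slot channel Recording channel, \code{"A"} or \code{"B"}.
#' @slot polarity \code{"condensation"} or \code{"rarefaction"}.
#' @slot stimulusKind \code{"click"} or \code{"da40"}.
#' @slot participantId Participant identifier.
#' @slot collectionIndex 1L or 2L (collection order).
#' @slot filterApplied Description of any filter already applied ("" if none).
#'
#' @seealso [simulateSweeps()], [readSweeps()], [bandpassSweeps()]
#' @export
setClass("SweepBuffer",
  representation(
    data            = "matrix",
    samplingRate    = "numeric",
    t0Offset        = "numeric",
    channel         = "character",
    polarity        = "character",
    stimulusKind    = "character",
    participantId   = "character",
    collectionIndex = "integer",
    filterApplied   = "character"
  )
)

setValidity("SweepBuffer", function(object) {
  msg <- character()
  if (!is.numeric(object@data) || !all(is.finite(object@data)))
    msg <- c(msg, "sweep matrix must be finite numeric")
  if (object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be positive")
  if (!object@channel %in% .CHANNELS)
    msg <- c(msg, sprintf("channel must be one of %s",
                          paste(.CHANNELS, collapse = ", ")))
  if (!object@polarity %in% .POLARITIES)
    msg <- c(msg, sprintf("polarity must be one of %s",
                          paste(.POLARITIES, collapse = ", ")))
  if (!object@stimulusKind %in% .STIMULI)
    msg <- c(msg, "unknown stimulusKind")
  if (!object@collectionIndex %in% c(1L, 2L))
    msg <- c(msg, "collectionIndex must be 1 or 2")
  if (length(msg)) msg else TRUE
})

#' Averaged evoked response with exact composition bookkeeping
#'
#' One averaged (or subaveraged) waveform together with a record of exactly
#' how many sweeps from each (channel, polarity) cell contributed, so that the
#' polarity/channel balance of a subaverage is auditable.
#'
#' @slot amplitude Numeric vector, microvolts per sample.
#' @slot samplingRate Sampling rate, Hz.
#' @slot t0Offset Time of the first sample, ms relative to stimulus onset.
#' @slot stimulusKind \code{"click"} or \code{"da40"}.
#' @slot participantId Participant identifier.
#' @slot composition \code{data.frame} with columns \code{channel},
#'   \code{polarity}, \code{n} (sweep counts, >= 0).
#' @slot provenance Character vector of source buffer identifiers, in order.
#'
#' @seealso [buildSubaverages()], [exportWaveform()]
#' @export
setClass("AveragedResponse",
  representation(
    amplitude     = "numeric",
    samplingRate  = "numeric",
    t0Offset      = "numeric",
    stimulusKind  = "character",
    participantId = "character",
    composition   = "data.frame",
    provenance    = "character"
  )
)

setValidity("AveragedResponse", function(object) {
  msg <- character()
  if (!all(is.finite(object@amplitude)))
    msg <- c(msg, "amplitude must be finite")
  comp <- object@composition
  if (!all(c("channel", "polarity", "n") %in% names(comp)))
    msg <- c(msg, "composition needs columns channel, polarity, n")
  else if (nrow(comp) && any(comp$n < 0))
    msg <- c(msg, "composition counts must be >= 0")
  if (length(msg)) msg else TRUE
})
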