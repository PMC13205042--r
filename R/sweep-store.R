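## Centralized ms <-> sample-index conversion (floor-based).  Index 1 holds
## the sample at t0Offset; a time t maps to the index of the last sample at
## or before t.
.FORMAT_VERSION <- "abrstab-1"

#' Convert a time in ms to a sample index
#'
#' Floor-based: returns the 1-based index of the sample at time
#' \code{t0Offset + (i-1)/rate*1000} such that the sample time is the largest
#' one not exceeding \code{ms} (up to a half-sample tolerance for floating
#' point).
#'
#' @param ms Time in ms relative to stimulus onset.
#' @param samplingRate Sampling rate, Hz.
#' @param t0Offset Time of the first sample, ms.
#' @return Integer sample index (may fall outside the epoch; callers check).
#' @export
msToIndex <- function(ms, samplingRate, t0Offset) {
  as.integer(floor((ms - t0Offset) * samplingRate / 1000 + 1e-9)) + 1L
}

.sidecarPath <- function(path) sub("\\.csv$", ".json", path)

.requiredMeta <- c("format_version", "units", "sampling_rate_hz",
                   "t0_offset_ms", "window_ms", "n_sweeps", "n_samples",
                   "channel", "polarity", "stimulus_kind", "participant_id",
                   "collection_index")

#' Write / read a sweep buffer
#'
#' The on-disk layout is an open two-file format: the numeric payload as
#' headerless delimited text (one sweep per row, microvolts) and a JSON
#' sidecar carrying all metadata (fields: format_version, units,
#' sampling_rate_hz, t0_offset_ms, window_ms, n_sweeps, n_samples, channel,
#' polarity, stimulus_kind, participant_id, collection_index,
#' filter_applied).  \code{readSweeps} validates the sidecar: any missing
#' field is a hard error naming the field, the units must be microvolts, and
#' the declared sample count must satisfy
#' \code{n_samples == round(window_ms * rate / 1000)} and match the matrix.
#'
#' @param buffer A \linkS4class{SweepBuffer}.
#' @param path Path to the \code{.csv} payload; the sidecar is written next
#'   to it with extension \code{.json}.
#' @return \code{writeSweeps}: the payload path, invisibly.
#'   \code{readSweeps}: a \linkS4class{SweepBuffer}.
#' @examples
#' tpl <- makeTemplate("click")
#' buf <- simulateSweeps(tpl, nSweeps = 3, seed = 1)
#' p <- file.path(tempdir(), "demo_click_A_condensation.csv")
#' writeSweeps(buf, p)
#' identical(sweepData(readSweeps(p)), sweepData(buf))
#' @export
writeSweeps <- function(buffer, path) {
  stopifnot(is(buffer, "SweepBuffer"))
  validObject(buffer)
  m <- ncol(buffer@data)
  meta <- list(
    format_version   = .FORMAT_VERSION,
    units            = "uV",
    sampling_rate_hz = buffer@samplingRate,
    t0_offset_ms     = buffer@t0Offset,
    window_ms        = m / buffer@samplingRate * 1000,
    n_sweeps         = nrow(buffer@data),
    n_samples        = m,
    channel          = buffer@channel,
    polarity         = buffer@polarity,
    stimulus_kind    = buffer@stimulusKind,
    participant_id   = buffer@participantId,
    collection_index = buffer@collectionIndex,
    filter_applied   = buffer@filterApplied
  )
  data.table::fwrite(data.table::as.data.table(buffer@data), path,
                     col.names = FALSE)
  jsonlite::write_json(meta, .sidecarPath(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeSweeps
#' @export
readSweeps <- function(path) {
  side <- .sidecarPath(path)
  if (!file.exists(path)) stop("payload file not found: ", path)
  if (!file.exists(side)) stop("metadata sidecar not found: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  missing <- setdiff(.requiredMeta, names(meta))
  if (length(missing))
    stop("sidecar is missing required field(s): ",
         paste(missing, collapse = ", "))
  if (!identical(meta$units, "uV"))
    stop("unit field must be 'uV', got '", meta$units, "'")
  expected <- round(meta$window_ms * meta$sampling_rate_hz / 1000)
  if (meta$n_samples != expected)
    stop(sprintf(
      "declared n_samples (%d) inconsistent with window_ms x rate (%g ms at %g Hz implies %d samples)",
      meta$n_samples, meta$window_ms, meta$sampling_rate_hz, expected))
  dat <- as.matrix(data.table::fread(path, header = FALSE))
  dimnames(dat) <- NULL
  if (ncol(dat) != meta$n_samples || nrow(dat) != meta$n_sweeps)
    stop(sprintf(
      "payload is %d x %d but sidecar declares %d sweeps x %d samples",
      nrow(dat), ncol(dat), meta$n_sweeps, meta$n_samples))
  new("SweepBuffer", data = dat,
      samplingRate = meta$sampling_rate_hz, t0Offset = meta$t0_offset_ms,
      channel = meta$channel, polarity = meta$polarity,
      stimulusKind = meta$stimulus_kind,
      participantId = as.character(meta$participant_id),
      collectionIndex = as.integer(meta$collection_index),
      filterApplied = if (is.null(meta$filter_applied)) ""
                      else meta$filter_applied)
}

#' Canonical file name for a stored sweep buffer
#'
#' \code{<participant>_<stimulus>_<channel>_<polarity>.csv}; collection index
#' is appended when > 1.
#'
#' @param buffer A \linkS4class{SweepBuffer}.
#' @return File name (no directory).
#' @export
sweepFileName <- function(buffer) {
  base <- sprintf("%s_%s_%s_%s", buffer@participantId, buffer@stimulusKind,
                  buffer@channel, buffer@polarity)
  if (buffer@collectionIndex > 1L)
    base <- sprintf("%s_%d", base, buffer@collectionIndex)
  paste0(base, ".csv")
}

#' Export an averaged waveform as two-column text
#'
#' Writes \code{time_ms, amplitude_uV} with a header row at six significant
#' digits, sufficient for re-reads to agree within 1e-5 microvolts at
#' physiological amplitudes.
#'
#' @param avg An \linkS4class{AveragedResponse}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
exportWaveform <- function(avg, path) {
  stopifnot(is(avg, "AveragedResponse"))
  validObject(avg)
  df <- data.frame(time_ms = signif(sweepTimes(avg), 6),
                   amplitude_uV = signif(avg@amplitude, 6))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an exported waveform
#'
#' @param path Path written by [exportWaveform()].
#' @return \code{data.frame} with columns \code{time_ms},
#'   \code{amplitude_uV}.
#' @export
readWaveform <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_ms", "amplitude_uV") %in% names(df)))
    stop("not a waveform export: expected columns time_ms, amplitude_uV")
  df
}
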