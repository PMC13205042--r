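#' Zero-phase bandpass filter a sweep buffer
#'
#' Applies a 4th-order Butterworth bandpass forward and backward
#' (\code{signal::filtfilt}), so latencies are preserved and DC is removed.
#' The defaults (100-3000 Hz) are the conventional brainstem-response band.
#' The applied filter is recorded in the buffer metadata.
#'
#' @param buffer A \linkS4class{SweepBuffer}.
#' @param lowHz,highHz Band edges in Hz; must satisfy
#'   \code{0 < lowHz < highHz < samplingRate/2}.
#' @param order Butterworth order (per pass); default 4.
#' @return A filtered \linkS4class{SweepBuffer}.
#' @export
bandpassSweeps <- function(buffer, lowHz = 100, highHz = 3000, order = 4) {
  stopifnot(is(buffer, "SweepBuffer"))
  rate <- buffer@samplingRate
  if (lowHz <= 0 || highHz <= lowHz || highHz >= rate / 2)
    stop("band must satisfy 0 < lowHz < highHz < samplingRate/2")
  bf <- signal::butter(order, c(lowHz, highHz) / (rate / 2), type = "pass")
  ## remove the per-sweep mean first: the IIR start-up transient of a DC
  ## offset would otherwise dwarf the response on short epochs
  dat <- t(apply(buffer@data, 1, function(x)
    signal::filtfilt(bf, x - mean(x))))
  out <- buffer
  out@data <- dat
  out@filterApplied <- sprintf("butterworth%d-bandpass-%g-%g-zerophase",
                               order, lowHz, highHz)
  out
}

#' Amplitude-based artifact rejection
#'
#' Rejects sweeps whose per-sample peak magnitude strictly exceeds the
#' threshold ("exceeding +/- 35 microvolts"); a sweep peaking at exactly the
#' threshold is kept.  Order of the kept sweeps is preserved, and the
#' decision is per-sweep, so it is independent of sweep order.
#'
#' @param buffer A \linkS4class{SweepBuffer}.
#' @param thresholdUv Rejection criterion in microvolts (default 35).
#' @return A list with \code{buffer} (kept sweeps) and \code{report}, a
#'   rejection report list with fields \code{n_in}, \code{n_rejected},
#'   \code{n_kept}, \code{threshold_uv} and \code{rejected_indices}.
#' @export
rejectArtifacts <- function(buffer, thresholdUv = 35) {
  stopifnot(is(buffer, "SweepBuffer"))
  if (thresholdUv <= 0) stop("thresholdUv must be positive")
  peak <- apply(abs(buffer@data), 1, max)
  bad <- which(peak > thresholdUv)
  if (length(bad) == nrow(buffer@data))
    stop("all ", nrow(buffer@data), " sweeps exceed +/-", thresholdUv,
         " uV; empty buffer")
  out <- buffer
  out@data <- buffer@data[setdiff(seq_len(nrow(buffer@data)), bad), ,
                          drop = FALSE]
  report <- list(n_in = nrow(buffer@data), n_rejected = length(bad),
                 n_kept = nrow(out@data), threshold_uv = thresholdUv,
                 rejected_indices = bad)
  list(buffer = out, report = report)
}

#' Accumulate the first N low-noise sweeps
#'
#' Mirrors online averaging to a fixed low-noise criterion: sweeps are
#' filtered (optional), screened against the rejection threshold, and the
#' first \code{target} accepted sweeps are kept in arrival order.  By default
#' rejection is tested on the filtered sweeps, matching acquisition systems
#' that filter before averaging (\code{rejectOn = "raw"} screens the
#' unfiltered sweeps instead, then returns them filtered if \code{filter} is
#' TRUE).
#'
#' @param buffer A \linkS4class{SweepBuffer} holding the incoming sweep
#'   stream in arrival order.
#' @param target Number of accepted sweeps required (default 1500).
#' @param thresholdUv Rejection criterion, microvolts (default 35).
#' @param filter Apply the standard 100-3000 Hz zero-phase bandpass first?
#'   Default TRUE.
#' @param rejectOn \code{"filtered"} (default) or \code{"raw"}.
#' @return A list with \code{buffer} (exactly \code{target} sweeps) and
#'   \code{report} (as in [rejectArtifacts()], plus \code{target}).
#' @export
accumulateLowNoise <- function(buffer, target = 1500, thresholdUv = 35,
                               filter = TRUE,
                               rejectOn = c("filtered", "raw")) {
  stopifnot(is(buffer, "SweepBuffer"))
  rejectOn <- match.arg(rejectOn)
  screened <- if (filter && rejectOn == "filtered")
    bandpassSweeps(buffer) else buffer
  peak <- apply(abs(screened@data), 1, max)
  accepted <- which(peak <= thresholdUv)
  if (length(accepted) < target)
    stop(sprintf(
      "sweep stream exhausted: %d accepted of %d needed (%d short)",
      length(accepted), target, target - length(accepted)))
  keep <- accepted[seq_len(target)]
  out <- if (filter && rejectOn == "raw") bandpassSweeps(buffer) else screened
  out@data <- out@data[keep, , drop = FALSE]
  report <- list(n_in = nrow(buffer@data),
                 n_rejected = sum(peak > thresholdUv),
                 n_kept = target, threshold_uv = thresholdUv,
                 target = target, rejected_indices = which(peak > thresholdUv))
  list(buffer = out, report = report)
}
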