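#' Canonical component analysis windows
#'
#' Returns the windows (ms post-onset, half-open \code{[start, end)}) over
#' which waveform stability is correlated: click ABR 1-8 ms, and for the
#' /da/ response the full response 0-55 ms, onset 5-10 ms, FFR (sustained)
#' 22-40 ms and offset 45-50 ms.
#'
#' @param name Optional component name; if given, a single-row window.
#' @return \code{data.frame} with columns \code{name}, \code{start_ms},
#'   \code{end_ms}.
#' @export
componentWindows <- function(name = NULL) {
  w <- data.frame(
    name     = c("click", "full_sabr", "onset", "ffr", "offset"),
    start_ms = c(1, 0, 5, 22, 45),
    end_ms   = c(8, 55, 10, 40, 50),
    stringsAsFactors = FALSE
  )
  if (is.null(name)) return(w)
  if (!name %in% w$name) stop("unknown component window: ", name)
  w[w$name == name, , drop = FALSE]
}

#' Slice an averaged waveform to a component window
#'
#' Half-open window: samples with \code{start_ms <= t < end_ms}, with the
#' floor-based ms-to-index convention of [msToIndex()], so adjacent windows
#' never share samples.
#'
#' @param avg An \linkS4class{AveragedResponse}.
#' @param window One row of [componentWindows()] or a list with
#'   \code{start_ms}, \code{end_ms}.
#' @return Numeric amplitude vector.
#' @export
windowSlice <- function(avg, window) {
  stopifnot(is(avg, "AveragedResponse"))
  start <- window$start_ms
  end <- window$end_ms
  if (start >= end) stop("window start must precede end")
  n <- length(avg@amplitude)
  i1 <- msToIndex(start, avg@samplingRate, avg@t0Offset)
  i2 <- msToIndex(end, avg@samplingRate, avg@t0Offset)  # first excluded index
  if (i1 < 1L || i2 > n + 1L)
    stop(sprintf("window %g-%g ms lies outside the %g-%g ms epoch",
                 start, end, avg@t0Offset,
                 avg@t0Offset + n / avg@samplingRate * 1000))
  avg@amplitude[i1:(i2 - 1L)]
}

#' Windowed Pearson stability between two averaged responses
#'
#' The package's core statistic: the Pearson product-moment correlation of
#' the two subaverage waveforms over a component window.  A constant slice
#' makes the correlation undefined and is a hard error, never a silent zero.
#'
#' @param avg1,avg2 \linkS4class{AveragedResponse} objects on the same
#'   timebase.
#' @param window As in [windowSlice()].
#' @return Pearson r.
#' @export
stabilityR <- function(avg1, avg2, window) {
  if (length(avg1@amplitude) != length(avg2@amplitude) ||
      abs(avg1@t0Offset - avg2@t0Offset) > 1e-9 ||
      abs(avg1@samplingRate - avg2@samplingRate) > 1e-9)
    stop("the two averages do not share a timebase")
  x <- windowSlice(avg1, window)
  y <- windowSlice(avg2, window)
  if (length(x) < 3L) stop("window holds fewer than 3 samples")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant waveform slice: correlation undefined")
  stats::cor(x, y)
}

#' Fisher z-transform of a correlation
#'
#' \code{atanh(r)} after clamping \code{|r|} to \code{1 - 1e-7}, so the
#' noiseless limit r = 1 maps to a large finite value rather than Inf.
#' Strictly monotone; \code{|r| > 1} is an error.
#'
#' @param r Correlation(s) in [-1, 1].
#' @return Fisher z value(s).
#' @examples
#' fisherZ(0.85)  # 1.25615
#' @export
fisherZ <- function(r) {
  if (any(abs(r) > 1 + 1e-12)) stop("|r| > 1: not a correlation")
  atanh(pmin(1 - 1e-7, pmax(-(1 - 1e-7), r)))
}

.bufferKey <- function(b)
  sprintf("%s_%s_%s_%s_%d", b@participantId, b@stimulusKind, b@channel,
          b@polarity, b@collectionIndex)

.meanResponse <- function(buffers, participantId, stimulusKind) {
  dat <- do.call(rbind, lapply(buffers, slot, "data"))
  compTab <- do.call(rbind, lapply(buffers, function(b)
    data.frame(channel = b@channel, polarity = b@polarity,
               n = nrow(b@data), stringsAsFactors = FALSE)))
  comp <- stats::aggregate(n ~ channel + polarity, compTab, sum)
  new("AveragedResponse", amplitude = colMeans(dat),
      samplingRate = buffers[[1]]@samplingRate,
      t0Offset = buffers[[1]]@t0Offset, stimulusKind = stimulusKind,
      participantId = participantId, composition = comp,
      provenance = vapply(buffers, .bufferKey, character(1)))
}

#' Build the two polarity- and channel-balanced subaverages
#'
#' Pairs condensation sweeps from one channel with rarefaction sweeps from
#' the opposite channel and vice versa: subaverage 1 is the mean over
#' {A-condensation, B-rarefaction}, subaverage 2 over {B-condensation,
#' A-rarefaction}.  The two subaverages draw on disjoint sweep sets, contain
#' equal numbers of sweeps per polarity and per channel, and therefore cancel
#' any component that flips sign with polarity (cochlear microphonic /
#' stimulus artifact) as well as channel and collection-order effects.
#' Composition counts are recorded exactly.
#'
#' @param bufAcond,bufArare,bufBcond,bufBrare The four per-(channel,
#'   polarity) \linkS4class{SweepBuffer}s of one participant and stimulus,
#'   with equal sweep counts.
#' @param onUnequal \code{"error"} (default) or \code{"truncate"}: what to do
#'   when buffer sizes differ (truncation keeps the first \code{min(n)}
#'   sweeps of each buffer).
#' @return List of two \linkS4class{AveragedResponse} objects
#'   (\code{sub1}, \code{sub2}).
#' @export
buildSubaverages <- function(bufAcond, bufArare, bufBcond, bufBrare,
                             onUnequal = c("error", "truncate")) {
  onUnequal <- match.arg(onUnequal)
  bufs <- list(bufAcond, bufArare, bufBcond, bufBrare)
  stopifnot(all(vapply(bufs, is, logical(1), "SweepBuffer")))
  pid <- unique(vapply(bufs, slot, character(1), "participantId"))
  stim <- unique(vapply(bufs, slot, character(1), "stimulusKind"))
  if (length(pid) != 1L || length(stim) != 1L)
    stop("buffers mix participants or stimuli")
  t0 <- vapply(bufs, slot, numeric(1), "t0Offset")
  rate <- vapply(bufs, slot, numeric(1), "samplingRate")
  ns <- vapply(bufs, function(b) ncol(b@data), integer(1))
  if (diff(range(t0)) > 1e-9 || diff(range(rate)) > 1e-9 ||
      length(unique(ns)) != 1L)
    stop("buffers do not share a timebase")
  counts <- vapply(bufs, nSweeps, integer(1))
  if (length(unique(counts)) != 1L) {
    if (onUnequal == "error")
      stop("unequal buffer sizes: ", paste(counts, collapse = ", "))
    nmin <- min(counts)
    bufs <- lapply(bufs, function(b) {
      b@data <- b@data[seq_len(nmin), , drop = FALSE]; b
    })
  }
  list(
    sub1 = .meanResponse(bufs[c(1, 4)], pid, stim),  # A-cond + B-rare
    sub2 = .meanResponse(bufs[c(3, 2)], pid, stim)   # B-cond + A-rare
  )
}

#' Split a single-polarity buffer by collection order
#'
#' Click responses are collected with a single polarity, so the balanced
#' subaveraging substitutes the first/second halves of the accepted sweeps
#' (collection order) for the polarity split, preserving disjointness and
#' channel balance.
#'
#' @param buffer A \linkS4class{SweepBuffer}.
#' @return List of two buffers with \code{collectionIndex} 1 and 2; for an
#'   odd sweep count the first half receives the extra sweep.
#' @export
splitByCollection <- function(buffer) {
  stopifnot(is(buffer, "SweepBuffer"))
  n <- nSweeps(buffer)
  if (n < 2L) stop("need at least 2 sweeps to split by collection order")
  h <- ceiling(n / 2)
  first <- buffer; second <- buffer
  first@data <- buffer@data[seq_len(h), , drop = FALSE]
  first@collectionIndex <- 1L
  second@data <- buffer@data[(h + 1L):n, , drop = FALSE]
  second@collectionIndex <- 2L
  list(first = first, second = second)
}

.stabilityForPair <- function(sub, windows, stimulus) {
  do.call(rbind, lapply(seq_len(nrow(windows)), function(k) {
    w <- windows[k, , drop = FALSE]
    r <- stabilityR(sub$sub1, sub$sub2, w)
    data.frame(participant_id = sub$sub1@participantId,
               stimulus = stimulus, component = w$name, r = r,
               z = fisherZ(r),
               n_samples_in_window = length(windowSlice(sub$sub1, w)),
               n_sweeps_sub1 = sum(sub$sub1@composition$n),
               n_sweeps_sub2 = sum(sub$sub2@composition$n),
               stringsAsFactors = FALSE)
  }))
}

#' Per-participant stability records from sweep buffers
#'
#' Composes the full stability pipeline for one participant: balanced
#' subaverages, component-window correlations, Fisher transform.  The /da/
#' buffers (4: channel x polarity) yield the four speech components; the
#' click buffers (2 channels, single polarity, split by collection order)
#' yield the click component.  Either stimulus may be absent - a participant
#' with only a usable click still yields a click record.
#'
#' @param daBuffers Optional list of the four /da/
#'   \linkS4class{SweepBuffer}s named \code{Acond}, \code{Arare},
#'   \code{Bcond}, \code{Brare}.
#' @param clickBuffers Optional list of the two click buffers named
#'   \code{A}, \code{B}.
#' @return \code{data.frame} with one row per available component:
#'   \code{participant_id}, \code{stimulus}, \code{component}, \code{r},
#'   \code{z}, \code{n_samples_in_window}, \code{n_sweeps_sub1},
#'   \code{n_sweeps_sub2}.
#' @export
stabilityTable <- function(daBuffers = NULL, clickBuffers = NULL) {
  out <- list()
  if (!is.null(daBuffers)) {
    stopifnot(all(c("Acond", "Arare", "Bcond", "Brare") %in% names(daBuffers)))
    sub <- buildSubaverages(daBuffers$Acond, daBuffers$Arare,
                            daBuffers$Bcond, daBuffers$Brare)
    w <- componentWindows()
    out$da <- .stabilityForPair(sub, w[w$name != "click", ], "da40")
  }
  if (!is.null(clickBuffers)) {
    stopifnot(all(c("A", "B") %in% names(clickBuffers)))
    ha <- splitByCollection(clickBuffers$A)
    hb <- splitByCollection(clickBuffers$B)
    ## collection halves stand in for the polarity split
    sub <- list(sub1 = .meanResponse(list(ha$first, hb$second),
                                     clickBuffers$A@participantId, "click"),
                sub2 = .meanResponse(list(hb$first, ha$second),
                                     clickBuffers$A@participantId, "click"))
    out$click <- .stabilityForPair(sub, componentWindows("click"), "click")
  }
  if (!length(out)) stop("no buffers supplied")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
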