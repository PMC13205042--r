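## Canonical peak constants (literature-typical latencies/amplitudes; the
## sustained troughs D-E-F are spaced exactly 1/f0 apart so the interpeak
## interval equals the fundamental wavelength).

.clickPeakDefaults <- function() {
  data.frame(
    label        = c("I", "III", "V"),
    latency_ms   = c(1.7, 3.9, 5.7),
    amplitude_uv = c(0.20, 0.25, 0.40),
    width_ms     = c(0.5, 0.6, 0.8),
    stringsAsFactors = FALSE
  )
}

.daPeakDefaults <- function(f0Hz) {
  period <- 1000 / f0Hz
  data.frame(
    label        = c("V", "A", "C", "D", "E", "F", "O"),
    latency_ms   = c(6.6, 7.5, 18.5,
                     22.5, 22.5 + period, 22.5 + 2 * period, 48),
    amplitude_uv = c(0.35, -0.45, -0.15, -0.25, -0.25, -0.25, -0.30),
    width_ms     = c(1.0, 1.0, 1.2, NA, NA, NA, 1.0),
    stringsAsFactors = FALSE
  )
}

.EPOCHS <- list(click = c(-5, 20), da40 = c(-5, 55))

.gaussPeak <- function(t, latency, amp, width) {
  sigma <- width / 2.355            # width treated as FWHM
  amp * exp(-0.5 * ((t - latency) / sigma)^2)
}

## Raised-cosine on/off envelope for the sustained (FFR) portion.
.sustainEnvelope <- function(t, on, full, release, off) {
  env <- numeric(length(t))
  ramp <- t >= on & t < full
  env[ramp] <- 0.5 - 0.5 * cos(pi * (t[ramp] - on) / (full - on))
  env[t >= full & t <= release] <- 1
  fall <- t > release & t <= off
  env[fall] <- 0.5 + 0.5 * cos(pi * (t[fall] - release) / (off - release))
  env
}

#' Build a deterministic click or /da/ response template
#'
#' Constructs the noise-free waveform that [simulateSweeps()] perturbs.  The
#' click template spans a 25 ms epoch (-5 to +20 ms) and consists of
#' Gaussian-shaped waves I, III and V.  The 40 ms /da/ template spans a 60 ms
#' epoch (-5 to +55 ms): a V/A onset complex, a transition trough C, a
#' sustained portion phase-locked to the fundamental \code{f0Hz} (plus an
#' attenuated second harmonic) whose troughs are the D, E, F waves spaced
#' exactly \code{1000/f0Hz} ms apart, and an offset wave O near 48 ms.
#'
#' The template is fully deterministic for fixed arguments.  Peak latencies
#' and amplitudes are literature-typical constants exposed through
#' \code{peaks} for users who need different waveform anatomy.
#'
#' @param stimulusKind \code{"click"} or \code{"da40"}.
#' @param samplingRateHz Sampling rate in Hz (>= 8000); default 20000.
#' @param f0Hz Fundamental frequency of the sustained portion (da40 only);
#'   default 100 Hz, held constant over the vowel (no pitch ramp).
#' @param peaks Optional \code{data.frame} overriding the default peak
#'   registry (columns \code{label}, \code{latency_ms}, \code{amplitude_uv},
#'   \code{width_ms}; sustained rows may carry \code{NA} width).
#' @return A \linkS4class{ResponseTemplate}.
#' @examples
#' tpl <- makeTemplate("da40")
#' peakRegistry(tpl)
#' @export
makeTemplate <- function(stimulusKind = c("click", "da40"),
                         samplingRateHz = 20000, f0Hz = NULL, peaks = NULL) {
  stimulusKind <- match.arg(stimulusKind)
  if (samplingRateHz < 8000)
    stop("samplingRateHz must be >= 8000")
  if (stimulusKind == "click" && !is.null(f0Hz))
    stop("f0Hz is only meaningful for the da40 template")
  if (stimulusKind == "da40" && is.null(f0Hz))
    f0Hz <- 100
  if (!is.null(f0Hz) && f0Hz <= 0)
    stop("f0Hz must be positive")

  epoch <- .EPOCHS[[stimulusKind]]
  nSamples <- round(diff(epoch) * samplingRateHz / 1000)
  t <- epoch[1] + (seq_len(nSamples) - 1L) / samplingRateHz * 1000

  if (is.null(peaks)) {
    peaks <- if (stimulusKind == "click") .clickPeakDefaults()
             else .daPeakDefaults(f0Hz)
  }

  amp <- numeric(nSamples)
  if (stimulusKind == "click") {
    for (k in seq_len(nrow(peaks)))
      amp <- amp + .gaussPeak(t, peaks$latency_ms[k],
                              peaks$amplitude_uv[k], peaks$width_ms[k])
    ## slow negativity after wave V, not a registered peak
    amp <- amp + .gaussPeak(t, 6.9, -0.25, 1.2)
    f0 <- numeric(0)
  } else {
    transient <- is.na(peaks$width_ms) == FALSE
    for (k in which(transient))
      amp <- amp + .gaussPeak(t, peaks$latency_ms[k],
                              peaks$amplitude_uv[k], peaks$width_ms[k])
    sustained <- peaks[is.na(peaks$width_ms), , drop = FALSE]
    if (nrow(sustained)) {
      period <- 1000 / f0Hz
      phase0 <- min(sustained$latency_ms)   # first sustained trough (wave D)
      ampS <- abs(sustained$amplitude_uv[1])
      env <- .sustainEnvelope(t, on = phase0 - 2, full = phase0,
                              release = max(sustained$latency_ms),
                              off = max(sustained$latency_ms) + 2)
      carrier <- -cos(2 * pi * f0Hz * (t - phase0) / 1000) -
        0.25 * cos(2 * pi * 2 * f0Hz * (t - phase0) / 1000)
      amp <- amp + ampS * env * carrier / 1.25
    }
    f0 <- f0Hz
  }

  new("ResponseTemplate",
      stimulusKind = stimulusKind, timebase = t, amplitude = amp,
      samplingRate = samplingRateHz, peakRegistry = peaks, f0 = f0)
}
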