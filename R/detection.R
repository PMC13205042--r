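## Windowed DFT power at arbitrary frequencies (Hann window, segment
## demeaned so DC leakage cannot reach the signal bin).
.hannPower <- function(x, rate, freqs) {
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L))
  xw <- (x - mean(x)) * w
  tt <- (seq_len(n) - 1L) / rate
  vapply(freqs, function(f) {
    e <- exp(-2i * pi * f * tt)
    Mod(sum(xw * e))^2
  }, numeric(1))
}

#' Spectral F-test for response presence against the noise floor
#'
#' Decides whether the sustained (FFR) portion of an averaged /da/ response
#' contains energy at the stimulus fundamental above the noise floor.  The
#' windowed segment (Hann taper) is evaluated at the frequency nearest
#' \code{f0Hz} on a fine (zero-padding-equivalent) grid; the noise floor is
#' the mean power over \code{2K} flanking frequencies spaced at the segment's
#' intrinsic Rayleigh resolution (rate / segment length), taken K per side
#' where the band allows and borrowed from the opposite side otherwise.  The
#' frequencies one resolution step either side of the signal are excluded.
#' With a Hann taper, bins two or more Rayleigh steps apart are effectively
#' independent, so under the null \code{F = P_signal / mean(P_noise)} is
#' F-distributed with (2, 4K) degrees of freedom.
#'
#' @param avg An \linkS4class{AveragedResponse} (a /da/ average).
#' @param window FFR window as in [windowSlice()]; default 22-40 ms.
#' @param f0Hz Fundamental frequency to test (default 100 Hz).
#' @param K Noise bins per side (default 5, so 10 noise bins).
#' @param alpha Decision level (default 0.05).
#' @return A list: \code{f_statistic}, \code{df} (length 2), \code{p_value},
#'   \code{present}, \code{signal_bin_hz}, \code{noise_bins_hz},
#'   \code{alpha}.
#' @export
spectralFTest <- function(avg, window = list(start_ms = 22, end_ms = 40),
                          f0Hz = 100, K = 5, alpha = 0.05) {
  stopifnot(is(avg, "AveragedResponse"))
  x <- windowSlice(avg, window)
  rate <- avg@samplingRate
  n <- length(x)
  rayleigh <- rate / n                     # intrinsic resolution, Hz
  if (f0Hz <= rayleigh || f0Hz >= rate / 2)
    stop(sprintf("f0 (%g Hz) outside the resolvable band (%g, %g) Hz",
                 f0Hz, rayleigh, rate / 2))
  fine <- rate / 4096                      # fine search grid
  fSig <- round(f0Hz / fine) * fine

  ## candidate noise frequencies: >= 2 Rayleigh steps from the signal and
  ## from each other, so all evaluated bins are effectively independent
  below <- fSig - 2 * rayleigh * seq_len(3 * K)
  above <- fSig + 2 * rayleigh * seq_len(3 * K)
  below <- below[below > rayleigh]
  above <- above[above < rate / 2 - rayleigh]
  nb <- min(K, length(below))
  fNoise <- c(below[seq_len(nb)], above[seq_len(min(2 * K - nb,
                                                    length(above)))])
  if (length(fNoise) < 2 * K)
    stop("window too short: fewer than 2K independent noise bins available")

  pw <- .hannPower(x, rate, c(fSig, fNoise))
  f <- pw[1] / mean(pw[-1])
  df <- c(2, 4 * K)
  p <- stats::pf(f, df[1], df[2], lower.tail = FALSE)
  list(f_statistic = f, df = df, p_value = p, present = p < alpha,
       signal_bin_hz = fSig, noise_bins_hz = fNoise, alpha = alpha)
}

#' Prestimulus-interval length
#'
#' The prestimulus noise interval is 10% of the length over which the
#' response is analyzed.  For the canonical stimuli the configured values
#' are returned directly: 0.8 ms for the click (10% of the 8 ms analysis
#' span) and 5 ms for the /da/ response.
#'
#' @param analysisWindowMs Analysis-window length in ms (used when
#'   \code{stimulusKind} is not given).
#' @param stimulusKind Optional \code{"click"} or \code{"da40"}.
#' @return Prestimulus interval in ms.
#' @examples
#' prestimWindow(stimulusKind = "click")  # 0.8
#' prestimWindow(20)                      # 2
#' @export
prestimWindow <- function(analysisWindowMs = NULL, stimulusKind = NULL) {
  if (!is.null(stimulusKind)) {
    defaults <- c(click = 0.8, da40 = 5)
    if (!stimulusKind %in% names(defaults))
      stop("unknown stimulusKind: ", stimulusKind)
    return(unname(defaults[stimulusKind]))
  }
  if (is.null(analysisWindowMs) || analysisWindowMs <= 0)
    stop("analysisWindowMs must be positive")
  0.1 * analysisWindowMs
}

#' Prestimulus RMS noise metric
#'
#' Root-mean-square amplitude over the samples with
#' \code{-prestimMs <= t < 0}; invariant to any post-stimulus content.
#'
#' @param avg An \linkS4class{AveragedResponse}.
#' @param prestimMs Prestimulus interval length, ms (see [prestimWindow()]).
#' @return A list: \code{rms_uv}, \code{window} (start/end ms),
#'   \code{analysis_window_ms} = \code{prestimMs / 0.1}, the analysis length
#'   the 10% rule corresponds to.
#' @export
prestimRms <- function(avg, prestimMs) {
  stopifnot(is(avg, "AveragedResponse"), prestimMs > 0)
  if (avg@t0Offset > -prestimMs + 1e-9)
    stop(sprintf("epoch starts at %g ms; %g ms of prestimulus required",
                 avg@t0Offset, prestimMs))
  x <- windowSlice(avg, list(start_ms = -prestimMs, end_ms = 0))
  list(rms_uv = sqrt(mean(x^2)), window = c(-prestimMs, 0),
       analysis_window_ms = prestimMs / 0.1)
}
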