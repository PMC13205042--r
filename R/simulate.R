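#' Construct a trial-level noise model
#'
#' All parameters default to zero, i.e. the noiseless limit in which every
#' simulated sweep equals the template exactly.
#'
#' @param noiseSd SD (microvolts) of additive Gaussian noise band-limited to
#'   \code{noiseBand}; after band-limiting the noise is rescaled so its
#'   marginal SD is exactly \code{noiseSd}.
#' @param jitterSd SD (ms) of the per-trial latency shift applied to the
#'   whole template by linear-interpolation resampling.
#' @param ampCv Coefficient of variation of the per-trial multiplicative
#'   amplitude factor (factor = max(0, 1 + ampCv * N(0,1))).
#' @param artifactRate Probability per trial of a large-excursion artifact
#'   (a 105 microvolt transient, well beyond the 35 microvolt rejection
#'   criterion).
#' @param polarityComponentAmp Amplitude (microvolts) of a deterministic
#'   post-onset sinusoid whose sign follows the stimulus polarity, mimicking
#'   cochlear-microphonic/stimulus artifact.
#' @param polarityComponentHz Frequency of that sinusoid (default 1000 Hz,
#'   inside the 100-3000 Hz analysis band so filtering does not remove it).
#' @param noiseBand Band (Hz) the additive noise is limited to.
#' @return A \linkS4class{NoiseModel}.
#' @export
noiseModel <- function(noiseSd = 0, jitterSd = 0, ampCv = 0,
                       artifactRate = 0, polarityComponentAmp = 0,
                       polarityComponentHz = 1000,
                       noiseBand = c(100, 3000)) {
  new("NoiseModel", noiseSd = noiseSd, jitterSd = jitterSd, ampCv = ampCv,
      artifactRate = artifactRate,
      polarityComponentAmp = polarityComponentAmp,
      polarityComponentHz = polarityComponentHz,
      noiseBand = as.numeric(noiseBand))
}

#' Specify a simulated cohort
#'
#' Defaults reproduce the study conditions this package models: 40
#' participants, AQ totals with mean 21.56 and SD 12.53, a grand-mean
#' stability of 0.43 Fisher z, sum-to-zero component offsets
#' (full sABR -0.38, onset +0.24, FFR -0.15, offset -0.47, click +0.76) and
#' an AQ slope of -0.023 Fisher z per AQ point.  The random-intercept SD
#' (0.54) and residual SD (0.64) are back-solved so the fixed effects account
#' for roughly 29% and fixed-plus-random for roughly 58% of the total
#' variance at those fixed-effect magnitudes.
#'
#' @param nParticipants Number of participants (>= 2).
#' @param intercept Grand mean, Fisher-z scale.
#' @param traitMean,traitSd Mean/SD of simulated AQ totals (integer-rounded
#'   and clamped to 0..50).
#' @param betaTrait Fisher-z change per AQ point.
#' @param componentOffsets Named numeric over
#'   \code{c("full_sabr","onset","ffr","offset","click")}, summing to zero.
#' @param participantSd Random-intercept SD (Fisher z).
#' @param residualSd Residual SD (Fisher z).
#' @param betaSubscale Optional additional slope carried by one AQ subscale
#'   beyond the total-AQ effect (0 = none).
#' @param subscaleName Which subscale carries \code{betaSubscale}.
#' @param seed Integer seed (mandatory).
#' @return A \linkS4class{CohortSpec}.
#' @export
cohortSpec <- function(nParticipants = 40,
                       intercept = 0.43,
                       traitMean = 21.56, traitSd = 12.53,
                       betaTrait = -0.023,
                       componentOffsets = c(full_sabr = -0.38, onset = 0.24,
                                            ffr = -0.15, offset = -0.47,
                                            click = 0.76),
                       participantSd = 0.54, residualSd = 0.64,
                       betaSubscale = 0,
                       subscaleName = "attention_switching",
                       seed) {
  if (missing(seed)) stop("seed is mandatory in cohortSpec()")
  new("CohortSpec",
      nParticipants = as.integer(nParticipants), intercept = intercept,
      traitMean = traitMean, traitSd = traitSd, betaTrait = betaTrait,
      componentOffsets = componentOffsets, participantSd = participantSd,
      residualSd = residualSd, betaSubscale = betaSubscale,
      subscaleName = subscaleName, seed = as.integer(seed))
}

## Evaluate an expression under a fixed RNG seed without disturbing the
## caller's RNG state.  After seeding, 64 draws are discarded: states seeded
## from nearby integers share structure in their first outputs
## (Mersenne-Twister seeding), and simulation batches routinely use
## consecutive seeds.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  invisible(stats::runif(64L))
  force(expr)
}

## Band-limited Gaussian noise, generated as one long filtered stream and
## reshaped; rescaled so the marginal SD equals sd exactly.
.bandNoise <- function(n, m, sd, band, rate) {
  x <- stats::rnorm(n * m)
  if (band[2] < rate / 2) {
    ## single-pass IIR: for stationary noise only the magnitude response
    ## matters, and one pass is half the cost of zero-phase filtering
    bf <- signal::butter(4, band / (rate / 2), type = "pass")
    x <- signal::filter(bf, x)
  }
  x <- x / stats::sd(x) * sd
  matrix(x, nrow = n, ncol = m, byrow = TRUE)
}

.polarityComponent <- function(t, amp, hz) {
  ifelse(t >= 0, amp * sin(2 * pi * hz * t / 1000), 0)
}

#' Simulate stimulus-locked sweeps from a template
#'
#' Each sweep is \code{ampFactor * shift(template, jitter) + sign *
#' polarityComponent + noise}, where the sign is +1 for condensation and -1
#' for rarefaction sweeps, jitter is drawn from N(0, jitterSd^2) and applied
#' by linear-interpolation resampling, and the additive noise is band-limited
#' Gaussian.  With \code{artifactRate > 0}, the affected trials receive a
#' 105 microvolt transient at a random post-onset latency.  Output is
#' bit-reproducible for a fixed seed.
#'
#' @param template A \linkS4class{ResponseTemplate}.
#' @param noise A \linkS4class{NoiseModel}; default is noiseless.
#' @param nSweeps Number of sweeps (>= 1).
#' @param channel Recording channel, \code{"A"} or \code{"B"}.
#' @param polarity \code{"condensation"} or \code{"rarefaction"}.
#' @param participantId Participant identifier recorded in the metadata.
#' @param collectionIndex 1L or 2L.
#' @param seed Integer seed (default 0).
#' @return A \linkS4class{SweepBuffer}.
#' @examples
#' tpl <- makeTemplate("click")
#' buf <- simulateSweeps(tpl, noiseModel(noiseSd = 2), nSweeps = 10, seed = 1)
#' nSweeps(buf)
#' @export
simulateSweeps <- function(template, noise = noiseModel(), nSweeps,
                           channel = "A", polarity = "condensation",
                           participantId = "sim", collectionIndex = 1L,
                           seed = 0L) {
  stopifnot(is(template, "ResponseTemplate"), is(noise, "NoiseModel"))
  if (nSweeps < 1) stop("nSweeps must be >= 1")
  if (!polarity %in% .POLARITIES)
    stop("polarity must be 'condensation' or 'rarefaction'")
  tb <- template@timebase
  span <- max(tb) - min(tb)
  if (noise@jitterSd > span)
    stop("jitterSd exceeds the epoch duration")

  m <- length(tb)
  polaritySign <- if (polarity == "condensation") 1 else -1
  pc <- .polarityComponent(tb, noise@polarityComponentAmp,
                           noise@polarityComponentHz)

  dat <- .withSeed(seed, {
    jit <- if (noise@jitterSd > 0)
      stats::rnorm(nSweeps, 0, noise@jitterSd) else numeric(nSweeps)
    ampf <- if (noise@ampCv > 0)
      pmax(0, 1 + noise@ampCv * stats::rnorm(nSweeps)) else rep(1, nSweeps)
    isArt <- if (noise@artifactRate > 0)
      stats::runif(nSweeps) < noise@artifactRate else logical(nSweeps)
    artLat <- stats::runif(nSweeps, 0, max(tb))

    if (noise@jitterSd > 0) {
      base <- vapply(seq_len(nSweeps), function(i)
        stats::approx(tb, template@amplitude, xout = tb - jit[i],
                      rule = 2)$y, numeric(m))
      base <- t(base) * ampf
    } else {
      base <- tcrossprod(ampf, template@amplitude)
    }
    base <- base + rep(polaritySign * pc, each = nSweeps)
    if (noise@noiseSd > 0)
      base <- base + .bandNoise(nSweeps, m, noise@noiseSd, noise@noiseBand,
                                template@samplingRate)
    if (any(isArt)) {
      for (i in which(isArt))
        base[i, ] <- base[i, ] + .gaussPeak(tb, artLat[i], 105, 2)
    }
    base
  })

  new("SweepBuffer", data = dat, samplingRate = template@samplingRate,
      t0Offset = min(tb), channel = channel, polarity = polarity,
      stimulusKind = template@stimulusKind, participantId = participantId,
      collectionIndex = as.integer(collectionIndex), filterApplied = "")
}

## Split an AQ total into five subscale scores each capped at 10.
.splitSubscales <- function(total) {
  k <- 5L; cap <- 10L
  sub <- as.integer(stats::rmultinom(1, total, rep(1 / k, k)))
  repeat {
    over <- sub > cap
    if (!any(over)) break
    excess <- sum(sub[over] - cap)
    sub[over] <- cap
    room <- which(sub < cap)
    for (j in room) {
      take <- min(excess, cap - sub[j])
      sub[j] <- sub[j] + take
      excess <- excess - take
      if (excess == 0L) break
    }
  }
  sub
}

#' Simulate a cohort of stability and trait records
#'
#' Draws participant AQ totals (and subscales, SRS-2 T-scores, age, VCI),
#' then generates Fisher-z stability per participant x component from the
#' random-intercept linear model the package's inference targets:
#' \code{z_ij = intercept + offset_j + betaTrait * AQ_i (+ betaSubscale *
#' subscale_i) + b_i + e_ij}, with \code{r = tanh(z)}.
#'
#' @param spec A \linkS4class{CohortSpec}.
#' @return A list with \code{stability} (long \code{data.frame}:
#'   \code{participant_id}, \code{component}, \code{r}, \code{z}) and
#'   \code{traits} (one row per participant: \code{participant_id},
#'   \code{aq_total}, five \code{aq_*} subscale columns, \code{aq_form},
#'   \code{srs2_t}, \code{age}, \code{vci}, \code{group}).
#' @examples
#' coh <- simulateCohort(cohortSpec(nParticipants = 5, seed = 1))
#' head(coh$stability)
#' @export
simulateCohort <- function(spec) {
  stopifnot(is(spec, "CohortSpec"))
  validObject(spec)
  n <- spec@nParticipants
  comps <- names(spec@componentOffsets)
  subNames <- c("attention_switching", "attention_to_detail",
                "communication", "social_skills", "imagination")
  if (!spec@subscaleName %in% subNames)
    stop("unknown subscaleName: ", spec@subscaleName)

  .withSeed(spec@seed, {
    aq <- pmin(50, pmax(0, round(stats::rnorm(n, spec@traitMean,
                                              spec@traitSd))))
    subs <- t(vapply(aq, .splitSubscales, integer(5)))
    colnames(subs) <- subNames
    aqZ <- if (stats::sd(aq) > 0) (aq - mean(aq)) / stats::sd(aq)
           else numeric(n)
    srs2 <- round(50 + 10 * (0.88 * aqZ +
                               sqrt(1 - 0.88^2) * stats::rnorm(n)) + 0.9)
    srs2 <- pmin(90, pmax(30, srs2))
    age <- round(stats::runif(n, 6, 16.9), 1)
    vci <- pmin(140, pmax(70, round(stats::rnorm(n, 109.24, 14.35))))
    b <- stats::rnorm(n, 0, spec@participantSd)

    pid <- sprintf("P%03d", seq_len(n))
    long <- expand.grid(participant_id = pid, component = comps,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    idx <- match(long$participant_id, pid)
    mu <- spec@intercept + spec@componentOffsets[long$component] +
      spec@betaTrait * aq[idx] +
      spec@betaSubscale * subs[idx, spec@subscaleName] +
      b[idx]
    z <- mu + stats::rnorm(nrow(long), 0, spec@residualSd)
    long$z <- as.numeric(z)
    long$r <- tanh(long$z)
    long <- long[order(long$participant_id, match(long$component, comps)),
                 c("participant_id", "component", "r", "z")]
    rownames(long) <- NULL

    traits <- data.frame(participant_id = pid, aq_total = aq,
                         stringsAsFactors = FALSE)
    traits[paste0("aq_", subNames)] <- as.data.frame(subs)
    traits$aq_form <- ifelse(age < 12, "child",
                             ifelse(age < 16, "adolescent", "adult_self"))
    traits$srs2_t <- srs2
    traits$age <- age
    traits$vci <- vci
    traits$group <- ifelse(aq >= 32, "autistic", "neurotypical")
    list(stability = long, traits = traits)
  })
}
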