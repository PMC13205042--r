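#' Default pipeline configuration
#'
#' All values default to the recording protocol the package models: click at
#' 27.7/s, 70 dB nHL, condensation polarity; 40 ms /da/ at 11.1/s, 63 dB nHL,
#' alternating polarity (stimulus rates and levels are metadata only);
#' 100-3000 Hz zero-phase bandpass; +/-35 microvolt rejection; 1500 accepted
#' sweeps per (channel, polarity) buffer; the canonical component windows;
#' single-bin spectral F-test with K = 5 noise bins per side at alpha 0.05.
#'
#' @param nParticipants Cohort size for simulated runs (default 20).
#' @param target Accepted sweeps per buffer (default 1500).
#' @return Nested configuration list.
#' @export
defaultConfig <- function(nParticipants = 20, target = 1500) {
  list(
    stimulus = list(
      click = list(rate_per_s = 27.7, level_db_nhl = 70,
                   polarity = "condensation"),
      da40 = list(rate_per_s = 11.1, level_db_nhl = 63, f0_hz = 100,
                  polarity = "alternating")
    ),
    sampling_rate_hz = 20000,
    filter = list(low_hz = 100, high_hz = 3000),
    reject = list(threshold_uv = 35),
    accumulate = list(target = target, overdraw = 1.25),
    detection = list(K = 5, alpha = 0.05, f0_hz = 100),
    noise = list(noise_sd = 2, jitter_sd = 0.12, amp_cv = 0.1,
                 artifact_rate = 0.03, polarity_component_amp = 0.3,
                 aq_noise_slope = 0.03),
    cohort = list(n_participants = nParticipants),
    models = c("M0", "M1", "M2", "M3"),
    trait = "AQ"
  )
}

.validateConfig <- function(config) {
  known <- names(defaultConfig())
  extra <- setdiff(names(config), known)
  if (length(extra))
    stop("unknown config keys: ", paste(extra, collapse = ", "))
  base <- defaultConfig()
  for (k in names(config)) {
    if (is.list(base[[k]]) && is.list(config[[k]])) {
      extra2 <- setdiff(names(config[[k]]), names(base[[k]]))
      if (length(extra2))
        stop("unknown config keys under '", k, "': ",
             paste(extra2, collapse = ", "))
      base[[k]][names(config[[k]])] <- config[[k]]
    } else base[[k]] <- config[[k]]
  }
  base
}

.participantNoise <- function(cfg, aq) {
  ## higher AQ -> noisier trials -> lower stability; the demo cohort's
  ## trait effect enters at the sweep level through this mapping
  sd <- cfg$noise$noise_sd * (1 + cfg$noise$aq_noise_slope * (aq - 21.56))
  noiseModel(noiseSd = max(0.2, sd), jitterSd = cfg$noise$jitter_sd,
             ampCv = cfg$noise$amp_cv,
             artifactRate = cfg$noise$artifact_rate,
             polarityComponentAmp = cfg$noise$polarity_component_amp,
             noiseBand = c(cfg$filter$low_hz, cfg$filter$high_hz))
}

.simulateParticipantBuffers <- function(cfg, templates, pid, nm, seed) {
  nRaw <- ceiling(cfg$accumulate$target * cfg$accumulate$overdraw)
  acc <- function(template, channel, polarity, offset) {
    raw <- simulateSweeps(template, nm, nRaw, channel = channel,
                          polarity = polarity, participantId = pid,
                          seed = seed + offset)
    accumulateLowNoise(raw, target = cfg$accumulate$target,
                       thresholdUv = cfg$reject$threshold_uv)$buffer
  }
  list(
    da = list(Acond = acc(templates$da, "A", "condensation", 1L),
              Arare = acc(templates$da, "A", "rarefaction", 2L),
              Bcond = acc(templates$da, "B", "condensation", 3L),
              Brare = acc(templates$da, "B", "rarefaction", 4L)),
    click = list(A = acc(templates$click, "A", "condensation", 5L),
                 B = acc(templates$click, "B", "condensation", 6L))
  )
}

.grandAverage <- function(sub) {
  out <- sub$sub1
  out@amplitude <- (sub$sub1@amplitude + sub$sub2@amplitude) / 2
  comp <- rbind(sub$sub1@composition, sub$sub2@composition)
  out@composition <- stats::aggregate(n ~ channel + polarity, comp, sum)
  out@provenance <- c(sub$sub1@provenance, sub$sub2@provenance)
  out
}

#' Run the full simulated-cohort pipeline
#'
#' Chains the package end to end: simulate a trait cohort, generate raw
#' sweeps per participant whose trial noise scales with the AQ score,
#' bandpass-filter / reject / accumulate to the low-noise criterion, build
#' balanced subaverages and the stability table, run spectral response
#' detection and prestimulus RMS, validate the trait table, fit the nested
#' mixed-model set, select by BIC and compute Tukey component contrasts.
#' Outputs are deterministic for a fixed seed.
#'
#' Files written to \code{outDir}: \code{stability.csv}, \code{traits.csv},
#' \code{detect.csv}, \code{model_comparison.csv}, \code{coefficients.csv},
#' \code{contrasts.csv}, and \code{manifest.json} (config hash, seed, stage
#' row counts, convergence flags, versions).
#'
#' @param config Configuration list (see [defaultConfig()]); partial lists
#'   are merged over the defaults, unknown keys are rejected.
#' @param seed Integer seed driving every stage.
#' @param outDir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results
#'   (\code{stability}, \code{traits}, \code{detect}, \code{fits},
#'   \code{selection}, \code{contrasts}, \code{manifest}).
#' @export
runPipeline <- function(config = list(), seed = 1, outDir = tempfile("abr")) {
  cfg <- .validateConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  templates <- list(
    click = makeTemplate("click", cfg$sampling_rate_hz),
    da = makeTemplate("da40", cfg$sampling_rate_hz, cfg$stimulus$da40$f0_hz)
  )

  cohort <- simulateCohort(cohortSpec(
    nParticipants = cfg$cohort$n_participants, seed = seed))
  traits <- cohort$traits

  stab <- list(); det <- list()
  for (i in seq_len(nrow(traits))) {
    pid <- traits$participant_id[i]
    nm <- .participantNoise(cfg, traits$aq_total[i])
    bufs <- tryCatch(
      .simulateParticipantBuffers(cfg, templates, pid, nm,
                                  seed = seed * 1000L + i * 10L),
      error = function(e) stop("stage simulate/preprocess failed for ",
                               pid, ": ", conditionMessage(e)))
    stab[[pid]] <- stabilityTable(daBuffers = bufs$da,
                                  clickBuffers = bufs$click)

    sub <- buildSubaverages(bufs$da$Acond, bufs$da$Arare,
                            bufs$da$Bcond, bufs$da$Brare)
    avg <- .grandAverage(sub)
    ft <- spectralFTest(avg, f0Hz = cfg$detection$f0_hz,
                        K = cfg$detection$K, alpha = cfg$detection$alpha)
    clickSub <- stabilityTable(clickBuffers = bufs$click)  # click r only
    clickAvg <- .grandAverage(list(
      sub1 = .meanResponse(list(splitByCollection(bufs$click$A)$first),
                           pid, "click"),
      sub2 = .meanResponse(list(splitByCollection(bufs$click$B)$first),
                           pid, "click")))
    det[[pid]] <- data.frame(
      participant_id = pid,
      f_statistic = ft$f_statistic, p_value = ft$p_value,
      present = ft$present,
      prestim_rms_sabr = prestimRms(avg,
        prestimWindow(stimulusKind = "da40"))$rms_uv,
      prestim_rms_click = prestimRms(clickAvg,
        prestimWindow(stimulusKind = "click"))$rms_uv,
      stringsAsFactors = FALSE)
  }
  stability <- do.call(rbind, stab); rownames(stability) <- NULL
  detect <- do.call(rbind, det); rownames(detect) <- NULL

  vt <- validateTraits(traits, stability)
  fits <- fitModelSet(stability, vt$clean, trait = cfg$trait,
                      models = cfg$models)
  sel <- selectModel(fits)
  best <- fits[[sel$best]]
  contr <- componentContrasts(best)

  utils::write.csv(stability, file.path(outDir, "stability.csv"),
                   row.names = FALSE)
  utils::write.csv(traits, file.path(outDir, "traits.csv"),
                   row.names = FALSE)
  utils::write.csv(detect, file.path(outDir, "detect.csv"),
                   row.names = FALSE)
  utils::write.csv(sel$table, file.path(outDir, "model_comparison.csv"),
                   row.names = FALSE)
  utils::write.csv(best$coefficients, file.path(outDir, "coefficients.csv"),
                   row.names = FALSE)
  utils::write.csv(contr$contrasts, file.path(outDir, "contrasts.csv"),
                   row.names = FALSE)

  cfgJson <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  cfgFile <- file.path(outDir, "config.json")
  writeLines(cfgJson, cfgFile)
  manifest <- list(
    format_version = .FORMAT_VERSION,
    seed = seed,
    config_md5 = unname(tools::md5sum(cfgFile)),
    n_participants = nrow(traits),
    rows = list(stability = nrow(stability), traits = nrow(traits),
                detect = nrow(detect)),
    best_model = sel$best,
    converged = vapply(fits, `[[`, logical(1), "converged"),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("abrstab"))
  )
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(stability = stability, traits = traits, detect = detect,
                 fits = fits, selection = sel, contrasts = contr,
                 manifest = manifest, outDir = outDir))
}
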