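test_that("noiseless sweeps reproduce the template exactly", {
  buf <- simulateSweeps(clickTpl, nSweeps = 5, seed = 1)
  expect_equal(nSweeps(buf), 5L)
  dev <- sweep(sweepData(buf), 2, amplitude(clickTpl))
  expect_equal(max(abs(dev)), 0)
})

test_that("sweep simulation is bit-reproducible under a fixed seed", {
  nm <- noiseModel(noiseSd = 2, jitterSd = 0.1, ampCv = 0.1,
                   artifactRate = 0.1, polarityComponentAmp = 0.3)
  a <- simulateSweeps(daTpl, nm, 20, seed = 7)
  b <- simulateSweeps(daTpl, nm, 20, seed = 7)
  expect_identical(sweepData(a), sweepData(b))
  c <- simulateSweeps(daTpl, nm, 20, seed = 8)
  expect_false(identical(sweepData(a), sweepData(c)))
})

test_that("invalid simulation arguments fail loudly", {
  expect_error(simulateSweeps(clickTpl, nSweeps = 0, seed = 1), ">= 1")
  expect_error(simulateSweeps(clickTpl, nSweeps = 5, polarity = "up"),
               "polarity")
  expect_error(simulateSweeps(clickTpl, noiseModel(jitterSd = 100),
                              nSweeps = 2), "jitter")
  expect_error(noiseModel(artifactRate = 1.5), "artifactRate")
  expect_error(noiseModel(noiseSd = -1), "nonnegative")
})

test_that("expected stability decreases as noise and jitter grow", {
  w <- componentWindows("click")
  meanR <- function(nm, seeds) {
    vapply(seeds, function(s) {
      sub <- buildSubaverages(
        simulateSweeps(clickTpl, nm, 60, "A", "condensation", seed = s * 7 + 1),
        simulateSweeps(clickTpl, nm, 60, "A", "rarefaction", seed = s * 7 + 2),
        simulateSweeps(clickTpl, nm, 60, "B", "condensation", seed = s * 7 + 3),
        simulateSweeps(clickTpl, nm, 60, "B", "rarefaction", seed = s * 7 + 4))
      stabilityR(sub$sub1, sub$sub2, w)
    }, numeric(1))
  }
  seeds <- 1:100
  rLow <- meanR(noiseModel(noiseSd = 1), seeds)
  rMid <- meanR(noiseModel(noiseSd = 3), seeds)
  rHigh <- meanR(noiseModel(noiseSd = 9), seeds)
  expect_lt(stats::wilcox.test(rMid, rLow, alternative = "less")$p.value,
            0.01)
  expect_lt(stats::wilcox.test(rHigh, rMid, alternative = "less")$p.value,
            0.01)

  jLow <- meanR(noiseModel(noiseSd = 0.5, jitterSd = 0.02), seeds)
  jHigh <- meanR(noiseModel(noiseSd = 0.5, jitterSd = 0.6), seeds)
  expect_lt(stats::wilcox.test(jHigh, jLow, alternative = "less")$p.value,
            0.01)
})

test_that("degenerate cohorts collapse to the deterministic linear predictor", {
  spec <- cohortSpec(nParticipants = 6, betaTrait = 0, participantSd = 0,
                     residualSd = 0, seed = 3)
  coh <- simulateCohort(spec)
  perComp <- split(coh$stability$z, coh$stability$component)
  for (comp in names(perComp))
    expect_equal(diff(range(perComp[[comp]])), 0)
  expect_equal(coh$stability$r, tanh(coh$stability$z))
})

test_that("cohort generator recovers the injected trait slope by OLS at large n", {
  spec <- cohortSpec(nParticipants = 600,
                     componentOffsets = c(full_sabr = 0, onset = 0, ffr = 0,
                                          offset = 0, click = 0),
                     betaTrait = -0.023, participantSd = 0.1,
                     residualSd = 0.2, seed = 17)
  coh <- simulateCohort(spec)
  d <- merge(coh$stability, coh$traits[c("participant_id", "aq_total")],
             by = "participant_id")
  slope <- stats::coef(stats::lm(z ~ aq_total, d))[["aq_total"]]
  expect_lt(abs(slope - (-0.023)), 0.004)
})

test_that("effects-coded component estimates from cohort data sum to zero", {
  coh <- simulateCohort(cohortSpec(nParticipants = 30, seed = 5))
  d <- coh$stability
  d$component <- factor(d$component)
  fit <- stats::lm(z ~ component, d,
                   contrasts = list(component = "contr.sum"))
  est <- stats::coef(fit)[-1]
  expect_equal(sum(c(est, -sum(est))), 0)
})

test_that("trait tables are complete and internally consistent", {
  coh <- simulateCohort(cohortSpec(nParticipants = 50, seed = 9))
  tr <- coh$traits
  subCols <- grep("^aq_(attention|communication|social|imagination)",
                  names(tr), value = TRUE)
  expect_length(subCols, 5L)
  expect_equal(rowSums(tr[subCols]), tr$aq_total, ignore_attr = TRUE)
  expect_true(all(tr[subCols] <= 10 & tr[subCols] >= 0))
  expect_true(all(tr$aq_total >= 0 & tr$aq_total <= 50))
  expect_true(all(tr$group %in% c("autistic", "neurotypical")))
  expect_true(all(tr$aq_form %in% c("child", "adolescent", "adult_self")))
  ## SRS-2 correlates strongly with AQ by construction
  expect_gt(stats::cor(tr$aq_total, tr$srs2_t), 0.7)
})

test_that("cohortSpec enforces its invariants", {
  expect_error(cohortSpec(seed = 1,
                          componentOffsets = c(full_sabr = 1, onset = 0,
                                               ffr = 0, offset = 0,
                                               click = 0)), "sum to zero")
  expect_error(cohortSpec(nParticipants = 1, seed = 1), ">= 2")
  expect_error(cohortSpec(nParticipants = 10), "seed")
})
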