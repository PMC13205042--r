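cohBig <- simulateCohort(cohortSpec(nParticipants = 200, seed = 11))
fitsBig <- fitModelSet(cohBig$stability, cohBig$traits, trait = "AQ")

test_that("M1 recovers injected parameters within its own confidence bands", {
  m1 <- fitsBig$M1
  expect_true(m1$converged)
  co <- m1$coefficients
  aq <- co[co$term == "aq_total", ]
  expect_true(aq$ci_lo <= -0.023 && -0.023 <= aq$ci_hi)
  ic <- co[co$term == "(Intercept)", ]
  expect_true(ic$ci_lo <= 0.43 && 0.43 <= ic$ci_hi)
  ## sum-coded component estimates, including the implied click level
  expect_equal(sum(m1$componentEffects), 0, tolerance = 1e-10)
  expect_equal(unname(m1$componentEffects),
               c(-0.38, 0.24, -0.15, -0.47, 0.76), tolerance = 0.12)
  ## Satterthwaite df are finite and positive
  expect_true(all(is.finite(co$df) & co$df > 0))
})

test_that("the likelihood is invariant to factor coding", {
  d <- fitsBig$M1$data
  f <- z ~ component + aq_total + (1 | participant_id)
  sumFit <- lmerTest::lmer(f, d, REML = FALSE,
                           contrasts = list(component = "contr.sum"))
  trtFit <- lmerTest::lmer(f, d, REML = FALSE,
                           contrasts = list(component = "contr.treatment"))
  expect_equal(as.numeric(logLik(sumFit)), as.numeric(logLik(trtFit)),
               tolerance = 1e-8)
  expect_equal(BIC(sumFit), BIC(trtFit), tolerance = 1e-8)
})

test_that("BIC selection table is ordered with exactly one zero delta", {
  sel <- selectModel(fitsBig)
  expect_identical(sel$best, "M1")
  expect_equal(sum(sel$table$delta_bic == 0), 1L)
  expect_true(all(diff(sel$table$bic) >= 0))
  single <- selectModel(fitsBig["M1"])
  expect_equal(single$table$delta_bic, 0)
  ## differing observation sets are incomparable
  cohSmall <- simulateCohort(cohortSpec(nParticipants = 30, seed = 4))
  other <- fitModelSet(cohSmall$stability, cohSmall$traits, "AQ",
                       models = "M0")
  expect_error(selectModel(c(fitsBig["M1"], other)), "incomparable")
})

test_that("BIC selection is consistent under both generating models", {
  nullSel <- vapply(1:60, function(s) {
    coh <- simulateCohort(cohortSpec(nParticipants = 40, betaTrait = 0,
                                     seed = 1000 + s))
    selectModel(fitModelSet(coh$stability, coh$traits, "AQ",
                            models = c("M0", "M1", "M2")))$best
  }, character(1))
  expect_gte(mean(nullSel == "M0"), 0.6)

  strongSel <- vapply(1:40, function(s) {
    coh <- simulateCohort(cohortSpec(nParticipants = 60, betaTrait = -0.04,
                                     residualSd = 0.3, participantSd = 0.2,
                                     seed = 2000 + s))
    selectModel(fitModelSet(coh$stability, coh$traits, "AQ",
                            models = c("M0", "M1", "M2")))$best
  }, character(1))
  expect_gte(mean(strongSel != "M0"), 0.9)
})

test_that("Tukey contrasts separate a shifted component and respect adjustment", {
  coh <- simulateCohort(cohortSpec(
    nParticipants = 60,
    componentOffsets = c(full_sabr = -0.125, onset = -0.125, ffr = -0.125,
                         offset = -0.125, click = 0.5),
    betaTrait = 0, participantSd = 0.1, residualSd = 0.15, seed = 21))
  fit <- fitStabilityLmm("M0", coh$stability, coh$traits, "AQ")
  ct <- componentContrasts(fit)
  expect_equal(nrow(ct$contrasts), 10L)
  clickPairs <- grepl("click", ct$contrasts$pair)
  expect_true(all(ct$contrasts$p_adjusted[clickPairs] < 0.05))
  ## the six equal-offset pairs are null; allow at most one familywise slip
  expect_gte(sum(ct$contrasts$p_adjusted[!clickPairs] > 0.05), 5L)

  ## adjusted p never undercuts the unadjusted t probability
  punadj <- 2 * stats::pt(abs(ct$contrasts$t_ratio), ct$contrasts$df,
                          lower.tail = FALSE)
  expect_true(all(ct$contrasts$p_adjusted >= punadj - 1e-12))
})

test_that("with two components the Tukey adjustment reduces to the t-test", {
  coh <- simulateCohort(cohortSpec(nParticipants = 40, seed = 31))
  stab2 <- coh$stability[coh$stability$component %in% c("click", "onset"), ]
  fit <- fitStabilityLmm("M0", stab2, coh$traits, "AQ")
  ct <- componentContrasts(fit)$contrasts
  expect_equal(nrow(ct), 1L)
  pt2 <- 2 * stats::pt(abs(ct$t_ratio), ct$df, lower.tail = FALSE)
  expect_equal(ct$p_adjusted, pt2, tolerance = 1e-6)
})

test_that("null Tukey screens stay quiet at the family level", {
  anySig <- vapply(1:60, function(s) {
    coh <- simulateCohort(cohortSpec(
      nParticipants = 60,
      componentOffsets = c(full_sabr = 0, onset = 0, ffr = 0, offset = 0,
                           click = 0),
      betaTrait = 0, participantSd = 0.3, residualSd = 0.4,
      seed = 3000 + s))
    fit <- fitStabilityLmm("M0", coh$stability, coh$traits, "AQ")
    any(componentContrasts(fit)$contrasts$p_adjusted < 0.05)
  }, logical(1))
  expect_gte(mean(!anySig), 0.9)
})

test_that("variance-partition R2 matches the plug-in variance oracle", {
  spec <- cohortSpec(nParticipants = 1500, seed = 41)
  coh <- simulateCohort(spec)
  fit <- fitStabilityLmm("M1", coh$stability, coh$traits, "AQ")
  ## oracle: variance of the true fixed predictor over the realized design,
  ## plus the injected variance components
  d <- fit$data
  truth <- spec@componentOffsets[as.character(d$component)] +
    (-0.023) * d$aq_total
  vf <- stats::var(truth)
  vr <- 0.54^2; ve <- 0.64^2
  expect_lt(abs(fit$r2_marginal - vf / (vf + vr + ve)), 0.03)
  expect_lt(abs(fit$r2_conditional - (vf + vr) / (vf + vr + ve)), 0.03)
})

test_that("R2 collapses marginal onto conditional without random variance", {
  coh <- simulateCohort(cohortSpec(nParticipants = 50, participantSd = 0,
                                   seed = 51))
  fit <- suppressMessages(
    fitStabilityLmm("M1", coh$stability, coh$traits, "AQ"))
  expect_equal(fit$r2_marginal, fit$r2_conditional, tolerance = 1e-3)
})

test_that("delta R2 is zero for identical fits and guards nesting", {
  expect_equal(deltaR2(fitsBig$M1, fitsBig$M1), 0)
  expect_gt(deltaR2(fitsBig$M1, fitsBig$M0), 0)
  expect_error(deltaR2(fitsBig$M0, fitsBig$M1), "not nested")
})

test_that("subscale likelihood-ratio tests are calibrated under the null", {
  lrIdent <- subscaleLrt(fitsBig$M1, fitsBig$M1)
  expect_equal(lrIdent$chi2, 0)
  expect_equal(lrIdent$p_value, 1)

  ## under the null neither the total nor the subscale carries any effect
  chis <- vapply(1:150, function(s) {
    coh <- simulateCohort(cohortSpec(nParticipants = 100, betaTrait = 0,
                                     seed = 4000 + s))
    aqSubscaleLrt(coh$stability, coh$traits, "imagination")$chi2
  }, numeric(1))
  ks <- stats::ks.test(chis, stats::pchisq, df = 1)
  expect_gt(ks$p.value, 0.01)
})

test_that("an injected subscale effect is detected with high power", {
  hits <- vapply(1:40, function(s) {
    coh <- simulateCohort(cohortSpec(nParticipants = 80,
                                     betaSubscale = 0.25,
                                     subscaleName = "communication",
                                     residualSd = 0.4,
                                     seed = 5000 + s))
    aqSubscaleLrt(coh$stability, coh$traits, "communication")$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("model fitting enforces its preconditions", {
  coh <- simulateCohort(cohortSpec(nParticipants = 10, seed = 61))
  one <- coh$stability[coh$stability$participant_id == "P001", ]
  expect_error(fitStabilityLmm("M1", one, coh$traits, "AQ"),
               ">= 2 participants")
  expect_error(aqSubscaleLrt(coh$stability, coh$traits, "empathy"),
               "aq_empathy")
  bad <- coh$stability
  bad$component[1] <- "sustained"
  expect_error(fitStabilityLmm("M1", bad, coh$traits, "AQ"), "unknown")
})
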