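.COMPONENT_LEVELS <- c("full_sabr", "onset", "ffr", "offset", "click")

.MODEL_TERMS <- list(
  M0 = "component",
  M1 = "component + trait",
  M2 = "component * trait",
  M3 = "component * trait + age + vci"
)

.traitColumn <- function(trait) switch(trait, AQ = "aq_total",
                                       SRS2 = "srs2_t",
                                       stop("unknown trait: ", trait))

.assembleModelData <- function(stability, traits, needed) {
  stopifnot(all(c("participant_id", "component", "z") %in% names(stability)))
  d <- merge(stability[c("participant_id", "component", "z")], traits,
             by = "participant_id")
  d$component <- factor(d$component, levels = .COMPONENT_LEVELS)
  if (anyNA(d$component)) stop("unknown component labels in stability table")
  d$component <- droplevels(d$component)
  d <- d[stats::complete.cases(d[needed]), , drop = FALSE]
  d <- d[order(d$participant_id, as.integer(d$component)), , drop = FALSE]
  rownames(d) <- NULL
  d
}

.lmmFit <- function(formula, data, label = "custom") {
  fit <- lmerTest::lmer(formula, data = data, REML = FALSE,
                        contrasts = list(component = "contr.sum"))
  sm <- summary(fit)$coefficients
  coefs <- data.frame(
    term = rownames(sm), estimate = sm[, "Estimate"],
    se = sm[, "Std. Error"], df = sm[, "df"], t = sm[, "t value"],
    p = sm[, "Pr(>|t|)"],
    ci_lo = sm[, "Estimate"] - stats::qt(0.975, sm[, "df"]) * sm[, "Std. Error"],
    ci_hi = sm[, "Estimate"] + stats::qt(0.975, sm[, "df"]) * sm[, "Std. Error"],
    row.names = NULL, stringsAsFactors = FALSE)

  compRows <- grepl("^component[0-9]+$", coefs$term)
  compEff <- NULL
  if (any(compRows)) {
    est <- coefs$estimate[compRows]
    lev <- levels(data$component)
    compEff <- c(est, -sum(est))
    names(compEff) <- lev
  }

  ll <- stats::logLik(fit)
  r2 <- r2Nakagawa(fit)
  msgs <- fit@optinfo$conv$lme4$messages
  structure(list(
    model = label, formula = formula, fit = fit, coefficients = coefs,
    componentEffects = compEff, loglik = as.numeric(ll),
    df_params = attr(ll, "df"), bic = stats::BIC(fit),
    n_obs = nrow(data), n_participants = length(unique(data$participant_id)),
    r2_marginal = r2[["r2_marginal"]], r2_conditional = r2[["r2_conditional"]],
    converged = is.null(msgs) || length(msgs) == 0L,
    obs_keys = paste(data$participant_id, data$component, sep = ":"),
    data = data), class = "abrModelFit")
}

#' Fit one of the nested stability mixed models
#'
#' The candidate set, fit with maximum likelihood (never REML, so BIC and
#' likelihood-ratio comparisons are valid) and a participant random
#' intercept:
#' \describe{
#'   \item{M0}{z ~ component + (1 | participant)}
#'   \item{M1}{z ~ component + trait + (1 | participant)}
#'   \item{M2}{z ~ component * trait + (1 | participant)}
#'   \item{M3}{z ~ component * trait + age + vci + (1 | participant)}
#' }
#' Components enter sum-coded (effects coding): the reported component
#' estimates are deviations from the grand mean and, together with the
#' implied estimate of the omitted (click) level, sum to zero.  Fixed-effect
#' t-tests use Satterthwaite degrees of freedom; 95% CIs are Wald intervals
#' on those df.  Non-convergence is flagged in the result, never silent.
#'
#' @param model \code{"M0"}, \code{"M1"}, \code{"M2"} or \code{"M3"}.
#' @param stability Long table with \code{participant_id}, \code{component},
#'   \code{z} (missing components are simply absent rows).
#' @param traits Trait table with \code{participant_id} and the trait
#'   columns.
#' @param trait \code{"AQ"} (uses \code{aq_total}) or \code{"SRS2"}
#'   (\code{srs2_t}).
#' @param data Optional pre-assembled model data (used by [fitModelSet()] to
#'   keep the observation set identical across models).
#' @return An \code{abrModelFit}: list with \code{coefficients} (term,
#'   estimate, se, Satterthwaite df, t, p, 95% CI), \code{componentEffects}
#'   (all five sum-coded deviations), \code{loglik}, \code{bic},
#'   \code{r2_marginal}, \code{r2_conditional}, \code{n_obs},
#'   \code{n_participants}, \code{converged}, and the fitted
#'   \code{lmerModLmerTest} in \code{$fit}.
#' @export
fitStabilityLmm <- function(model = c("M1", "M0", "M2", "M3"),
                            stability, traits, trait = c("AQ", "SRS2"),
                            data = NULL) {
  model <- match.arg(model)
  trait <- match.arg(trait)
  tcol <- .traitColumn(trait)
  if (is.null(data)) {
    needed <- switch(model, M0 = c("component", "z"),
                     M1 = , M2 = c("component", "z", tcol),
                     M3 = c("component", "z", tcol, "age", "vci"))
    data <- .assembleModelData(stability, traits, needed)
  }
  if (length(unique(data$participant_id)) < 2L)
    stop("need >= 2 participants")
  rhs <- sub("trait", tcol, .MODEL_TERMS[[model]], fixed = TRUE)
  f <- stats::as.formula(paste("z ~", rhs, "+ (1 | participant_id)"))
  .lmmFit(f, data, label = model)
}

#' Fit the full nested model set on a common observation set
#'
#' Subsets once to the observations complete for every covariate used by the
#' richest requested model, so the BICs of all fits are computed on
#' identical data and are comparable.
#'
#' @inheritParams fitStabilityLmm
#' @param models Which of M0-M3 to fit.
#' @return Named list of \code{abrModelFit} objects.
#' @export
fitModelSet <- function(stability, traits, trait = c("AQ", "SRS2"),
                        models = c("M0", "M1", "M2", "M3")) {
  trait <- match.arg(trait)
  tcol <- .traitColumn(trait)
  needed <- c("component", "z", tcol)
  if ("M3" %in% models) needed <- c(needed, "age", "vci")
  data <- .assembleModelData(stability, traits, needed)
  fits <- lapply(models, function(m)
    fitStabilityLmm(m, stability, traits, trait, data = data))
  names(fits) <- models
  fits
}

#' BIC model selection
#'
#' @param fits Named list of \code{abrModelFit} objects fit on identical
#'   observation sets (enforced; BIC is incomparable otherwise).
#' @return A list: \code{best} (name of the minimum-BIC model) and
#'   \code{table}, a \code{data.frame} (model, bic, delta_bic) sorted by
#'   BIC with exactly one zero delta.
#' @export
selectModel <- function(fits) {
  stopifnot(length(fits) >= 1L)
  keys <- lapply(fits, `[[`, "obs_keys")
  if (length(fits) > 1L &&
      !all(vapply(keys[-1], identical, logical(1), keys[[1]])))
    stop("fits were computed on differing observation sets; BIC incomparable")
  bic <- vapply(fits, `[[`, numeric(1), "bic")
  tab <- data.frame(model = names(fits), bic = unname(bic),
                    delta_bic = unname(bic - min(bic)),
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$bic), , drop = FALSE]
  rownames(tab) <- NULL
  list(best = tab$model[1], table = tab)
}

#' Tukey-adjusted pairwise component contrasts
#'
#' Estimated marginal means of the component factor and all pairwise
#' comparisons, adjusted with the studentized-range (Tukey) method on
#' Satterthwaite degrees of freedom.  Adjusted p-values are never below the
#' unadjusted ones.
#'
#' @param fit An \code{abrModelFit} whose model retains \code{component}.
#' @return A list: \code{emmeans} (component means data.frame) and
#'   \code{contrasts} (pair, estimate, se, df, t_ratio, p_adjusted).
#' @export
componentContrasts <- function(fit) {
  stopifnot(inherits(fit, "abrModelFit"))
  if (!"component" %in% all.vars(fit$formula))
    stop("component is not a term in this model")
  em <- emmeans::emmeans(fit$fit, ~ component, lmer.df = "satterthwaite",
                         data = fit$data)
  ct <- summary(emmeans::contrast(em, method = "pairwise", adjust = "tukey"))
  list(
    emmeans = as.data.frame(summary(em)),
    contrasts = data.frame(pair = as.character(ct$contrast),
                           estimate = ct$estimate, se = ct$SE, df = ct$df,
                           t_ratio = ct$t.ratio, p_adjusted = ct$p.value,
                           stringsAsFactors = FALSE))
}

#' Marginal and conditional R-squared for a random-intercept LMM
#'
#' Variance-partition R-squared: the fixed-effects variance is the variance
#' of the linear predictor from the fixed effects alone; the marginal R2
#' divides it by the total (fixed + random-intercept + residual), and the
#' conditional R2 adds the random-intercept variance to the numerator.
#'
#' @param fit An \code{abrModelFit} or \code{merMod}.
#' @return Named numeric: \code{r2_marginal}, \code{r2_conditional}.
#' @export
r2Nakagawa <- function(fit) {
  m <- if (inherits(fit, "abrModelFit")) fit$fit else fit
  stopifnot(inherits(m, "merMod"))
  pred <- as.vector(lme4::getME(m, "X") %*% lme4::fixef(m))
  vf <- stats::var(pred)
  vc <- lme4::VarCorr(m)
  vr <- sum(vapply(vc, function(v) sum(diag(v)), numeric(1)))
  ve <- attr(vc, "sc")^2
  tot <- vf + vr + ve
  c(r2_marginal = vf / tot, r2_conditional = (vf + vr) / tot)
}

#' Incremental variance explained by a predictor
#'
#' Difference in marginal R-squared between two nested fits on identical
#' observations (e.g. the trait's unique contribution beyond the component
#' effects).
#'
#' @param fitWith,fitWithout Nested \code{abrModelFit}s (same observations;
#'   the fixed terms of \code{fitWithout} must be a subset).
#' @return Numeric delta R-squared (marginal).
#' @export
deltaR2 <- function(fitWith, fitWithout) {
  stopifnot(inherits(fitWith, "abrModelFit"),
            inherits(fitWithout, "abrModelFit"))
  if (!identical(fitWith$obs_keys, fitWithout$obs_keys))
    stop("fits use different observation sets")
  tw <- attr(stats::terms(fitWith$formula), "term.labels")
  to <- attr(stats::terms(fitWithout$formula), "term.labels")
  if (!all(to %in% tw))
    stop("models are not nested")
  fitWith$r2_marginal - fitWithout$r2_marginal
}

#' Likelihood-ratio test between nested ML fits
#'
#' chi-squared = 2 * (logLik full - logLik reduced) on the difference in
#' parameter counts.  A reduced log-likelihood exceeding the full one beyond
#' numerical tolerance indicates a failed fit and is an error, not a silent
#' negative statistic.
#'
#' @param fitFull,fitReduced Nested \code{abrModelFit}s fit by ML on the
#'   same observations.
#' @return A list: \code{chi2}, \code{df}, \code{p_value}.
#' @export
subscaleLrt <- function(fitFull, fitReduced) {
  stopifnot(inherits(fitFull, "abrModelFit"),
            inherits(fitReduced, "abrModelFit"))
  if (!identical(fitFull$obs_keys, fitReduced$obs_keys))
    stop("fits use different observation sets")
  chi2 <- 2 * (fitFull$loglik - fitReduced$loglik)
  df <- fitFull$df_params - fitReduced$df_params
  if (chi2 < -1e-6)
    stop("reduced model log-likelihood exceeds the full model's; refit")
  chi2 <- max(0, chi2)
  p <- if (df > 0) stats::pchisq(chi2, df, lower.tail = FALSE) else 1
  list(chi2 = chi2, df = df, p_value = p)
}

#' AQ-subscale likelihood-ratio test
#'
#' Tests whether one AQ subscale explains stability beyond the total score:
#' the reduced model uses component + (AQ total minus the subscale); the
#' full model adds the subscale as a separate predictor.  Both are ML fits
#' with a participant random intercept on the same observations.
#'
#' @param stability,traits As in [fitStabilityLmm()]; \code{traits} must
#'   carry the \code{aq_<subscale>} column.
#' @param subscale One of \code{"attention_switching"},
#'   \code{"attention_to_detail"}, \code{"communication"},
#'   \code{"social_skills"}, \code{"imagination"}.
#' @return As [subscaleLrt()], plus \code{subscale} and the two fits.
#' @export
aqSubscaleLrt <- function(stability, traits, subscale) {
  scol <- paste0("aq_", subscale)
  if (!scol %in% names(traits))
    stop("traits table lacks column ", scol)
  traits$aq_rest <- traits$aq_total - traits[[scol]]
  data <- .assembleModelData(stability, traits,
                             c("component", "z", "aq_rest", scol))
  fr <- .lmmFit(stats::as.formula(
    "z ~ component + aq_rest + (1 | participant_id)"), data,
    label = "reduced")
  ff <- .lmmFit(stats::as.formula(
    paste("z ~ component + aq_rest +", scol, "+ (1 | participant_id)")),
    data, label = "full")
  out <- subscaleLrt(ff, fr)
  out$subscale <- subscale
  out$fit_full <- ff
  out$fit_reduced <- fr
  out
}

#' @export
print.abrModelFit <- function(x, ...) {
  cat(sprintf(
    "Stability LMM %s: %s\n  n_obs = %d, participants = %d%s\n",
    x$model, deparse(x$formula), x$n_obs, x$n_participants,
    if (x$converged) "" else "  [NOT CONVERGED]"))
  cat(sprintf("  logLik(ML) = %.2f, BIC = %.2f, R2m = %.3f, R2c = %.3f\n",
              x$loglik, x$bic, x$r2_marginal, x$r2_conditional))
  print(x$coefficients, digits = 3)
  invisible(x)
}
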