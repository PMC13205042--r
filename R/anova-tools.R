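## Mauchly W -> chi-squared approximation (standard large-sample form).
.mauchlyChi2 <- function(W, nSubjects, k) {
  dfEffect <- k - 1
  f <- (2 * dfEffect^2 + dfEffect + 2) / (6 * dfEffect)
  chi2 <- -(nSubjects - 1 - f) * log(W)
  df <- k * (k - 1) / 2 - 1
  c(chi2 = chi2, df = df)
}

#' Repeated-measures ANOVA with sphericity check and GG correction
#'
#' Within-subject ANOVA for one or two crossed repeated factors (complete
#' design required).  For each within effect with more than two levels,
#' Mauchly's test of sphericity is run; when it rejects at the 0.05 level
#' the Greenhouse-Geisser epsilon is applied to the degrees of freedom and
#' the corrected p-value is reported.  Two-level factors satisfy sphericity
#' trivially (epsilon = 1 exactly).  Computation is delegated to
#' \code{car::Anova} on a multivariate linear model.
#'
#' @param data Long \code{data.frame}.
#' @param dv Name of the numeric response column.
#' @param subject Name of the subject-id column.
#' @param within Character vector of one or two within-subject factor
#'   columns.
#' @param ggAlpha Mauchly level that triggers the correction (default 0.05).
#' @return A \code{data.frame}, one row per within effect: \code{effect},
#'   \code{F}, \code{df1}, \code{df2}, \code{p} (uncorrected),
#'   \code{mauchly_w}, \code{mauchly_chi2}, \code{mauchly_df},
#'   \code{mauchly_p}, \code{gg_epsilon}, \code{corrected},
#'   \code{df1_corrected}, \code{df2_corrected}, \code{p_corrected}.
#' @export
rmanovaGG <- function(data, dv, subject, within, ggAlpha = 0.05) {
  stopifnot(is.data.frame(data), length(within) %in% 1:2,
            all(c(dv, subject, within) %in% names(data)))
  for (w in within) data[[w]] <- factor(data[[w]])
  data[[subject]] <- factor(data[[subject]])

  cells <- interaction(data[within], drop = FALSE, sep = ".")
  tab <- table(data[[subject]], cells)
  if (any(tab != 1L))
    stop("incomplete or duplicated cells: every subject needs exactly one ",
         "observation per factor combination")

  subj <- levels(data[[subject]])
  cellLevels <- levels(cells)
  Y <- matrix(NA_real_, nrow = length(subj), ncol = length(cellLevels),
              dimnames = list(subj, cellLevels))
  Y[cbind(as.character(data[[subject]]), as.character(cells))] <- data[[dv]]

  idata <- unique(data[within])
  idata <- idata[order(interaction(idata, sep = ".")), , drop = FALSE]
  Y <- Y[, as.character(interaction(idata, sep = ".")), drop = FALSE]
  rownames(idata) <- NULL
  for (w in within) idata[[w]] <- factor(idata[[w]])

  mlm <- stats::lm(Y ~ 1)
  idesign <- stats::as.formula(paste("~", paste(within, collapse = "*")))
  av <- car::Anova(mlm, idata = idata, idesign = idesign, type = 3)
  s <- suppressWarnings(summary(av, multivariate = FALSE))
  uni <- s$univariate.tests
  sph <- s$sphericity.tests
  adj <- s$pval.adjustments

  effects <- setdiff(rownames(uni), "(Intercept)")
  nSubj <- nrow(Y)
  out <- do.call(rbind, lapply(effects, function(e) {
    df1 <- uni[e, "num Df"]; df2 <- uni[e, "den Df"]
    Fv <- uni[e, "F value"]; p <- uni[e, "Pr(>F)"]
    k <- df1 + 1
    if (!is.null(sph) && e %in% rownames(sph)) {
      W <- sph[e, "Test statistic"]
      mp <- sph[e, "p-value"]
      mc <- .mauchlyChi2(W, nSubj, k)
      eps <- adj[e, "GG eps"]
      pgg <- adj[e, "Pr(>F[GG])"]
    } else {                               # 2-level effect: sphericity holds
      W <- NA_real_; mp <- NA_real_
      mc <- c(chi2 = NA_real_, df = NA_real_)
      eps <- 1; pgg <- p
    }
    corrected <- !is.na(mp) && mp < ggAlpha
    data.frame(effect = e, F = Fv, df1 = df1, df2 = df2, p = p,
               mauchly_w = W, mauchly_chi2 = unname(mc["chi2"]),
               mauchly_df = unname(mc["df"]), mauchly_p = mp,
               gg_epsilon = eps, corrected = corrected,
               df1_corrected = df1 * eps, df2_corrected = df2 * eps,
               p_corrected = if (corrected) pgg else p,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  out
}

#' Variance inflation factors
#'
#' For each predictor column, \code{VIF_j = 1 / (1 - R2_j)} where
#' \code{R2_j} is from regressing predictor j on all others (with
#' intercept).  Exact collinearity is reported as \code{Inf}, not an error.
#'
#' @param X \code{data.frame} or matrix of at least two numeric predictor
#'   columns.
#' @return Named numeric vector of VIFs.
#' @examples
#' designVif(data.frame(a = rnorm(20), b = rnorm(20)))
#' @export
designVif <- function(X) {
  X <- as.data.frame(X)
  if (ncol(X) < 2L) stop("need >= 2 predictors")
  if (!all(vapply(X, is.numeric, logical(1))))
    stop("predictors must be numeric")
  vif <- vapply(seq_along(X), function(j) {
    ## exact collinearity makes summary() warn about a perfect fit; that
    ## case is the Inf branch below, so the warning carries no information
    r2 <- suppressWarnings(
      summary(stats::lm(X[[j]] ~ ., data = X[-j]))$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(vif) <- names(X)
  vif
}

#' Welch two-sample t-test
#'
#' Unequal-variance t-test with Welch-Satterthwaite degrees of freedom,
#' two-sided.
#'
#' @param groupA,groupB Numeric vectors (n >= 2 each).
#' @return A list: \code{t}, \code{df}, \code{p_value}, \code{mean_diff}.
#' @export
welchT <- function(groupA, groupB) {
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("need n >= 2 per group")
  if (stats::sd(groupA) == 0 && stats::sd(groupB) == 0) {
    if (mean(groupA) == mean(groupB))
      return(list(t = 0, df = NA_real_, p_value = 1,
                  mean_diff = 0))
    stop("zero variance in both groups")
  }
  ht <- stats::t.test(groupA, groupB, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value,
       mean_diff = unname(diff(rev(ht$estimate))))
}

#' Pearson correlation test
#'
#' @param x,y Numeric vectors of equal length (n >= 3 complete pairs).
#' @return A list: \code{r}, \code{p_value}, \code{n}.
#' @export
corrTest <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  if (sum(ok) < 3L) stop("need >= 3 complete pairs")
  ht <- stats::cor.test(x[ok], y[ok])
  list(r = unname(ht$estimate), p_value = ht$p.value, n = sum(ok))
}
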