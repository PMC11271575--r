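#' Residualized R-squared of a PRS
#'
#' Regresses the phenotype on the covariates (with intercept), then returns
#' the squared Pearson correlation between the residuals and the score — the
#' standard covariate-adjusted measure of PRS accuracy for continuous traits.
#'
#' @param phenotype numeric outcome.
#' @param covariates data frame / matrix of covariates, or `NULL`.
#' @param score PRS values.
#' @return R-squared in `[0, 1]`; 0 (with a warning) for a constant score.
#' @export
residualized_r2 <- function(phenotype, covariates, score) {
  n <- length(phenotype)
  if (n < 3) stop("residualized_r2: need at least 3 samples")
  resid <- if (is.null(covariates) || NCOL(covariates) == 0) {
    phenotype - mean(phenotype)
  } else {
    residuals(lm.fit(cbind(1, as.matrix(covariates)), phenotype))
  }
  if (sd(score) < 1e-12) {
    warning("residualized_r2: zero-variance score; R2 defined as 0")
    return(0)
  }
  cor(resid, score)^2
}

#' Empirical AUC (Mann-Whitney estimator)
#'
#' Probability that a random case scores above a random control, ties counted
#' one half.
#'
#' @param labels 0/1 (or two-level) outcome.
#' @param score PRS values.
#' @return AUC in `[0, 1]`.
#' @export
empirical_auc <- function(labels, score) {
  y <- as.numeric(as.factor(labels))
  if (length(unique(y)) != 2)
    stop("empirical_auc: both classes must be present")
  case <- y == max(y)
  n1 <- sum(case); n0 <- sum(!case)
  ranks <- rank(score, ties.method = "average")
  (sum(ranks[case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Logit-scale variance from an AUC
#'
#' Implements the printed conversion `sigma^2 = 2 * qnorm(AUC)` used to put
#' binary-trait PRS accuracies on a variance scale; the standard
#' liability-scale relation squares the quantile, `sigma^2 = 2 * qnorm(AUC)^2`,
#' and is selectable with `squared = TRUE`.
#'
#' @param auc AUC in `[0.5, 1)`.
#' @param squared use the squared-quantile form? Default `FALSE`.
#' @return Non-negative variance; monotone in AUC.
#' @export
logit_variance_from_auc <- function(auc, squared = FALSE) {
  if (any(auc < 0.5) || any(auc >= 1))
    stop("logit_variance_from_auc: auc must be in [0.5, 1)")
  q <- qnorm(auc)
  if (squared) 2 * q^2 else 2 * q
}

#' Relative improvement of one accuracy over another
#'
#' `(value_a - value_b) / value_b`, e.g. 0.269 for a 26.9% gain.
#'
#' @param value_a,value_b accuracies (e.g. R-squared); `value_b` must be
#'   positive.
#' @return Signed fraction.
#' @export
relative_improvement <- function(value_a, value_b) {
  if (any(value_b <= 0)) stop("relative_improvement: baseline must be > 0")
  (value_a - value_b) / value_b
}
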