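# Model-adequacy indices. Canonical definitions:
#   RMSEA = sqrt(max(0, (chi2 - df) / (df * (n - 1))))        (0 when df = 0)
#   CFI   = 1 - max(chi2 - df, 0) / max(chi2_b - df_b, chi2 - df, 0)
#   TLI   = ((chi2_b/df_b) - (chi2/df)) / ((chi2_b/df_b) - 1)
#   SRMR  = rms of standardized covariance residuals, lower triangle including
#           the diagonal, standardized by the sample SDs (means excluded).
# Under missing data the "sample" moments for SRMR are the saturated-model
# (EM) estimates, so SRMR remains defined.

#' Fit indices from chi-square statistics and moment residuals
#'
#' @param chi2,df likelihood-ratio statistic and degrees of freedom of the
#'   substantive model.
#' @param chi2B,dfB the same for the independence baseline model.
#' @param n number of cases used.
#' @param Ssample sample (or saturated-estimate) covariance of the observed
#'   variables.
#' @param SigmaHat model-implied covariance.
#' @return list with `rmsea`, `cfi`, `tli`, `srmr`.
#' @export
fitIndices <- function(chi2, df, chi2B, dfB, n, Ssample, SigmaHat) {
  if (df < 0) stop("df must be nonnegative")
  if (n < 2) stop("n must be at least 2")
  if (df == 0 && chi2 > 1e-4) stop("inconsistent inputs: chi2 > 0 with df = 0")
  rmsea <- if (df == 0) 0 else sqrt(max(0, (chi2 - df) / (df * (n - 1))))
  num <- max(chi2 - df, 0)
  den <- max(chi2B - dfB, chi2 - df, 0)
  cfi <- if (den == 0) 1 else 1 - num / den
  tli <- if (df == 0 || is.na(dfB) || dfB == 0) NA_real_ else {
    rb <- chi2B / dfB
    if (abs(rb - 1) < 1e-12) NA_real_ else (rb - chi2 / df) / (rb - 1)
  }
  srmr <- NA_real_
  if (!is.null(Ssample) && !is.null(SigmaHat)) {
    sds <- sqrt(pmax(diag(Ssample), 0))
    denom <- outer(sds, sds)
    res <- (Ssample - SigmaHat) / denom
    lt <- res[lower.tri(res, diag = TRUE)]
    srmr <- sqrt(mean(lt^2))
  }
  list(rmsea = rmsea, cfi = cfi, tli = tli, srmr = srmr)
}

#' Fit the independence baseline model by FIML
#'
#' Free means and variances, all covariances fixed at zero. Under missingness
#' the independence likelihood factorizes, so per-variable ML on the available
#' cases is the exact FIML solution. The chi-square is computed against the
#' saturated (EM) model on the same cases.
#'
#' @param data data.frame or matrix.
#' @param variables which columns to use (default: all).
#' @return list with `chi2B`, `dfB`, `loglikB`, `loglikSat`, `nUsed`.
#' @export
fitBaseline <- function(data, variables = colnames(data)) {
  X <- as.matrix(as.data.frame(data)[, variables, drop = FALSE])
  storage.mode(X) <- "double"
  p <- ncol(X)
  sat <- emSaturated(X)
  base <- baselineLogLik(X)
  chi2B <- max(0, 2 * (sat$loglik - base$loglik))
  dfB <- p * (p + 3) / 2 - base$npar
  list(chi2B = chi2B, dfB = dfB, loglikB = base$loglik,
       loglikSat = sat$loglik, nUsed = sat$nUsed)
}
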