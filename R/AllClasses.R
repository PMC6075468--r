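#' Path-model (RAM) specification
#'
#' A structural equation model in RAM form. `A` holds directed paths
#' (regressions and loadings, row = head, column = tail), `S` symmetric
#' (co)variances, `M` means/intercepts. Numeric matrices carry the fixed
#' values (and current values for free entries); the parallel label matrices
#' mark free parameters — a non-`NA` label means the entry is estimated, and
#' shared labels impose equality constraints. `observed` selects the manifest
#' variables (the RAM filter).
#'
#' @slot variables character, all variable names (observed then latent).
#' @slot observed character, names of manifest variables.
#' @slot A,S numeric square matrices over `variables`.
#' @slot M numeric vector of means/intercepts.
#' @slot Alab,Slab character matrices of free-parameter labels (`NA` = fixed).
#' @slot Mlab character vector of labels for `M`.
#' @slot meta list of builder metadata; `meta$report` names the reserved
#'   association labels (e.g. cross-sectional and longitudinal covariances).
#' @export
setClass("SemModel",
  representation(
    variables = "character",
    observed  = "character",
    A = "matrix", S = "matrix", M = "numeric",
    Alab = "matrix", Slab = "matrix", Mlab = "character",
    meta = "list"
  )
)

setValidity("SemModel", function(object) {
  v <- object@variables
  n <- length(v)
  msgs <- character(0)
  if (anyDuplicated(v)) msgs <- c(msgs, "duplicate variable names")
  for (nm in c("A", "S", "Alab", "Slab")) {
    m <- slot(object, nm)
    if (!all(dim(m) == c(n, n))) msgs <- c(msgs, sprintf("%s must be %d x %d", nm, n, n))
  }
  if (length(object@M) != n) msgs <- c(msgs, "M length mismatch")
  if (length(object@Mlab) != n) msgs <- c(msgs, "Mlab length mismatch")
  if (!all(object@observed %in% v)) msgs <- c(msgs, "observed not a subset of variables")
  if (length(msgs) == 0 && !isTRUE(all.equal(object@S, t(object@S)))) {
    msgs <- c(msgs, "S must be symmetric")
  }
  if (length(msgs) == 0 && !identical(object@Slab, t(object@Slab))) {
    msgs <- c(msgs, "Slab must be symmetric")
  }
  if (length(msgs)) msgs else TRUE
})

#' Fitted path model
#'
#' Result of [semFit()]: point estimates of the free parameters, observed-
#' information standard errors, log-likelihoods of the fitted, saturated and
#' independence models on the same cases, the likelihood-ratio chi-square with
#' fit indices, and the standardized solution.
#'
#' @slot model the [SemModel-class] with estimates written into its matrices.
#' @slot estimates,se named numeric vectors over free-parameter labels.
#' @slot vcov parameter covariance matrix (inverse observed information).
#' @slot loglik,loglikSat,loglikBase model/saturated/independence
#'   log-likelihoods.
#' @slot nUsed,nPatterns,npar,nIterations integers.
#' @slot chi2,df,pChi2,chi2Base,dfBase,rmsea,cfi,tli,srmr fit statistics.
#' @slot converged logical.
#' @slot standardized data.frame of per-location standardized estimates.
#' @slot warnings character.
#' @export
setClass("SemFit",
  representation(
    model = "SemModel",
    estimates = "numeric", se = "numeric", vcov = "matrix",
    loglik = "numeric", loglikSat = "numeric", loglikBase = "numeric",
    nUsed = "integer", nPatterns = "integer", npar = "integer",
    chi2 = "numeric", df = "numeric", pChi2 = "numeric",
    chi2Base = "numeric", dfBase = "numeric",
    rmsea = "numeric", cfi = "numeric", tli = "numeric", srmr = "numeric",
    converged = "logical", nIterations = "integer",
    standardized = "data.frame",
    warnings = "character"
  )
)

# Latent construct bookkeeping: six constructs, each with a level and a
# change component, in a fixed order shared by the generator and calibration.
lcsConstructs <- function() c("s100b", "gfa", "gmd", "wmh", "tb", "gm")

latentNames <- function() {
  as.vector(t(outer(lcsConstructs(), c("lvl", "chg"), paste, sep = "_")))
}

#' Synthetic cohort generator configuration
#'
#' Full parameterization of the two-wave synthetic cohort: joint-normal latent
#' level/change structure for six constructs (serum S100B, general FA and MD
#' factors, log-WMH, total brain and gray matter volume), tract measurement
#' models, covariate distributions and effects, intracranial volume,
#' perivascular-space change rating probabilities, missingness and artifact
#' injection settings. Build with [GeneratorConfig()] or
#' [defaultGeneratorConfig()].
#'
#' @slot nParticipants number of participants to generate.
#' @slot seed base RNG seed (missingness/artifact stages use seed+1, seed+2).
#' @slot latentMeans,latentCov mean vector and covariance of the 12 latent
#'   level/change components (order: construct-major, level then change).
#' @slot tracts per-tract measurement parameters for `fa` and `md`:
#'   `loading`, `intercept`, `residual_var`, `cross_wave_residual_cov`.
#' @slot hemisphereCor correlation of left/right residuals of bilateral tracts.
#' @slot covariateEffects centered covariate effects on manifests:
#'   `serum = c(age, sex)` and per-construct MRI vectors
#'   `c(age, sex, diabetes, hypertension)`.
#' @slot covariateDists age means/SDs per wave, wave lag, serum-to-scan lag
#'   (days), sex proportion, diabetes/hypertension prevalence.
#' @slot exclusionDists MMSE distribution and low-score/dementia/melanoma
#'   rates (exercises the exclusion rules).
#' @slot icvMean,icvSd intracranial volume distribution (cm^3).
#' @slot pvsProbs probabilities of perivascular-space change ratings -2..+2.
#' @slot pvsCoupling correlation of the PVS rating's latent propensity with
#'   the standardized latent serum change (0 = independent).
#' @slot missingness `attrition_intercept`, `attrition_slope_on_gm` (logit
#'   scale), `scan_missing_rate`.
#' @slot artifacts `outlier_rate`, `outlier_magnitude_sd`, `floor_rate`.
#' @export
setClass("GeneratorConfig",
  representation(
    nParticipants = "integer", seed = "integer",
    latentMeans = "numeric", latentCov = "matrix",
    tracts = "list", hemisphereCor = "numeric",
    covariateEffects = "list", covariateDists = "list",
    exclusionDists = "list",
    icvMean = "numeric", icvSd = "numeric",
    pvsProbs = "numeric", pvsCoupling = "numeric",
    missingness = "list", artifacts = "list"
  )
)

setValidity("GeneratorConfig", function(object) {
  msgs <- character(0)
  ln <- latentNames()
  if (object@nParticipants < 0L) msgs <- c(msgs, "nParticipants must be >= 0")
  if (!identical(names(object@latentMeans), ln)) {
    msgs <- c(msgs, "latentMeans must be named by the 12 latent components")
  }
  lc <- object@latentCov
  if (!all(dim(lc) == c(12L, 12L))) {
    msgs <- c(msgs, "latentCov must be 12 x 12")
  } else {
    if (!isTRUE(all.equal(lc, t(lc)))) msgs <- c(msgs, "latentCov must be symmetric")
    else if (!isPsd(lc)) {
      msgs <- c(msgs, "latentCov (cross-construct covariance) is not positive semidefinite")
    }
    if (any(diag(lc) < 0)) msgs <- c(msgs, "negative latent variance")
  }
  for (m in c("fa", "md")) {
    tr <- object@tracts[[m]]
    if (is.null(tr)) { msgs <- c(msgs, sprintf("tracts$%s missing", m)); next }
    for (tn in names(tr)) {
      p <- tr[[tn]]
      if (p[["residual_var"]] < 0) {
        msgs <- c(msgs, sprintf("negative residual_var in tracts$%s$%s", m, tn))
      }
      if (abs(p[["cross_wave_residual_cov"]]) > p[["residual_var"]] + 1e-12) {
        msgs <- c(msgs, sprintf("cross-wave residual block for tracts$%s$%s is not positive semidefinite", m, tn))
      }
    }
  }
  if (abs(sum(object@pvsProbs) - 1) > 1e-8) msgs <- c(msgs, "pvsProbs must sum to 1")
  if (any(object@pvsProbs < 0 | object@pvsProbs > 1)) msgs <- c(msgs, "pvsProbs must lie in [0,1]")
  if (abs(object@hemisphereCor) > 1) msgs <- c(msgs, "hemisphereCor must lie in [-1,1]")
  rates <- c(object@missingness$scan_missing_rate,
             object@artifacts$outlier_rate, object@artifacts$floor_rate)
  if (any(rates < 0 | rates > 1)) msgs <- c(msgs, "rate parameters must lie in [0,1]")
  if (length(msgs)) msgs else TRUE
})
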