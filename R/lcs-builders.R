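# Builders for the latent change score model families.
#
# Wave-3 scores are decomposed as wave-2 level plus a latent change with unit
# loadings. Single-indicator constructs carry zero measurement residuals, so
# their latent changes are essentially covariate-adjusted difference scores;
# multi-indicator constructs are measured by a common factor under strong
# factorial invariance (loadings and intercepts tied across waves, marker
# identification) with same-indicator cross-wave residual covariances.
# Cross-construct relations are covariances only (no level-to-change
# regressions); the cross-sectional (level-level) and longitudinal
# (change-change) covariances carry the reserved labels "cov_lvl_lvl" and
# "cov_chg_chg" for reporting.

#' Change score construct specification
#'
#' @param construct short construct name (used to prefix parameter labels and
#'   latent variable names).
#' @param indicators2,indicators3 column names of the wave-2/wave-3 indicators
#'   (length 1 for a single-indicator construct; same length and order).
#' @param indicatorNames short names per indicator for labels (defaults to
#'   `indicators2`).
#' @param invariance `"strong"` (loadings and intercepts tied across waves) or
#'   `"configural"`; ignored for single-indicator constructs.
#' @param residualPairs optional data.frame of extra residual covariances with
#'   columns `ind1`, `wave1`, `ind2`, `wave2` (short indicator names);
#'   same-indicator cross-wave residual covariances are always included.
#' @return list of class `"ChangeScoreSpec"`.
#' @export
changeScoreSpec <- function(construct, indicators2, indicators3,
                            indicatorNames = NULL,
                            invariance = c("strong", "configural"),
                            residualPairs = NULL) {
  invariance <- match.arg(invariance)
  stopifnot(length(indicators2) == length(indicators3), length(indicators2) >= 1)
  if (is.null(indicatorNames)) indicatorNames <- indicators2
  if (!is.null(residualPairs)) {
    bad <- setdiff(c(residualPairs$ind1, residualPairs$ind2), indicatorNames)
    if (length(bad)) stop("extra residual pair references unknown indicator: ",
                          paste(bad, collapse = ", "))
  }
  structure(list(construct = construct, ind2 = indicators2, ind3 = indicators3,
                 names = indicatorNames, invariance = invariance,
                 residualPairs = residualPairs),
            class = "ChangeScoreSpec")
}

edgeRow <- function(matrix, from, to, value = NA_real_, label = NA_character_) {
  data.frame(matrix = matrix, from = from, to = to, value = value, label = label,
             stringsAsFactors = FALSE)
}

# Edges for one construct block; returns list(edges, latents, lvl, chg).
constructEdges <- function(spec) {
  cn <- spec$construct
  lvl <- paste0(cn, "_lvl"); chg <- paste0(cn, "_chg")
  e <- list()
  add <- function(...) e[[length(e) + 1L]] <<- edgeRow(...)
  k <- length(spec$ind2)
  if (k == 1L) {
    # level defined by the wave-2 observation (loading 1, zero residual);
    # wave-3 = level + change with zero residual
    add("A", lvl, spec$ind2, 1)
    add("A", lvl, spec$ind3, 1)
    add("A", chg, spec$ind3, 1)
    latents <- c(lvl, chg)
  } else {
    f3 <- paste0(cn, "_w3f")
    add("A", lvl, f3, 1)
    add("A", chg, f3, 1)
    strong <- spec$invariance == "strong"
    for (i in seq_len(k)) {
      tn <- spec$names[i]
      if (i == 1L) {
        add("A", lvl, spec$ind2[i], 1)
        add("A", f3, spec$ind3[i], 1)
      } else if (strong) {
        lam <- paste0("lam_", cn, "_", tn)
        add("A", lvl, spec$ind2[i], 1, lam)
        add("A", f3, spec$ind3[i], 1, lam)
      } else {
        add("A", lvl, spec$ind2[i], 1, paste0("lam_", cn, "_", tn, "_w2"))
        add("A", f3, spec$ind3[i], 1, paste0("lam_", cn, "_", tn, "_w3"))
      }
      # intercepts (marker indicator fixed at 0 at both waves)
      if (i > 1L) {
        if (strong) {
          nu <- paste0("nu_", cn, "_", tn)
          add("M", NA, spec$ind2[i], 0, nu)
          add("M", NA, spec$ind3[i], 0, nu)
        } else {
          add("M", NA, spec$ind2[i], 0, paste0("nu_", cn, "_", tn, "_w2"))
          add("M", NA, spec$ind3[i], 0, paste0("nu_", cn, "_", tn, "_w3"))
        }
      }
      # residual variances per wave, same-indicator cross-wave covariance
      add("S", spec$ind2[i], spec$ind2[i], 1, paste0("evar_", cn, "_", tn, "_w2"))
      add("S", spec$ind3[i], spec$ind3[i], 1, paste0("evar_", cn, "_", tn, "_w3"))
      add("S", spec$ind2[i], spec$ind3[i], 0, paste0("ecov_", cn, "_", tn))
    }
    if (!is.null(spec$residualPairs)) {
      rp <- spec$residualPairs
      for (r in seq_len(nrow(rp))) {
        i1 <- match(rp$ind1[r], spec$names); i2 <- match(rp$ind2[r], spec$names)
        v1 <- if (rp$wave1[r] == 2) spec$ind2[i1] else spec$ind3[i1]
        v2 <- if (rp$wave2[r] == 2) spec$ind2[i2] else spec$ind3[i2]
        add("S", v1, v2, 0, paste0("ecov_", cn, "_", rp$ind1[r], rp$wave1[r],
                                   "_", rp$ind2[r], rp$wave2[r]))
      }
    }
    latents <- c(lvl, f3, chg)
  }
  add("S", lvl, lvl, 1, paste0("var_", cn, "_lvl"))
  add("S", chg, chg, 1, paste0("var_", cn, "_chg"))
  add("S", lvl, chg, 0, paste0("cov_", cn, "_lvlchg"))
  add("M", NA, lvl, 0, paste0("mean_", cn, "_lvl"))
  add("M", NA, chg, 0, paste0("mean_", cn, "_chg"))
  list(edges = do.call(rbind, e), latents = latents, lvl = lvl, chg = chg,
       observed = c(spec$ind2, spec$ind3))
}

#' Build a univariate latent change score model
#'
#' @param spec a [changeScoreSpec()].
#' @return A [SemModel-class] with reserved report labels in
#'   `meta$report` (`mean_<c>_chg`, `var_<c>_chg`).
#' @export
buildUnivariateLcs <- function(spec) {
  blk <- constructEdges(spec)
  vars <- c(blk$observed, blk$latents)
  semModel(vars, blk$observed, blk$edges,
           meta = list(report = list(changeMean = paste0("mean_", spec$construct, "_chg"),
                                     changeVar = paste0("var_", spec$construct, "_chg")),
                       lvl = blk$lvl, chg = blk$chg))
}

#' Build a bivariate latent change score model
#'
#' Combines two constructs and freely estimates all six covariances among
#' their levels and changes. The cross-sectional level-level and longitudinal
#' change-change covariances carry the reserved labels `cov_lvl_lvl` and
#' `cov_chg_chg` (see `meta$report`).
#'
#' @param xspec,yspec [changeScoreSpec()] objects with disjoint indicators.
#' @return A [SemModel-class].
#' @export
buildBivariateLcs <- function(xspec, yspec) {
  if (length(intersect(c(xspec$ind2, xspec$ind3), c(yspec$ind2, yspec$ind3)))) {
    stop("constructs share observed variables")
  }
  if (xspec$construct == yspec$construct) stop("constructs must have distinct names")
  bx <- constructEdges(xspec)
  by <- constructEdges(yspec)
  cross <- rbind(
    edgeRow("S", bx$lvl, by$lvl, 0, "cov_lvl_lvl"),
    edgeRow("S", bx$chg, by$chg, 0, "cov_chg_chg"),
    edgeRow("S", bx$lvl, by$chg, 0, paste0("cov_", xspec$construct, "lvl_", yspec$construct, "chg")),
    edgeRow("S", bx$chg, by$lvl, 0, paste0("cov_", xspec$construct, "chg_", yspec$construct, "lvl")))
  vars <- c(bx$observed, by$observed, bx$latents, by$latents)
  semModel(vars, c(bx$observed, by$observed), rbind(bx$edges, by$edges, cross),
           meta = list(report = list(level = "cov_lvl_lvl", change = "cov_chg_chg"),
                       xlvl = bx$lvl, xchg = bx$chg, ylvl = by$lvl, ychg = by$chg))
}

#' Build a latent-factor change score model for tract indicators
#'
#' Convenience wrapper: a [changeScoreSpec()] with multiple indicators under
#' strong factorial invariance (marker identification: first indicator's
#' loading fixed at 1 and intercept at 0 at both waves; all other loadings and
#' intercepts equality-constrained across waves; same-indicator cross-wave
#' residual covariances free).
#'
#' @inheritParams buildUnivariateLcs
#' @export
buildLatentFactorLcs <- function(spec) {
  if (length(spec$ind2) < 2) stop("latent-factor construct needs >= 2 indicators")
  buildUnivariateLcs(spec)
}

#' Build the observed-change variant for the PVS rating
#'
#' The visual rating of perivascular-space change enters as an observed
#' numeric variable correlated with the serum latent level and latent change
#' (no PVS level variable). The two covariances carry the reserved report
#' labels.
#'
#' @param serumSpec [changeScoreSpec()] for the serum construct.
#' @param pvsVariable column name of the observed change rating.
#' @return A [SemModel-class].
#' @export
buildPvsVariant <- function(serumSpec, pvsVariable = "pvs_change") {
  bs <- constructEdges(serumSpec)
  if (pvsVariable %in% bs$observed) stop("pvs variable clashes with serum indicators")
  e <- rbind(
    bs$edges,
    edgeRow("M", NA, pvsVariable, 0, paste0("m_", pvsVariable)),
    edgeRow("S", pvsVariable, pvsVariable, 1, paste0("var_", pvsVariable)),
    edgeRow("S", bs$lvl, pvsVariable, 0, "cov_lvl_lvl"),
    edgeRow("S", bs$chg, pvsVariable, 0, "cov_chg_chg"))
  vars <- c(bs$observed, pvsVariable, bs$latents)
  semModel(vars, c(bs$observed, pvsVariable), e,
           meta = list(report = list(level = "cov_lvl_lvl", change = "cov_chg_chg"),
                       xlvl = bs$lvl, xchg = bs$chg, ylvl = pvsVariable,
                       ychg = pvsVariable))
}

# Internal: grow a model with additional observed variables (zero entries).
expandModel <- function(model, newObserved) {
  oldVars <- model@variables
  latents <- setdiff(oldVars, model@observed)
  vars <- c(model@observed, newObserved, latents)
  n <- length(vars)
  A <- S <- matrix(0, n, n, dimnames = list(vars, vars))
  Alab <- Slab <- matrix(NA_character_, n, n, dimnames = list(vars, vars))
  M <- stats::setNames(numeric(n), vars)
  Mlab <- stats::setNames(rep(NA_character_, n), vars)
  idx <- match(oldVars, vars)
  A[idx, idx] <- model@A; S[idx, idx] <- model@S
  Alab[idx, idx] <- model@Alab; Slab[idx, idx] <- model@Slab
  M[idx] <- model@M; Mlab[idx] <- model@Mlab
  methods::new("SemModel", variables = vars,
               observed = c(model@observed, newObserved),
               A = A, S = S, M = M, Alab = Alab, Slab = Slab, Mlab = Mlab,
               meta = model@meta)
}

#' Add exogenous covariates with regression paths onto manifest variables
#'
#' Covariates enter as observed exogenous variables with free means, free
#' variances and free pairwise covariances, plus free regression paths onto
#' each mapped manifest variable. Reserved report labels are untouched.
#'
#' @param model a [SemModel-class].
#' @param covariateMap named list: manifest variable -> character vector of
#'   covariate column names.
#' @return the augmented [SemModel-class].
#' @export
addCovariates <- function(model, covariateMap) {
  manifests <- names(covariateMap)
  bad <- setdiff(manifests, model@observed)
  if (length(bad)) stop("unknown manifest variable(s): ", paste(bad, collapse = ", "))
  covs <- unique(unlist(covariateMap))
  newCovs <- setdiff(covs, model@variables)
  m2 <- expandModel(model, newCovs)
  for (i in seq_along(covs)) {
    ci <- covs[i]
    m2@Mlab[ci] <- paste0("m_", ci)
    m2@Slab[ci, ci] <- paste0("var_", ci)
    m2@S[ci, ci] <- 1
    for (j in seq_len(i - 1L)) {
      cj <- covs[j]
      m2@Slab[ci, cj] <- m2@Slab[cj, ci] <- paste0("cov_", cj, "_", ci)
    }
  }
  for (man in manifests) {
    for (cv in covariateMap[[man]]) {
      m2@Alab[man, cv] <- paste0("b_", man, "_", cv)
    }
  }
  methods::validObject(m2)
  m2
}

#' Add an auxiliary variable via saturated correlates
#'
#' The auxiliary covaries freely with every other observed variable (the
#' covariance is with the residual for endogenous manifests), with a free mean
#' and variance. Substantive parameters and their labels are untouched; with
#' complete data the augmentation leaves all substantive estimates unchanged,
#' and under missingness related to the auxiliary it makes the
#' missing-at-random assumption behind FIML more plausible.
#'
#' @param model a [SemModel-class].
#' @param auxVariable column name of the auxiliary observed variable.
#' @return the augmented [SemModel-class].
#' @export
addAuxiliary <- function(model, auxVariable) {
  if (auxVariable %in% model@variables) {
    stop("auxiliary variable already in the model: ", auxVariable)
  }
  m2 <- expandModel(model, auxVariable)
  m2@Mlab[auxVariable] <- paste0("m_", auxVariable)
  m2@Slab[auxVariable, auxVariable] <- paste0("var_", auxVariable)
  m2@S[auxVariable, auxVariable] <- 1
  for (v in setdiff(m2@observed, auxVariable)) {
    m2@Slab[auxVariable, v] <- m2@Slab[v, auxVariable] <- paste0("aux_", v)
  }
  methods::validObject(m2)
  m2
}

#' Propose extra tract-tract residual covariances
#'
#' Fits nothing itself: given a fitted configural (or strong) model, ranks the
#' cross-indicator covariance residuals (saturated estimate minus
#' model-implied, standardized) and returns the largest ones as candidate
#' extra residual pairs.
#'
#' @param fit a [SemFit-class] of a latent-factor model.
#' @param data the data used for the fit.
#' @param indicators character vector of indicator columns to consider.
#' @param k number of pairs to propose.
#' @return data.frame with columns `var1`, `var2`, `residual`.
#' @export
suggestResidualPairs <- function(fit, data, indicators, k = 5L) {
  X <- as.matrix(as.data.frame(data)[, fit@model@observed, drop = FALSE])
  storage.mode(X) <- "double"
  sat <- emSaturated(X)
  mom <- impliedMoments(fit@model)
  sds <- sqrt(diag(sat$Sigma))
  res <- (sat$Sigma - mom$Sigma) / outer(sds, sds)
  idx <- match(indicators, fit@model@observed)
  out <- list()
  for (a in seq_along(idx)) for (b in seq_len(a - 1L)) {
    out[[length(out) + 1L]] <- data.frame(
      var1 = indicators[b], var2 = indicators[a],
      residual = res[idx[a], idx[b]])
  }
  out <- do.call(rbind, out)
  out <- out[order(-abs(out$residual)), , drop = FALSE]
  utils::head(out, k)
}

#' Standard covariate map for the cohort's models
#'
#' Serum manifests are corrected for age at serum draw (per wave) and sex;
#' MRI manifests for age at scan (per wave), sex, diabetes and hypertension.
#'
#' @param serumVars character of length 2 (wave-2, wave-3 serum columns).
#' @param mriVars2,mriVars3 MRI manifest columns per wave.
#' @return named list usable with [addCovariates()].
#' @export
standardCovariateMap <- function(serumVars = c("s100b_2", "s100b_3"),
                                 mriVars2 = character(0),
                                 mriVars3 = character(0)) {
  map <- list()
  map[[serumVars[1]]] <- c("age_serum_2", "sex")
  map[[serumVars[2]]] <- c("age_serum_3", "sex")
  for (v in mriVars2) map[[v]] <- c("age_mri_2", "sex", "diabetes_2", "hypertension_2")
  for (v in mriVars3) map[[v]] <- c("age_mri_3", "sex", "diabetes_2", "hypertension_2")
  map
}
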