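#' Shipped generator calibration
#'
#' Parses the versioned calibration file distributed with the package:
#' marginal descriptives of the emulated cohort (serum means/SDs, ages, sex
#' split, MMSE, brain volumes, PVS rating frequencies), the wave-to-wave serum
#' stability, and the standardized serum-MRI coupling values used as
#' generating truths in calibrated simulations.
#'
#' @param path optional alternative calibration file (YAML).
#' @return named list mirroring the file.
#' @export
defaultCalibration <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "calibration.yaml", package = "lcsem")
  }
  yaml::read_yaml(path)
}

tractNames <- function() c("genu", "splenium", "atr", "cingulum", "uncinate", "arcuate", "ilf")
bilateralTracts <- function() c("atr", "cingulum", "uncinate", "arcuate", "ilf")

defaultTractParams <- function() {
  mk <- function(loading, intercept, rv, cc) {
    c(loading = loading, intercept = intercept,
      residual_var = rv, cross_wave_residual_cov = cc)
  }
  list(
    fa = list(
      genu     = mk(1.00, 0.0000, 9e-4, 4e-4),
      splenium = mk(0.90, 0.1450, 9e-4, 4e-4),
      atr      = mk(0.80, 0.0200, 9e-4, 4e-4),
      cingulum = mk(0.85, 0.0675, 9e-4, 4e-4),
      uncinate = mk(0.75, 0.0625, 9e-4, 4e-4),
      arcuate  = mk(0.80, 0.0600, 9e-4, 4e-4),
      ilf      = mk(0.85, 0.0575, 9e-4, 4e-4)
    ),
    md = list(
      genu     = mk(1.00, 0.000, 4e-4, 1.8e-4),
      splenium = mk(0.90, 0.102, 4e-4, 1.8e-4),
      atr      = mk(0.80, 0.224, 4e-4, 1.8e-4),
      cingulum = mk(0.85, 0.088, 4e-4, 1.8e-4),
      uncinate = mk(0.80, 0.244, 4e-4, 1.8e-4),
      arcuate  = mk(0.75, 0.200, 4e-4, 1.8e-4),
      ilf      = mk(0.85, 0.168, 4e-4, 1.8e-4)
    )
  )
}

# Level/change latent moments for one construct given the two wave SDs and the
# wave-to-wave stability correlation (level variance anchored at wave 2):
#   cov(w2,w3) = r sd2 sd3 = var_L + cov_LC
#   var(w3)    = var_L + var_C + 2 cov_LC
levelChangeSpec <- function(mean2, sd2, mean3, sd3, stability) {
  varL <- sd2^2
  covW <- stability * sd2 * sd3
  covLC <- covW - varL
  varC <- sd3^2 - varL - 2 * covLC
  if (varC < 0) stop("implied change variance negative; check stability/SDs")
  c(lvl_mean = mean2, chg_mean = mean3 - mean2,
    lvl_var = varL, chg_var = varC, lvl_chg_cov = covLC)
}

# Serum spec adjusted so the OBSERVED wave moments hit the calibrated values
# after adding the (centered) covariate effects: the covariate variance
# contributions are subtracted from the latent moments in closed form.
serumLatentSpec <- function(cal, covEff, covDists) {
  ageE <- covEff$serum[["age"]]
  sexE <- covEff$serum[["sex"]]
  pq <- covDists$sex_p_male * (1 - covDists$sex_p_male)
  vAge2 <- covDists$age_w2_sd^2
  vAge3 <- covDists$age_w2_sd^2 + covDists$wave_lag_sd^2  # age3 = age2 + lag
  c2 <- ageE^2 * vAge2 + sexE^2 * pq
  c3 <- ageE^2 * vAge3 + sexE^2 * pq
  c23 <- ageE^2 * vAge2 + sexE^2 * pq
  s <- cal$serum
  varL <- s$w2_sd^2 - c2
  covW <- s$stability_r * s$w2_sd * s$w3_sd - c23
  covLC <- covW - varL
  varC <- (s$w3_sd^2 - c3) - varL - 2 * covLC
  if (min(varL, varC) < 0) stop("serum calibration infeasible with these covariate effects")
  c(lvl_mean = s$w2_mean, chg_mean = s$w3_mean - s$w2_mean,
    lvl_var = varL, chg_var = varC, lvl_chg_cov = covLC)
}

#' Default generator configuration
#'
#' Builds a [GeneratorConfig-class] whose observed serum moments reproduce the
#' calibrated wave means/SDs and stability, whose volumetric constructs match
#' the calibrated descriptives, and whose standardized serum-MRI latent
#' couplings equal the shipped calibration values (MRI-MRI couplings default
#' to zero). See the methods vignette for the rationale behind quantities the
#' calibration file does not pin down (MRI stabilities, tract measurement
#' parameters, covariate effect sizes).
#'
#' @param n number of participants.
#' @param seed base RNG seed.
#' @param calibration calibration list from [defaultCalibration()].
#' @return A [GeneratorConfig-class].
#' @export
defaultGeneratorConfig <- function(n = 600L, seed = 1L,
                                   calibration = defaultCalibration()) {
  cal <- calibration
  covDists <- list(
    age_w2_mean = cal$ages$serum_w2_mean, age_w2_sd = cal$ages$serum_w2_sd,
    wave_lag_mean = cal$ages$wave_lag_mean, wave_lag_sd = cal$ages$wave_lag_sd,
    scan_lag_days = c(w2_mean = cal$ages$scan_lag_days_w2_mean,
                      w2_sd = cal$ages$scan_lag_days_w2_sd,
                      w3_mean = cal$ages$scan_lag_days_w3_mean,
                      w3_sd = cal$ages$scan_lag_days_w3_sd),
    sex_p_male = cal$sex$male_n_w2 / (cal$sex$male_n_w2 + cal$sex$female_n_w2),
    diabetes_prev = 0.10, hypertension_prev = 0.40
  )
  covEff <- list(
    serum = c(age = 0.0010, sex = -0.009),
    mri = list(
      gfa = c(age = -0.0020, sex = 0.004, diabetes = -0.006, hypertension = -0.004),
      gmd = c(age = 0.0030, sex = -0.004, diabetes = 0.008, hypertension = 0.005),
      wmh = c(age = 0.040, sex = -0.050, diabetes = 0.100, hypertension = 0.150),
      tb  = c(age = -3.00, sex = 30.0, diabetes = -4.0, hypertension = -3.0),
      gm  = c(age = -1.50, sex = 15.0, diabetes = -2.5, hypertension = -2.0)
    )
  )
  specs <- list(
    s100b = serumLatentSpec(cal, covEff, covDists),
    gfa = levelChangeSpec(0.45, sqrt(0.0012), 0.44, sqrt(0.0012), 0.80),
    gmd = levelChangeSpec(0.72, 0.03, 0.732, 0.03, 0.85),
    wmh = levelChangeSpec(log(cal$volumes$wmh_w2_median), 0.9,
                          log(cal$volumes$wmh_w3_median), 0.9, 0.90),
    tb  = levelChangeSpec(cal$volumes$tb_w2_mean, cal$volumes$tb_w2_sd,
                          cal$volumes$tb_w3_mean, cal$volumes$tb_w3_sd, 0.98),
    gm  = levelChangeSpec(cal$volumes$gm_w2_mean, cal$volumes$gm_w2_sd,
                          cal$volumes$gm_w3_mean, cal$volumes$gm_w3_sd, 0.95)
  )
  ln <- latentNames()
  mu <- stats::setNames(numeric(12), ln)
  Sg <- matrix(0, 12, 12, dimnames = list(ln, ln))
  for (con in lcsConstructs()) {
    sp <- specs[[con]]
    l <- paste0(con, "_lvl"); cgh <- paste0(con, "_chg")
    mu[l] <- sp[["lvl_mean"]]; mu[cgh] <- sp[["chg_mean"]]
    Sg[l, l] <- sp[["lvl_var"]]; Sg[cgh, cgh] <- sp[["chg_var"]]
    Sg[l, cgh] <- Sg[cgh, l] <- sp[["lvl_chg_cov"]]
  }
  # serum-MRI couplings (standardized -> covariances); MRI-MRI left at zero
  for (con in setdiff(lcsConstructs(), "s100b")) {
    cp <- cal$couplings[[con]]
    if (is.null(cp)) next
    Sg["s100b_lvl", paste0(con, "_lvl")] <- Sg[paste0(con, "_lvl"), "s100b_lvl"] <-
      cp$level * sqrt(Sg["s100b_lvl", "s100b_lvl"] * Sg[paste0(con, "_lvl"), paste0(con, "_lvl")])
    Sg["s100b_chg", paste0(con, "_chg")] <- Sg[paste0(con, "_chg"), "s100b_chg"] <-
      cp$change * sqrt(Sg["s100b_chg", "s100b_chg"] * Sg[paste0(con, "_chg"), paste0(con, "_chg")])
  }
  pvsN <- cal$pvs$n_zero + cal$pvs$n_plus_one
  methods::new("GeneratorConfig",
    nParticipants = as.integer(n), seed = as.integer(seed),
    latentMeans = mu, latentCov = Sg,
    tracts = defaultTractParams(), hemisphereCor = 0.7,
    covariateEffects = covEff, covariateDists = covDists,
    exclusionDists = list(mmse_mean = cal$mmse$mean, mmse_sd = cal$mmse$sd,
                          mmse_low_rate = 0.01, dementia_rate = 0.01,
                          melanoma_rate = 0.015),
    icvMean = 1450, icvSd = 120,
    pvsProbs = stats::setNames(c(0, 0, cal$pvs$n_zero / pvsN, cal$pvs$n_plus_one / pvsN, 0),
                               as.character(-2:2)),
    pvsCoupling = 0,
    missingness = list(attrition_intercept = stats::qlogis(0.20),
                       attrition_slope_on_gm = -0.3,
                       scan_missing_rate = 0.236),
    artifacts = list(outlier_rate = 0, outlier_magnitude_sd = 2, floor_rate = 0))
}

#' Modify a generator configuration
#'
#' Replaces named slots of a [GeneratorConfig-class] and revalidates. Slot
#' values given as lists are merged element-wise into the existing list.
#'
#' @param config a [GeneratorConfig-class].
#' @param ... slot replacements, e.g. `nParticipants = 1000`,
#'   `missingness = list(attrition_slope_on_gm = -1)`.
#' @export
updateConfig <- function(config, ...) {
  mods <- list(...)
  for (nm in names(mods)) {
    if (!nm %in% methods::slotNames("GeneratorConfig")) stop("unknown slot: ", nm)
    cur <- methods::slot(config, nm)
    v <- mods[[nm]]
    if (is.list(cur) && is.list(v) && !is.null(names(v))) {
      cur[names(v)] <- v
      methods::slot(config, nm) <- cur
    } else if (nm %in% c("nParticipants", "seed")) {
      methods::slot(config, nm) <- as.integer(v)
    } else {
      methods::slot(config, nm) <- v
    }
  }
  methods::validObject(config)
  config
}

#' @describeIn updateConfig set every cross-construct latent coupling (and the
#'   PVS coupling) to zero — an all-null generating configuration for
#'   false-positive-rate studies.
#' @export
zeroCouplings <- function(config) {
  Sg <- config@latentCov
  for (a in lcsConstructs()) for (b in lcsConstructs()) {
    if (a == b) next
    for (ca in c("_lvl", "_chg")) for (cb in c("_lvl", "_chg")) {
      Sg[paste0(a, ca), paste0(b, cb)] <- 0
    }
  }
  config@latentCov <- Sg
  config@pvsCoupling <- 0
  methods::validObject(config)
  config
}

#' @describeIn updateConfig remove all covariate effects on manifest variables
#'   (distributions unchanged).
#' @export
zeroCovariateEffects <- function(config) {
  ce <- config@covariateEffects
  ce$serum[] <- 0
  for (nm in names(ce$mri)) ce$mri[[nm]][] <- 0
  config@covariateEffects <- ce
  # re-solve the serum latent spec so observed moments stay on calibration
  cal <- defaultCalibration()
  sp <- serumLatentSpec(cal, ce, config@covariateDists)
  config@latentMeans["s100b_lvl"] <- sp[["lvl_mean"]]
  config@latentMeans["s100b_chg"] <- sp[["chg_mean"]]
  old <- config@latentCov
  sdOldL <- sqrt(old["s100b_lvl", "s100b_lvl"]); sdOldC <- sqrt(old["s100b_chg", "s100b_chg"])
  config@latentCov["s100b_lvl", "s100b_lvl"] <- sp[["lvl_var"]]
  config@latentCov["s100b_chg", "s100b_chg"] <- sp[["chg_var"]]
  config@latentCov["s100b_lvl", "s100b_chg"] <-
    config@latentCov["s100b_chg", "s100b_lvl"] <- sp[["lvl_chg_cov"]]
  # rescale serum-other covariances to preserve the coupling correlations
  for (other in setdiff(colnames(old), c("s100b_lvl", "s100b_chg"))) {
    config@latentCov["s100b_lvl", other] <- config@latentCov[other, "s100b_lvl"] <-
      old["s100b_lvl", other] / sdOldL * sqrt(sp[["lvl_var"]])
    config@latentCov["s100b_chg", other] <- config@latentCov[other, "s100b_chg"] <-
      old["s100b_chg", other] / sdOldC * sqrt(sp[["chg_var"]])
  }
  methods::validObject(config)
  config
}

#' Tract-protocol generator configuration
#'
#' For single-indicator tract analyses the factor measurement model attenuates
#' any observed tract-serum correlation below the latent coupling, so
#' calibrated tract simulations instead make the named tract the construct
#' itself: its loading is fixed at 1 with zero residual, and the serum-level
#' to construct-level correlation is set to the shipped per-tract calibration
#' value (or `coupling`).
#'
#' @param tract one of `"genu"`, `"splenium"`, `"atr"`, `"cingulum"`,
#'   `"uncinate"`, `"arcuate"`, `"ilf"`.
#' @param metric `"fa"` or `"md"`.
#' @param coupling standardized serum-level/tract-level correlation; defaults
#'   to the shipped calibration (FA only for some tracts).
#' @param config base configuration to modify.
#' @return A [GeneratorConfig-class].
#' @export
tractCalibration <- function(tract, metric = "fa", coupling = NULL,
                             config = defaultGeneratorConfig()) {
  stopifnot(tract %in% tractNames(), metric %in% c("fa", "md"))
  if (is.null(coupling)) {
    cal <- defaultCalibration()
    coupling <- cal$tract_fa_level[[tract]]
    if (is.null(coupling) || metric != "fa") {
      stop("no shipped coupling for ", metric, " ", tract, "; supply `coupling`")
    }
  }
  con <- if (metric == "fa") "gfa" else "gmd"
  tp <- config@tracts[[metric]][[tract]]
  tp[["loading"]] <- 1
  tp[["residual_var"]] <- 0
  tp[["cross_wave_residual_cov"]] <- 0
  config@tracts[[metric]][[tract]] <- tp
  Sg <- config@latentCov
  l <- paste0(con, "_lvl")
  Sg["s100b_lvl", l] <- Sg[l, "s100b_lvl"] <-
    coupling * sqrt(Sg["s100b_lvl", "s100b_lvl"] * Sg[l, l])
  config@latentCov <- Sg
  methods::validObject(config)
  config
}

#' @export
setMethod("show", "GeneratorConfig", function(object) {
  cat(sprintf("GeneratorConfig: n = %d, seed = %d\n",
              object@nParticipants, object@seed))
  r <- object@latentCov["s100b_lvl", "gfa_lvl"] /
    sqrt(object@latentCov["s100b_lvl", "s100b_lvl"] * object@latentCov["gfa_lvl", "gfa_lvl"])
  cat(sprintf("  serum level mean %.3f, gFA level coupling r = %.3f\n",
              object@latentMeans["s100b_lvl"], r))
  cat(sprintf("  attrition: logit %.2f + %.2f x z(GM); scan missing rate %.3f\n",
              object@missingness$attrition_intercept,
              object@missingness$attrition_slope_on_gm,
              object@missingness$scan_missing_rate))
  invisible(object)
})
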