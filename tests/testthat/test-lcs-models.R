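# Latent change score model builders: difference-score identities, invariance,
# covariates, the auxiliary augmentation, and the PVS variant.

test_that("the univariate change score model is the ML difference-score model", {
  d <- bivariateData(400, 0.6, seed = 51, mx = 10, my = 12, sx = 2, sy = 2.5)
  names(d) <- c("w2", "w3")
  fit <- semFit(buildUnivariateLcs(changeScoreSpec("c", "w2", "w3")), d)
  diffs <- d$w3 - d$w2
  n <- nrow(d)
  expect_equal(unname(fit@estimates["mean_c_chg"]), mean(diffs), tolerance = 1e-6)
  expect_equal(unname(fit@estimates["var_c_chg"]), var(diffs) * (n - 1) / n,
               tolerance = 1e-5)
  expect_equal(unname(fit@estimates["mean_c_lvl"]), mean(d$w2), tolerance = 1e-6)
  # saturated single-construct model: zero df
  expect_equal(fit@df, 0)
})

test_that("identical waves give a degenerate zero-variance change", {
  set.seed(52)
  d <- data.frame(w2 = rnorm(80, 5))
  d$w3 <- d$w2
  fit <- semFit(buildUnivariateLcs(changeScoreSpec("c", "w2", "w3")), d,
                se = FALSE, indices = FALSE)
  expect_lt(abs(fit@estimates[["var_c_chg"]]), 1e-6)
  expect_lt(abs(fit@estimates[["mean_c_chg"]]), 1e-8)
})

test_that("the calibrated serum change mean is recovered at large n", {
  pp <- quickCohort(10000, seed = 61, preprocess = FALSE)
  fit <- semFit(buildUnivariateLcs(changeScoreSpec("s100b", "s100b_2", "s100b_3")),
                pp, indices = FALSE)
  est <- fit@estimates[["mean_s100b_chg"]]
  se <- fit@se[["mean_s100b_chg"]]
  expect_lt(abs(est - 0.007), 3 * se)
})

test_that("the bivariate model frees exactly the hand-enumerated parameters", {
  m <- buildBivariateLcs(changeScoreSpec("a", "a2", "a3"),
                         changeScoreSpec("b", "b2", "b3"))
  # 4 means, 4 variances, 6 covariances
  expect_equal(length(unique(freeParamTable(m)$label)), 14)
  expect_true(all(c("cov_lvl_lvl", "cov_chg_chg") %in% freeParamTable(m)$label))
  expect_error(buildBivariateLcs(changeScoreSpec("a", "x2", "x3"),
                                 changeScoreSpec("b", "x2", "b3")),
               "share observed")
})

test_that("bivariate couplings are recovered, including the null", {
  # null: all couplings zero
  cfg0 <- zeroCovariateEffects(zeroCouplings(defaultGeneratorConfig(n = 5000, seed = 63)))
  tab0 <- generateCohort(cfg0)
  m <- buildBivariateLcs(changeScoreSpec("s100b", "s100b_2", "s100b_3"),
                         changeScoreSpec("gm", "gm_2", "gm_3"))
  f0 <- semFit(m, tab0, indices = FALSE)
  expect_lt(abs(f0@estimates[["cov_lvl_lvl"]] / f0@se[["cov_lvl_lvl"]]), 3)

  # change-change correlation of 0.4 between serum and gray matter
  cfg <- defaultGeneratorConfig(n = 5000, seed = 64)
  Sg <- cfg@latentCov
  Sg["s100b_chg", "gm_chg"] <- Sg["gm_chg", "s100b_chg"] <-
    0.4 * sqrt(Sg["s100b_chg", "s100b_chg"] * Sg["gm_chg", "gm_chg"])
  cfg <- updateConfig(zeroCovariateEffects(cfg), latentCov = Sg)
  truth <- cfg@latentCov["s100b_chg", "gm_chg"]
  tab <- generateCohort(cfg)
  f1 <- semFit(m, tab, indices = FALSE)
  expect_lt(abs(f1@estimates[["cov_chg_chg"]] - truth), 3 * f1@se[["cov_chg_chg"]])
  std <- f1@standardized
  expect_equal(std$std[std$label == "cov_chg_chg"], 0.4, tolerance = 0.05)
})

test_that("the single-indicator standardized level coupling equals the residualized Pearson r", {
  cfg <- tractCalibration("atr", "fa", config = defaultGeneratorConfig(n = 5000, seed = 65))
  pp <- preprocessCohort(generateCohort(cfg))$table
  m <- lcsem:::buildOutcomeModel("tract:atr:fa", covariates = TRUE, auxiliary = FALSE)
  fit <- semFit(m, pp, se = FALSE, indices = FALSE)
  std <- fit@standardized
  est <- std$std[std$label == "cov_lvl_lvl"]
  # oracle: Pearson correlation of the covariate-residualized wave-2 values
  r1 <- resid(lm(s100b_2 ~ age_serum_2 + sex, pp))
  r2 <- resid(lm(fa_atr_2 ~ age_mri_2 + sex + diabetes_2 + hypertension_2, pp))
  expect_equal(est, cor(r1, r2), tolerance = 0.01)
})

test_that("the factor model df matches the hand enumeration and invariance is testable", {
  pp <- quickCohort(300, seed = 71)
  strong <- buildLatentFactorLcs(miniFactorSpec())
  # 3 indicators x 2 waves: 6*7/2 + 6 = 27 moments; params: 2 loadings +
  # 2 intercepts + 6 residual vars + 3 cross-wave covs + 2+2+1 latent = 18
  fitS <- semFit(strong, pp)
  expect_equal(fitS@df, 27 - 18)
  expect_true(fitS@converged)

  # violate invariance: rescale one wave-3 indicator
  pp2 <- pp
  pp2$fa_splenium_3 <- pp2$fa_splenium_3 * 1.5
  fitS2 <- semFit(strong, pp2, se = FALSE)
  conf <- buildLatentFactorLcs(miniFactorSpec(invariance = "configural"))
  fitC2 <- semFit(conf, pp2, se = FALSE)
  lr <- fitS2@chi2 - fitC2@chi2
  expect_gt(lr, qchisq(0.999, df = fitS2@df - fitC2@df))
  # freed parameters: one loading + one intercept per non-marker indicator
  expect_equal(fitS2@df - fitC2@df, 4)
})

test_that("the full seven-indicator model df matches the moment count", {
  spec <- changeScoreSpec("gfa",
                          sprintf("fa_%s_2", lcsem:::tractNames()),
                          sprintf("fa_%s_3", lcsem:::tractNames()),
                          indicatorNames = lcsem:::tractNames())
  m <- buildLatentFactorLcs(spec)
  # 14*17/2 + 14 = 119 moments; 6+6+14+7+5 = 38 free labels
  expect_equal(length(unique(freeParamTable(m)$label)), 38)
  p <- length(semObserved(m))
  expect_equal(p * (p + 3) / 2 - 38, 81)
})

test_that("the PVS variant carries reserved labels and recovers its couplings", {
  m <- buildPvsVariant(changeScoreSpec("s100b", "s100b_2", "s100b_3"))
  labs <- unique(freeParamTable(m)$label)
  expect_true(all(c("cov_lvl_lvl", "cov_chg_chg") %in% labs))
  expect_error(buildPvsVariant(changeScoreSpec("s100b", "pvs_change", "s100b_3")),
               "clashes")

  # independent rating: both couplings within 3 SEs of zero
  cfg0 <- zeroCovariateEffects(defaultGeneratorConfig(n = 5000, seed = 81))
  tab0 <- generateCohort(cfg0)
  f0 <- semFit(m, tab0, indices = FALSE)
  expect_lt(abs(f0@estimates[["cov_lvl_lvl"]] / f0@se[["cov_lvl_lvl"]]), 3)
  expect_lt(abs(f0@estimates[["cov_chg_chg"]] / f0@se[["cov_chg_chg"]]), 3)

  # coupled rating: the implied observed-scale correlation is the oracle
  cfg1 <- updateConfig(cfg0, pvsCoupling = -0.3)
  tab1 <- generateCohort(cfg1)
  f1 <- semFit(m, tab1, indices = FALSE)
  p1 <- sum(cfg1@pvsProbs[c("1", "2")])
  impliedR <- -0.3 * dnorm(qnorm(1 - p1)) / sqrt(p1 * (1 - p1))
  std <- f1@standardized
  est <- std$std[std$label == "cov_chg_chg"]
  expect_lt(abs(est - impliedR), 3 * f1@se[["cov_chg_chg"]] /
              sqrt(f1@estimates[["var_s100b_chg"]] * f1@estimates[["var_pvs_change"]]))
  expect_lt(est, 0)
})

test_that("covariate correction deconfounds the level association", {
  # strong age effects on both serum and the tract manifests
  cfg <- tractCalibration("atr", "fa", config = defaultGeneratorConfig(n = 4000, seed = 83))
  ce <- cfg@covariateEffects
  ce$serum[["age"]] <- 0.015
  ce$mri$gfa[["age"]] <- -0.02
  cfg@covariateEffects <- ce
  pp <- preprocessCohort(generateCohort(cfg))$table
  mAdj <- lcsem:::buildOutcomeModel("tract:atr:fa", covariates = TRUE, auxiliary = FALSE)
  mRaw <- lcsem:::buildOutcomeModel("tract:atr:fa", covariates = FALSE, auxiliary = FALSE)
  stdOf <- function(m) {
    f <- semFit(m, pp, se = FALSE, indices = FALSE)
    s <- f@standardized
    s$std[s$label == "cov_lvl_lvl"]
  }
  adj <- stdOf(mAdj); raw <- stdOf(mRaw)
  expect_lt(abs(adj - (-0.155)), 0.05)
  expect_gt(abs(raw - (-0.155)), abs(adj - (-0.155)) + 0.02)

  # null covariate effects: adjusted and unadjusted agree
  cfg0 <- zeroCovariateEffects(cfg)
  pp0 <- preprocessCohort(generateCohort(cfg0))$table
  f1 <- semFit(mAdj, pp0, se = FALSE, indices = FALSE)
  f2 <- semFit(mRaw, pp0, se = FALSE, indices = FALSE)
  s1 <- f1@standardized; s2 <- f2@standardized
  expect_equal(s1$std[s1$label == "cov_lvl_lvl"], s2$std[s2$label == "cov_lvl_lvl"],
               tolerance = 0.02)
})

test_that("covariate maps reject unknown manifests and add the expected parameters", {
  m <- buildUnivariateLcs(changeScoreSpec("s100b", "s100b_2", "s100b_3"))
  expect_error(addCovariates(m, list(nope = "sex")), "unknown manifest")
  m2 <- addCovariates(m, list(s100b_2 = c("age_serum_2", "sex"),
                              s100b_3 = c("age_serum_3", "sex")))
  # 3 covariates: 3 means + 3 vars + 3 covs + 4 paths = 13 extra labels
  expect_equal(length(unique(freeParamTable(m2)$label)) -
                 length(unique(freeParamTable(m)$label)), 13)
})

test_that("the auxiliary augmentation is inert on complete data and preserves df", {
  pp <- quickCohort(800, seed = 85)
  m <- buildBivariateLcs(changeScoreSpec("s100b", "s100b_2", "s100b_3"),
                         changeScoreSpec("wmh", "wmh_2", "wmh_3"))
  mA <- addAuxiliary(m, "gm_2")
  expect_error(addAuxiliary(mA, "gm_2"), "already in the model")
  f <- semFit(m, pp, se = FALSE)
  fA <- semFit(mA, pp, se = FALSE)
  for (lab in c("cov_lvl_lvl", "cov_chg_chg", "mean_s100b_chg")) {
    expect_lt(abs(f@estimates[[lab]] - fA@estimates[[lab]]), 1e-5)
  }
  # the auxiliary block is saturated: degrees of freedom are unchanged
  expect_equal(f@df, fA@df)
})
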