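# Synthetic cohort generator: schema, determinism, calibration, missingness,
# artifact injection.

test_that("empty and deterministic generation respect the schema", {
  cfg <- defaultGeneratorConfig(n = 0, seed = 1)
  empty <- generateCohort(cfg)
  expect_equal(nrow(empty), 0)
  expect_equal(ncol(empty), 74)
  expect_true(all(c("s100b_2", "fa_atr_l_3", "md_genu_2", "pvs_change",
                    "icv") %in% names(empty)))

  cfg2 <- defaultGeneratorConfig(n = 50, seed = 99)
  t1 <- generateCohort(cfg2)
  t2 <- generateCohort(cfg2)
  expect_identical(t1, t2)
  # different seed differs
  t3 <- generateCohort(defaultGeneratorConfig(n = 50, seed = 100))
  expect_false(identical(t1, t3))
})

test_that("zero residual variance makes tract indicators exact affine images of the factor", {
  cfg <- defaultGeneratorConfig(n = 2000, seed = 5)
  tr <- cfg@tracts
  for (m in c("fa", "md")) for (t in names(tr[[m]])) {
    tr[[m]][[t]][["residual_var"]] <- 0
    tr[[m]][[t]][["cross_wave_residual_cov"]] <- 0
  }
  cfg <- updateConfig(zeroCovariateEffects(defaultGeneratorConfig(n = 2000, seed = 5)),
                      tracts = tr)
  tab <- generateCohort(cfg)
  # marker tract (genu, loading 1, intercept 0) reveals the factor exactly;
  # every other indicator must equal intercept + loading x factor
  g <- tab$fa_genu_2
  p <- cfg@tracts$fa$splenium
  expect_lt(max(abs(tab$fa_splenium_2 - (p[["intercept"]] + p[["loading"]] * g))), 1e-9)
  p2 <- cfg@tracts$fa$atr
  expect_lt(max(abs(tab$fa_atr_l_2 - (p2[["intercept"]] + p2[["loading"]] * g))), 1e-9)
  expect_equal(tab$fa_atr_l_2, tab$fa_atr_r_2, tolerance = 1e-12)
})

test_that("default calibration reproduces the configured serum moments", {
  cfg <- defaultGeneratorConfig(n = 10000, seed = 7)
  tab <- generateCohort(cfg)
  # wave means within 3 Monte-Carlo SEs of the calibrated values
  expect_lt(abs(mean(tab$s100b_2) - 0.085), 3 * sd(tab$s100b_2) / 100)
  expect_lt(abs(mean(tab$s100b_3) - 0.092), 3 * sd(tab$s100b_3) / 100)
  # stability correlation at its closed-form implied value
  r <- cor(tab$s100b_2, tab$s100b_3)
  expect_lt(abs(r - 0.585), 3 * (1 - 0.585^2) / 100)
  # ICV constant across waves by construction, FA within [0, 1], volumes > 0
  expect_true(all(tab$fa_genu_2 >= 0 & tab$fa_genu_2 <= 1))
  expect_true(all(tab$wmh_2 > 0 & tab$tb_2 > 0 & tab$gm_2 > 0))
  expect_true(all(tab$pvs_change %in% -2:2))
})

test_that("latent cross-construct covariance is reproduced in the draws", {
  cfg <- defaultGeneratorConfig(n = 20000, seed = 17)
  cfg <- zeroCovariateEffects(cfg)
  tab <- generateCohort(cfg)
  # serum level/gm level correlation: observable directly (zero effects,
  # single-indicator constructs)
  trueR <- cfg@latentCov["s100b_lvl", "gm_lvl"] /
    sqrt(cfg@latentCov["s100b_lvl", "s100b_lvl"] * cfg@latentCov["gm_lvl", "gm_lvl"])
  r <- cor(tab$s100b_2, tab$gm_2)
  expect_lt(abs(r - trueR), 3 / sqrt(nrow(tab)))
})

test_that("non-PSD and invalid configurations are rejected with informative errors", {
  cfg <- defaultGeneratorConfig(n = 10, seed = 1)
  Sg <- cfg@latentCov
  Sg["s100b_lvl", "gfa_lvl"] <- Sg["gfa_lvl", "s100b_lvl"] <- 1  # breaks PSD
  expect_error(updateConfig(cfg, latentCov = Sg), "positive semidefinite")
  expect_error(updateConfig(cfg, missingness = list(scan_missing_rate = 1.5)),
               "rate")
  tr <- cfg@tracts
  tr$fa$genu[["residual_var"]] <- -1
  expect_error(updateConfig(cfg, tracts = tr), "residual_var")
})

test_that("attrition is MAR on baseline gray matter and recoverable by logistic regression", {
  cfg <- updateConfig(defaultGeneratorConfig(n = 10000, seed = 23),
                      missingness = list(attrition_slope_on_gm = -0.6,
                                         scan_missing_rate = 0))
  tab <- generateCohort(cfg)
  miss <- applyMissingness(tab, cfg)
  drop <- is.na(miss$s100b_3)
  expect_true(mean(drop) > 0.1 && mean(drop) < 0.4)
  # direction forced by the negative slope
  expect_gt(mean(tab$gm_2[!drop]), mean(tab$gm_2[drop]))
  # logistic-regression oracle recovers the slope
  gz <- as.vector(scale(tab$gm_2))
  gl <- glm(drop ~ gz, family = binomial())
  est <- coef(summary(gl))["gz", ]
  expect_lt(abs(est["Estimate"] - (-0.6)), 3 * est["Std. Error"])
  # MAR: conditional on baseline GM, dropout is independent of wave-3 values
  gl2 <- glm(drop ~ gz + tab$s100b_3 + tab$wmh_3, family = binomial())
  z <- coef(summary(gl2))[c("tab$s100b_3", "tab$wmh_3"), "z value"]
  expect_true(all(abs(z) < 3))
  # wave-2 serum is never removed
  expect_false(anyNA(miss$s100b_2))
})

test_that("no-missingness settings leave the table unchanged", {
  cfg <- updateConfig(defaultGeneratorConfig(n = 200, seed = 3),
                      missingness = list(attrition_intercept = -Inf,
                                         attrition_slope_on_gm = 0,
                                         scan_missing_rate = 0))
  tab <- generateCohort(cfg)
  expect_identical(applyMissingness(tab, cfg), tab)
})

test_that("artifact injection is audited and respects its construction rules", {
  cfg <- defaultGeneratorConfig(n = 500, seed = 13)
  tab <- generateCohort(cfg)
  # both rates zero: unchanged, empty audit log
  t0 <- injectArtifacts(tab, cfg)
  expect_equal(nrow(artifactLog(t0)), 0)
  expect_equal(t0$s100b_2, tab$s100b_2)

  # outlier_rate chosen to inject exactly k = 10 of 1000 cells
  cfg2 <- updateConfig(cfg, artifacts = list(outlier_rate = 0.01,
                                             floor_rate = 0.02))
  t1 <- injectArtifacts(tab, cfg2)
  log <- artifactLog(t1)
  out <- log[log$rule == "outlier", ]
  expect_equal(nrow(out), 10)
  for (w in 2:3) {
    thr <- mean(tab[[paste0("s100b_", w)]]) + 4 * sd(tab[[paste0("s100b_", w)]])
    expect_true(all(out$new[out$wave == w] > thr))
  }
  flo <- log[log$rule == "assay_floor", ]
  expect_equal(nrow(flo), round(0.02 * (500 - sum(out$wave == 3))))
  expect_true(all(flo$new < 0.02))
  expect_true(all(t1$s100b_3[match(flo$participant_id, t1$participant_id)] < 0.02))
})

test_that("PVS coupling shifts the rating distribution with serum change", {
  cfg <- updateConfig(zeroCovariateEffects(defaultGeneratorConfig(n = 8000, seed = 29)),
                      pvsCoupling = -0.4)
  tab <- generateCohort(cfg)
  chg <- tab$s100b_3 - tab$s100b_2
  expect_lt(cor(chg, tab$pvs_change), -0.05)
})
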