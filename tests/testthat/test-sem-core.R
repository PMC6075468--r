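# RAM algebra, FIML likelihood, fitting, standardization, bootstrap.

test_that("implied moments follow the RAM algebra on hand-evaluated cases", {
  # single indicator y = 1 * eta, var(eta) = 1, residual 0.25 -> var(y) = 1.25
  m <- semModel(c("y", "eta"), "y", rbind(
    data.frame(matrix = "A", from = "eta", to = "y", value = 1, label = NA),
    data.frame(matrix = "S", from = "eta", to = "eta", value = 1, label = NA),
    data.frame(matrix = "S", from = "y", to = "y", value = 0.25, label = NA)))
  mom <- impliedMoments(m)
  expect_equal(unname(mom$Sigma["y", "y"]), 1.25)

  # no paths: Sigma = diag(s), mu = m
  m2 <- semModel(c("a", "b"), c("a", "b"), rbind(
    data.frame(matrix = "S", from = "a", to = "a", value = 2, label = NA),
    data.frame(matrix = "S", from = "b", to = "b", value = 3, label = NA),
    data.frame(matrix = "M", from = NA, to = "a", value = 5, label = NA),
    data.frame(matrix = "M", from = NA, to = "b", value = -1, label = NA)))
  mom2 <- impliedMoments(m2)
  expect_equal(unname(mom2$Sigma), diag(c(2, 3)))
  expect_equal(unname(mom2$mu), c(5, -1))

  # latent change: y3 = eta2 + delta, var 4 + 1 + 2*(-1) = 3
  m3 <- semModel(c("y3", "eta2", "delta"), "y3", rbind(
    data.frame(matrix = "A", from = "eta2", to = "y3", value = 1, label = NA),
    data.frame(matrix = "A", from = "delta", to = "y3", value = 1, label = NA),
    data.frame(matrix = "S", from = "eta2", to = "eta2", value = 4, label = NA),
    data.frame(matrix = "S", from = "delta", to = "delta", value = 1, label = NA),
    data.frame(matrix = "S", from = "eta2", to = "delta", value = -1, label = NA)))
  expect_equal(unname(impliedMoments(m3)$Sigma["y3", "y3"]), 3)
})

test_that("casewise likelihood matches closed forms and the per-case oracle", {
  # one case, one variable, x = 0 under N(0,1)
  m <- semModel("x", "x", data.frame(matrix = "S", from = "x", to = "x",
                                     value = 1, label = NA))
  expect_equal(fimlLogLik(m, data = data.frame(x = 0)), -0.5 * log(2 * pi),
               tolerance = 1e-10)

  # two cases with disjoint observed masks: sum of univariate log densities
  m2 <- semModel(c("a", "b"), c("a", "b"), rbind(
    data.frame(matrix = "S", from = "a", to = "a", value = 2, label = NA),
    data.frame(matrix = "S", from = "b", to = "b", value = 0.5, label = NA),
    data.frame(matrix = "S", from = "a", to = "b", value = 0.3, label = NA),
    data.frame(matrix = "M", from = NA, to = "a", value = 1, label = NA)))
  d2 <- data.frame(a = c(0.7, NA), b = c(NA, -0.2))
  expect_equal(fimlLogLik(m2, data = d2),
               dnorm(0.7, 1, sqrt(2), log = TRUE) +
                 dnorm(-0.2, 0, sqrt(0.5), log = TRUE),
               tolerance = 1e-12)

  # pattern grouping equals the case-by-case computation under missingness
  set.seed(42)
  d3 <- as.data.frame(matrix(rnorm(300), 100, 3))
  names(d3) <- c("a", "b", "c")
  d3$a[sample(100, 30)] <- NA
  d3$b[sample(100, 25)] <- NA
  m3 <- saturatedModel(c("a", "b", "c"))
  m3 <- lcsem:::applyTheta(m3, lcsem:::semStart(m3, as.matrix(d3)))
  expect_equal(fimlLogLik(m3, data = d3), casewiseLogLik(m3, d3),
               tolerance = 1e-10)

  # row order invariance
  perm <- sample(nrow(d3))
  expect_equal(fimlLogLik(m3, data = d3), fimlLogLik(m3, data = d3[perm, ]),
               tolerance = 1e-10)
})

test_that("analytic score matches central finite differences", {
  set.seed(7)
  d <- bivariateData(80, 0.5, seed = 7, mx = 2, sx = 1.5)
  d$x[sample(80, 20)] <- NA
  spec <- changeScoreSpec("c", "x", "y")
  model <- addAuxiliary(buildUnivariateLcs(spec), "x2")
  d$x2 <- rnorm(80) + 0.3 * d$y
  X <- as.matrix(d[, semObserved(model)])
  labs <- unique(freeParamTable(model)$label)
  th <- lcsem:::semStart(model, X) * runif(length(labs), 0.9, 1.1)
  bp <- lcsem:::buildPatterns(X)
  ctx <- lcsem:::makeEvalContext(model)
  mo <- lcsem:::evalMoments(ctx, th)
  ga <- lcsem:::evalGradient(ctx, mo, bp$patterns)
  f <- function(t) {
    mo <- lcsem:::evalMoments(ctx, t)
    lcsem:::logLikFromMoments(mo$Sigma, mo$mu, bp$patterns)
  }
  gn <- vapply(seq_along(th), function(j) {
    h <- 1e-5 * max(1, abs(th[j]))
    tp <- th; tp[j] <- tp[j] + h
    tm <- th; tm[j] <- tm[j] - h
    (f(tp) - f(tm)) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(ga - gn) / (abs(gn) + 1)), 1e-6)
})

test_that("saturated fit recovers the ML sample moments with chi-square zero", {
  d <- bivariateData(150, 0.6, seed = 11, mx = 1, my = -2, sx = 2, sy = 0.5)
  fit <- semFit(twoVarModel(), d)
  expect_true(fit@converged)
  expect_lt(fit@chi2, 1e-6)
  expect_equal(fit@df, 0)
  n <- nrow(d)
  expect_equal(unname(fit@estimates["m_x"]), mean(d$x), tolerance = 1e-6)
  expect_equal(unname(fit@estimates["s_x_x"]), var(d$x) * (n - 1) / n,
               tolerance = 1e-5)
  expect_equal(unname(fit@estimates["s_x_y"]), cov(d$x, d$y) * (n - 1) / n,
               tolerance = 1e-5)
  # standardizing the saturated bivariate fit reproduces the Pearson r
  std <- standardizedSolution(fit)
  expect_equal(std$std[std$label == "s_x_y"], cor(d$x, d$y), tolerance = 1e-6)
})

test_that("complete-data FIML equals the closed-form multivariate normal ML", {
  d <- bivariateData(200, 0.4, seed = 3)
  fit <- semFit(twoVarModel(), d)
  expect_equal(fit@loglik, completeSaturatedLogLik(d), tolerance = 1e-8)
  expect_equal(fit@loglikSat, completeSaturatedLogLik(d), tolerance = 1e-8)
})

test_that("a generated covariance is recovered within Monte-Carlo error", {
  d <- bivariateData(5000, 0.5, seed = 21)
  fit <- semFit(twoVarModel(), d)
  se <- fit@se[["s_x_y"]]
  expect_true(is.finite(se) && se > 0)
  expect_lt(abs(fit@estimates[["s_x_y"]] - 0.5), 3 * se)
  # Wald z against the standard-error scale expected at this n
  expect_lt(se, 0.05)
})

test_that("equality constraints equal an explicitly reduced parameterization", {
  set.seed(5)
  d <- data.frame(a = rnorm(120, 1, 1.2))
  d$b <- d$a * 0.5 + rnorm(120, 1, 1)
  # model with tied variances of a-residual and b-residual
  tied <- semModel(c("a", "b"), c("a", "b"), rbind(
    data.frame(matrix = "A", from = "a", to = "b", value = 0, label = "beta"),
    data.frame(matrix = "S", from = "a", to = "a", value = 1, label = "v"),
    data.frame(matrix = "S", from = "b", to = "b", value = 1, label = "v"),
    data.frame(matrix = "M", from = NA, to = "a", value = 0, label = "ma"),
    data.frame(matrix = "M", from = NA, to = "b", value = 0, label = "mb")))
  fitTied <- semFit(tied, d, se = FALSE, indices = FALSE)
  # brute-force profile over the common variance (the reduced parameterization)
  nll <- function(p) {
    mom <- impliedMoments(lcsem:::applyTheta(tied, c(beta = p[1], v = exp(p[2]),
                                                     ma = p[3], mb = p[4])))
    -lcsem:::logLikFromMoments(mom$Sigma, mom$mu,
                               lcsem:::buildPatterns(as.matrix(d))$patterns)
  }
  red <- optim(c(0.5, 0, mean(d$a), mean(d$b)), nll, method = "BFGS")
  expect_equal(fitTied@loglik, -red$value, tolerance = 1e-7)
})

test_that("standardization uses model-implied SDs (correlation metric)", {
  # cov = 2, sd1 = sd2 = 2 -> standardized 0.5
  m <- semModel(c("p", "q"), c("p", "q"), rbind(
    data.frame(matrix = "S", from = "p", to = "p", value = 4, label = "vp"),
    data.frame(matrix = "S", from = "q", to = "q", value = 4, label = "vq"),
    data.frame(matrix = "S", from = "p", to = "q", value = 2, label = "cpq")))
  std <- standardizedSolution(m)
  expect_equal(std$std[std$label == "cpq"], 0.5)
  # standardized covariances of a proper fit are bounded by 1 in magnitude
  d <- bivariateData(400, 0.8, seed = 13)
  fit <- semFit(twoVarModel(), d)
  covs <- fit@standardized
  offdiag <- covs$matrix == "S" & covs$from != covs$to
  expect_true(all(abs(covs$std[offdiag]) <= 1 + 1e-10))
})

test_that("chi-square is invariant to rescaling a scale-free indicator", {
  pp <- quickCohort(250, seed = 31)
  m <- buildLatentFactorLcs(miniFactorSpec())
  f1 <- semFit(m, pp, se = FALSE)
  pp2 <- pp
  for (cl in c("fa_splenium_2", "fa_splenium_3")) pp2[[cl]] <- pp2[[cl]] * 1000
  f2 <- semFit(m, pp2, se = FALSE)
  expect_true(f1@converged && f2@converged)
  expect_equal(f1@chi2, f2@chi2, tolerance = 1e-3)
})

test_that("bias-corrected bootstrap behaves at its boundary cases", {
  # zero sampling variance: free mean of a constant column, fixed unit variance
  m <- semModel("z", "z", rbind(
    data.frame(matrix = "S", from = "z", to = "z", value = 1, label = NA),
    data.frame(matrix = "M", from = NA, to = "z", value = 0, label = "mz")))
  d <- data.frame(z = rep(5, 40))
  ci <- bootstrapCI(m, d, "mz", nBoot = 30, seed = 1, standardized = FALSE)
  expect_equal(ci$lower, ci$est)
  expect_equal(ci$upper, ci$est)

  # near-symmetric sampling distribution: z0 ~ 0, BC ~ plain percentile
  d2 <- bivariateData(300, 0.3, seed = 17)
  ci2 <- bootstrapCI(twoVarModel(), d2, "s_x_y", nBoot = 199, seed = 2,
                     standardized = FALSE)
  reps <- attr(ci2, "replicates")[, 1]
  perc <- quantile(reps, c(0.025, 0.975), names = FALSE)
  expect_lt(abs(ci2$lower - perc[1]), 0.02)
  expect_lt(abs(ci2$upper - perc[2]), 0.02)
  expect_true(ci2$lower < ci2$est && ci2$est < ci2$upper)
})

test_that("model JSON serialization round-trips losslessly", {
  serum <- changeScoreSpec("s100b", "s100b_2", "s100b_3")
  models <- list(
    buildUnivariateLcs(serum),
    buildBivariateLcs(serum, changeScoreSpec("wmh", "wmh_2", "wmh_3")),
    buildPvsVariant(serum),
    addCovariates(buildUnivariateLcs(serum),
                  list(s100b_2 = c("age_serum_2", "sex"))),
    buildLatentFactorLcs(miniFactorSpec(
      residualPairs = data.frame(ind1 = "genu", wave1 = 2,
                                 ind2 = "splenium", wave2 = 2))))
  for (m in models) {
    m2 <- readSemModel(writeSemModel(m))
    expect_identical(m2@variables, m@variables)
    expect_identical(m2@observed, m@observed)
    expect_equal(m2@A, m@A)
    expect_equal(m2@S, m@S)
    expect_equal(m2@M, m@M)
    expect_identical(m2@Alab, m@Alab)
    expect_identical(m2@Slab, m@Slab)
    expect_identical(unname(m2@Mlab), unname(m@Mlab))
  }
})

test_that("unidentified models and empty data are rejected up front", {
  m <- semModel(c("x"), "x", rbind(
    data.frame(matrix = "S", from = "x", to = "x", value = 1, label = "v1"),
    data.frame(matrix = "M", from = NA, to = "x", value = 0, label = "m1"),
    data.frame(matrix = "A", from = "x", to = "x", value = 0, label = "extra")))
  expect_error(semFit(m, data.frame(x = rnorm(10))), "not identified")
  expect_error(semFit(twoVarModel(), data.frame(x = numeric(0), y = numeric(0))),
               "empty")
})
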