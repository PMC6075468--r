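# Shared fixtures and independent oracles for the test suite.

# Independent brute-force Benjamini-Hochberg step-up oracle.
bruteForceBH <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (k in seq_len(m)) {
    adj[k] <- min(1, min(m * ps[k:m] / (k:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Case-by-case FIML log-likelihood oracle (no pattern grouping).
casewiseLogLik <- function(model, data) {
  mom <- impliedMoments(model)
  X <- as.matrix(as.data.frame(data)[, semObserved(model), drop = FALSE])
  ll <- 0
  for (i in seq_len(nrow(X))) {
    o <- which(!is.na(X[i, ]))
    if (!length(o)) next
    S <- mom$Sigma[o, o, drop = FALSE]
    mu <- mom$mu[o]
    ch <- chol(S)
    z <- backsolve(ch, X[i, o] - mu, transpose = TRUE)
    ll <- ll - 0.5 * (length(o) * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2))
  }
  ll
}

# Closed-form saturated log-likelihood for complete data (ML 1/n moments).
completeSaturatedLogLik <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  S <- crossprod(sweep(X, 2, colMeans(X))) / n
  -0.5 * n * (p * log(2 * pi) + determinant(S, logarithm = TRUE)$modulus[1] + p)
}

# Small bivariate normal sample generator for engine tests.
bivariateData <- function(n, rho, seed, mx = 0, my = 0, sx = 1, sy = 1) {
  set.seed(seed)
  x <- rnorm(n)
  y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  data.frame(x = mx + sx * x, y = my + sy * y)
}

# Two-variable saturated SemModel with a labelled covariance.
twoVarModel <- function() {
  saturatedModel(c("x", "y"))
}

# Small three-indicator latent change score factor spec on generated tract
# columns (cheap stand-in for the full seven-indicator model).
miniFactorSpec <- function(residualPairs = NULL,
                           invariance = "strong") {
  changeScoreSpec("gfa",
                  indicators2 = c("fa_genu_2", "fa_splenium_2", "fa_atr_2"),
                  indicators3 = c("fa_genu_3", "fa_splenium_3", "fa_atr_3"),
                  indicatorNames = c("genu", "splenium", "atr"),
                  invariance = invariance,
                  residualPairs = residualPairs)
}

# Generate, optionally thin out, and average a default-calibration cohort.
quickCohort <- function(n, seed, missing = FALSE, preprocess = TRUE) {
  cfg <- defaultGeneratorConfig(n = n, seed = seed)
  tab <- generateCohort(cfg)
  if (missing) tab <- applyMissingness(tab, cfg)
  if (preprocess) preprocessCohort(tab)$table else tab
}
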