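# Fitting a SemModel by FIML with deterministic start values.
#
# Start heuristic: observed-variable means/variances from the data; free
# directed paths start at 1 when the tail is latent (loadings) and 0 when it
# is observed (covariate regressions); covariances start at 0. A latent's
# mean/variance is seeded from an indicator that only that latent reaches
# (e.g. the wave-2 measure for a level factor); latent change components, which
# share all their indicators with the level, start at 0 mean and half the
# indicator variance. Start values contain no randomness, so fits are
# reproducible.

semStart <- function(model, X) {
  vars <- model@variables
  nv <- length(vars)
  obsIdx <- match(model@observed, vars)
  mns <- vrs <- stats::setNames(numeric(length(obsIdx)), model@observed)
  for (j in seq_along(obsIdx)) {
    x <- X[, j]; x <- x[!is.na(x)]
    mns[j] <- if (length(x)) mean(x) else 0
    vrs[j] <- if (length(x) > 1) max(stats::var(x), 1e-8) else 1
  }
  tab <- freeParamTable(model)
  labs <- unique(tab$label)
  # provisional A: free loadings at 1 (latent tail) / 0 (observed tail)
  A0 <- model@A
  for (k in seq_len(nrow(tab))) {
    if (tab$matrix[k] == "A") {
      A0[tab$row[k], tab$col[k]] <-
        if (vars[tab$col[k]] %in% model@observed) 0 else 1
    }
  }
  B0 <- tryCatch(solve(diag(nv) - A0), error = function(e) diag(nv))
  E0 <- B0[obsIdx, , drop = FALSE]
  nLatentSources <- vapply(seq_along(obsIdx), function(j) {
    sum(abs(E0[j, -obsIdx]) > 1e-12)
  }, numeric(1))
  exclusiveInd <- function(li) {
    hits <- which(abs(E0[, li]) > 1e-12)
    hits1 <- hits[nLatentSources[hits] == 1]
    if (length(hits1)) hits1[1L] else NA_integer_
  }
  anyInd <- function(li) {
    hits <- which(abs(E0[, li]) > 1e-12)
    if (length(hits)) hits[1L] else NA_integer_
  }
  hasLatentIn <- vapply(seq_len(nv), function(i) {
    any(abs(A0[i, -obsIdx]) > 1e-12)
  }, logical(1))
  start <- stats::setNames(numeric(length(labs)), labs)
  for (l in labs) {
    r <- tab[tab$label == l, ][1L, ]
    i <- r$row
    isObs <- vars[i] %in% model@observed
    if (r$matrix == "A") {
      start[l] <- if (vars[r$col] %in% model@observed) 0 else 1
    } else if (r$matrix == "M") {
      if (isObs) start[l] <- mns[vars[i]]
      else {
        j <- exclusiveInd(i)
        start[l] <- if (!is.na(j)) mns[j] / E0[j, i] else 0
      }
    } else if (r$row == r$col) {
      if (isObs) {
        start[l] <- if (hasLatentIn[i]) 0.5 * vrs[vars[i]] else vrs[vars[i]]
      } else {
        j <- exclusiveInd(i)
        if (!is.na(j)) start[l] <- vrs[j] / E0[j, i]^2
        else {
          j <- anyInd(i)
          start[l] <- if (!is.na(j)) 0.5 * vrs[j] else 1
        }
      }
    } else start[l] <- 0
  }
  start
}

#' Fit a path model by full-information maximum likelihood
#'
#' Maximizes the casewise multivariate-normal likelihood over the free
#' parameters (equality constraints via shared labels), computes the
#' saturated-model likelihood by EM on the same cases, the likelihood-ratio
#' chi-square `2 * (loglik_sat - loglik)`, standard errors from the inverse
#' observed information (numerically differentiated analytic score), fit
#' indices, and the standardized solution. Variances are unconstrained during
#' optimization; negative variance estimates (Heywood cases) are flagged in
#' `warnings`. The fit is deterministic: start values are data-derived with no
#' randomness.
#'
#' @param model a [SemModel-class].
#' @param data data.frame with the model's observed variables (missing values
#'   allowed; rows with no observed model variable are dropped).
#' @param start optional named start values (defaults to the built-in
#'   heuristic).
#' @param se compute observed-information standard errors (skip for speed in
#'   e.g. bootstrap replicates).
#' @param indices compute saturated/baseline models and fit indices.
#' @param maxIter optimizer iteration cap.
#' @return A [SemFit-class].
#' @export
semFit <- function(model, data, start = NULL, se = TRUE, indices = TRUE,
                   maxIter = 10000L) {
  X <- as.matrix(as.data.frame(data)[, model@observed, drop = FALSE])
  storage.mode(X) <- "double"
  if (nrow(X) == 0L) stop("data is empty")
  bp <- buildPatterns(X)
  pats <- bp$patterns
  p <- length(model@observed)
  tab <- freeParamTable(model)
  labs <- unique(tab$label)
  tab$labIdx <- match(tab$label, labs)
  npar <- length(labs)
  nMoments <- p * (p + 3) / 2
  df <- nMoments - npar
  if (df < 0) stop(sprintf("model not identified: %d free parameters exceed %d observed moments",
                           npar, nMoments))
  th0 <- semStart(model, X)
  if (!is.null(start)) {
    common <- intersect(names(start), labs)
    th0[common] <- start[common]
  }
  warn <- character(0)

  ctx <- makeEvalContext(model)
  obj <- function(th) {
    mo <- evalMoments(ctx, th)
    if (is.null(mo)) return(Inf)
    ll <- logLikFromMoments(mo$Sigma, mo$mu, pats)
    if (!is.finite(ll)) return(Inf)
    -ll
  }
  grad <- function(th) {
    mo <- evalMoments(ctx, th)
    if (is.null(mo)) return(rep(0, ctx$npar))
    -evalGradient(ctx, mo, pats)
  }
  # parameter typical magnitudes (from start-value implied total SDs) feed
  # PORT's scale vector; mixed units (serum ~1e-3, volumes ~1e3) otherwise
  # stall the quasi-Newton updates
  typ <- rep(1, ctx$npar)
  mo0 <- evalMoments(ctx, th0)
  if (!is.null(mo0)) {
    SigmaAll <- mo0$B %*% mo0$S %*% t(mo0$B)
    sdAll <- sqrt(pmax(diag(SigmaAll), 1e-12))
    tab1 <- tab[!duplicated(tab$label), , drop = FALSE]
    for (k in seq_len(nrow(tab1))) {
      i <- tab1$row[k]; j <- tab1$col[k]
      typ[tab1$labIdx[k]] <- switch(tab1$matrix[k],
        A = sdAll[i] / sdAll[j],
        S = sdAll[i] * sdAll[j],
        M = max(sdAll[i], abs(mo0$M[i]), 1e-6))
    }
    typ <- pmax(typ, 1e-12)
  }
  runOpt <- function(par) {
    stats::nlminb(par, obj, gradient = grad, scale = 1 / typ,
                  control = list(iter.max = maxIter, eval.max = 4L * maxIter,
                                 rel.tol = 1e-11, x.tol = 1e-14))
  }
  scaledGnorm <- function(par, value) max(abs(grad(par) * typ)) / max(1, abs(value))
  opt <- runOpt(th0)
  nIter <- opt$iterations
  # PORT occasionally reports "false convergence" at the optimum; a restart
  # resets its Hessian approximation and polishes the solution
  tries <- 0L
  while (opt$convergence != 0 && tries < 2L &&
         scaledGnorm(opt$par, opt$objective) > 1e-6) {
    tries <- tries + 1L
    opt2 <- runOpt(opt$par)
    nIter <- nIter + opt2$iterations
    if (opt2$objective <= opt$objective) opt <- opt2 else break
  }
  # certify the stationary point: a quasi-Newton polish from the solution
  # must not improve the objective materially
  bestPar <- opt$par
  bestVal <- opt$objective
  pol <- tryCatch(
    stats::optim(bestPar, obj, grad, method = "L-BFGS-B",
                 control = list(parscale = typ, maxit = 500, factr = 1e5)),
    error = function(e) NULL)
  polGain <- 0
  if (!is.null(pol) && is.finite(pol$value) && pol$value < bestVal) {
    polGain <- bestVal - pol$value
    bestPar <- pol$par
    bestVal <- pol$value
  }
  est <- stats::setNames(bestPar, labs)
  fitted <- applyTheta(model, est)
  loglik <- -bestVal
  gnorm <- scaledGnorm(bestPar, loglik)
  converged <- opt$convergence == 0 || gnorm < 1e-4 ||
    polGain < 1e-7 * max(1, abs(loglik))
  if (!converged) {
    warn <- c(warn, sprintf("optimizer did not converge (%s; scaled gradient %.2e)",
                            opt$message, gnorm))
  }
  # Heywood check: negative free variances
  diagFree <- tab[tab$matrix == "S" & tab$row == tab$col, ]
  if (nrow(diagFree)) {
    neg <- vapply(seq_len(nrow(diagFree)), function(k) {
      fitted@S[diagFree$row[k], diagFree$row[k]] < 0
    }, logical(1))
    if (any(neg)) {
      warn <- c(warn, paste0("negative variance estimate (Heywood case): ",
                             paste(unique(diagFree$label[neg]), collapse = ", ")))
    }
  }

  seVec <- stats::setNames(rep(NA_real_, npar), labs)
  vc <- matrix(NA_real_, npar, npar, dimnames = list(labs, labs))
  if (se && npar > 0) {
    info <- tryCatch(numJacobian(grad, opt$par), error = function(e) NULL)
    if (!is.null(info)) {
      info <- (info + t(info)) / 2
      vc0 <- tryCatch(solve(info), error = function(e) NULL)
      if (!is.null(vc0) && all(is.finite(diag(vc0))) && all(diag(vc0) > -1e-8)) {
        vc <- vc0
        dimnames(vc) <- list(labs, labs)
        seVec <- sqrt(pmax(diag(vc), 0))
      } else warn <- c(warn, "observed information not invertible; standard errors unavailable")
    }
  }

  llSat <- llBase <- NA_real_
  chi2 <- pChi2 <- chi2B <- dfB <- rmsea <- cfi <- tli <- srmr <- NA_real_
  nIter <- as.integer(nIter)
  if (indices) {
    sat <- emSaturated(X)
    llSat <- sat$loglik
    chi2 <- max(0, 2 * (llSat - loglik))
    if (2 * (llSat - loglik) < -1e-5 * max(1, abs(llSat))) {
      warn <- c(warn, "fitted log-likelihood exceeds saturated log-likelihood beyond tolerance")
    }
    pChi2 <- if (df > 0) stats::pchisq(chi2, df, lower.tail = FALSE) else NA_real_
    base <- baselineLogLik(X)
    llBase <- base$loglik
    chi2B <- max(0, 2 * (llSat - llBase))
    dfB <- nMoments - base$npar
    mom <- impliedMoments(fitted)
    fi <- fitIndices(chi2, df, chi2B, dfB, bp$nUsed, sat$Sigma, mom$Sigma)
    rmsea <- fi$rmsea; cfi <- fi$cfi; tli <- fi$tli; srmr <- fi$srmr
  }

  std <- standardizeModel(fitted)
  methods::new("SemFit",
    model = fitted, estimates = est, se = seVec, vcov = vc,
    loglik = loglik, loglikSat = llSat, loglikBase = llBase,
    nUsed = as.integer(bp$nUsed), nPatterns = as.integer(length(pats)),
    npar = as.integer(npar),
    chi2 = chi2, df = as.numeric(df), pChi2 = pChi2,
    chi2Base = chi2B, dfBase = dfB,
    rmsea = rmsea, cfi = cfi, tli = tli, srmr = srmr,
    converged = converged, nIterations = nIter,
    standardized = std, warnings = warn)
}

# Standardize all free parameters by the model-implied total SDs:
# covariances -> correlation metric, paths/loadings by sd(tail)/sd(head).
standardizeModel <- function(model) {
  nv <- length(model@variables)
  B <- solve(diag(nv) - model@A)
  SigmaAll <- B %*% model@S %*% t(B)
  sdv <- sqrt(pmax(diag(SigmaAll), 0))
  tab <- freeParamTable(model)
  if (!nrow(tab)) {
    return(data.frame(label = character(0), matrix = character(0),
                      from = character(0), to = character(0),
                      est = numeric(0), std = numeric(0)))
  }
  est <- std <- numeric(nrow(tab))
  from <- to <- character(nrow(tab))
  flagged <- FALSE
  for (k in seq_len(nrow(tab))) {
    i <- tab$row[k]; j <- tab$col[k]
    if (tab$matrix[k] == "A") {
      est[k] <- model@A[i, j]
      std[k] <- if (sdv[i] > 0) est[k] * sdv[j] / sdv[i] else NA_real_
      from[k] <- model@variables[j]; to[k] <- model@variables[i]
    } else if (tab$matrix[k] == "S") {
      est[k] <- model@S[i, j]
      std[k] <- if (sdv[i] > 0 && sdv[j] > 0) est[k] / (sdv[i] * sdv[j]) else NA_real_
      from[k] <- model@variables[j]; to[k] <- model@variables[i]
    } else {
      est[k] <- model@M[i]
      std[k] <- if (sdv[i] > 0) est[k] / sdv[i] else NA_real_
      from[k] <- NA_character_; to[k] <- model@variables[i]
    }
    if (is.na(std[k])) flagged <- TRUE
  }
  out <- data.frame(label = tab$label, matrix = tab$matrix, from = from,
                    to = to, est = est, std = std)
  if (flagged) attr(out, "undefined") <- TRUE
  out
}

#' Standardized solution of a fitted model
#'
#' Covariances are divided by the product of the involved variables'
#' model-implied total standard deviations (correlation metric); directed
#' paths and loadings are rescaled by sd(tail)/sd(head). Entries with a zero
#' implied variance are returned as `NA` (flagged via the `"undefined"`
#' attribute), never dropped.
#'
#' @param fit a [SemFit-class] (or [SemModel-class] with values in place).
#' @return data.frame with columns `label`, `matrix`, `from`, `to`, `est`,
#'   `std`.
#' @export
standardizedSolution <- function(fit) {
  if (methods::is(fit, "SemFit")) standardizeModel(fit@model)
  else standardizeModel(fit)
}

#' Saturated (unstructured) model over a set of variables
#'
#' All means, variances and covariances free; zero degrees of freedom.
#'
#' @param variables character vector of observed variable names.
#' @return A [SemModel-class].
#' @export
saturatedModel <- function(variables) {
  edges <- list()
  for (i in seq_along(variables)) {
    edges[[length(edges) + 1L]] <- data.frame(
      matrix = "M", from = NA, to = variables[i], value = 0,
      label = paste0("m_", variables[i]))
    for (j in seq_len(i)) {
      edges[[length(edges) + 1L]] <- data.frame(
        matrix = "S", from = variables[j], to = variables[i],
        value = ifelse(i == j, 1, 0),
        label = paste0("s_", variables[j], "_", variables[i]))
    }
  }
  semModel(variables, variables, do.call(rbind, edges))
}

#' @export
setMethod("show", "SemFit", function(object) {
  cat(sprintf("SemFit: %d cases (%d missingness patterns), %d free parameters\n",
              object@nUsed, object@nPatterns, object@npar))
  cat(sprintf("  loglik %.3f | chi2(%g) = %.3f, p = %.3g\n",
              object@loglik, object@df, object@chi2, object@pChi2))
  cat(sprintf("  RMSEA %.3f  CFI %.3f  TLI %.3f  SRMR %.3f\n",
              object@rmsea, object@cfi, object@tli, object@srmr))
  if (!object@converged) cat("  WARNING: not converged\n")
  if (length(object@warnings)) cat("  warnings:", paste(object@warnings, collapse = "; "), "\n")
  invisible(object)
})

#' @export
setMethod("coef", "SemFit", function(object, ...) object@estimates)

#' @export
setMethod("logLik", "SemFit", function(object, ...) {
  structure(object@loglik, df = object@npar, nobs = object@nUsed, class = "logLik")
})

#' Extract fit statistics from a fitted model
#'
#' @param fit a [SemFit-class].
#' @return named list: chi2, df, pChi2, rmsea, cfi, tli, srmr, loglik, npar,
#'   nUsed, converged.
#' @export
fitMeasures <- function(fit) {
  list(chi2 = fit@chi2, df = fit@df, pChi2 = fit@pChi2,
       rmsea = fit@rmsea, cfi = fit@cfi, tli = fit@tli, srmr = fit@srmr,
       loglik = fit@loglik, npar = fit@npar, nUsed = fit@nUsed,
       converged = fit@converged)
}
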