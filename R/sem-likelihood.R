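# RAM algebra and full-information maximum likelihood.
#
# Implied moments follow Sigma = F (I-A)^-1 S (I-A)^-T F', mu = F (I-A)^-1 M.
# The casewise likelihood is evaluated per missingness pattern using pattern
# sufficient statistics (count, mean, raw cross-product); grouping is an
# optimization only and equals the case-by-case sum. The analytic score chains
# the per-pattern derivatives w.r.t. (Sigma, mu) through the RAM structure,
# which keeps the optimizer cost independent of the parameter count.

#' Model-implied moments of the observed variables
#'
#' @param model a [SemModel-class].
#' @param theta optional parameter vector (named by free label); defaults to
#'   the values stored in the model matrices.
#' @return list with `Sigma` (covariance) and `mu` (means) over
#'   [semObserved()] variables.
#' @export
impliedMoments <- function(model, theta = NULL) {
  if (!is.null(theta)) model <- applyTheta(model, theta)
  n <- length(model@variables)
  ImA <- diag(n) - model@A
  B <- tryCatch(solve(ImA), error = function(e) {
    stop("(I - A) is singular at this parameterization: ", conditionMessage(e))
  })
  obs <- match(model@observed, model@variables)
  E <- B[obs, , drop = FALSE]
  Sigma <- E %*% model@S %*% t(E)
  Sigma <- (Sigma + t(Sigma)) / 2
  mu <- as.vector(E %*% model@M)
  dimnames(Sigma) <- list(model@observed, model@observed)
  names(mu) <- model@observed
  list(Sigma = Sigma, mu = mu)
}

# Group rows of the observed-data matrix by missingness pattern. Rows with no
# observed values are dropped (counted). Returns pattern sufficient stats.
buildPatterns <- function(X) {
  n <- nrow(X)
  obsmask <- !is.na(X)
  keep <- rowSums(obsmask) > 0L
  X <- X[keep, , drop = FALSE]
  obsmask <- obsmask[keep, , drop = FALSE]
  key <- apply(obsmask, 1L, function(r) paste(which(r), collapse = ","))
  groups <- split(seq_len(nrow(X)), key)
  pats <- lapply(groups, function(idx) {
    o <- which(obsmask[idx[1L], ])
    Xi <- X[idx, o, drop = FALSE]
    list(obs = o, n = length(idx),
         xbar = colMeans(Xi),
         sxx = crossprod(Xi),
         rows = idx)
  })
  list(patterns = unname(pats), nUsed = nrow(X), nDropped = n - nrow(X))
}

# Core FIML log-likelihood given implied moments. Returns -Inf when any
# pattern-marginal covariance is not positive definite.
logLikFromMoments <- function(Sigma, mu, pats) {
  ll <- 0
  for (p in pats) {
    o <- p$obs
    So <- Sigma[o, o, drop = FALSE]
    ch <- tryCatch(chol(So), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    muo <- mu[o]
    ldet <- 2 * sum(log(diag(ch)))
    Sinv <- chol2inv(ch)
    C <- p$sxx - p$n * (outer(p$xbar, muo) + outer(muo, p$xbar)) +
      p$n * outer(muo, muo)
    ll <- ll - 0.5 * (p$n * (length(o) * log(2 * pi) + ldet) + sum(Sinv * C))
  }
  ll
}

#' Casewise (FIML) log-likelihood of a path model
#'
#' Sums, over cases, the multivariate-normal log-density of each case's
#' observed subset under the model-implied moments. Cases with no observed
#' model variable are excluded.
#'
#' @inheritParams impliedMoments
#' @param data data.frame or matrix containing the model's observed variables.
#' @return the log-likelihood (scalar); `-Inf` if a pattern-marginal
#'   covariance is not positive definite (with a warning).
#' @export
fimlLogLik <- function(model, theta = NULL, data) {
  mom <- impliedMoments(model, theta)
  X <- as.matrix(as.data.frame(data)[, model@observed, drop = FALSE])
  storage.mode(X) <- "double"
  bp <- buildPatterns(X)
  ll <- logLikFromMoments(mom$Sigma, mom$mu, bp$patterns)
  if (!is.finite(ll)) warning("implied pattern-marginal covariance not positive definite")
  ll
}

# Analytic score of the FIML log-likelihood w.r.t. the free-parameter labels.
# Uses dl/dSigma = -n/2 Sinv + 1/2 Sinv C Sinv per pattern (embedded into the
# full observed block) and the RAM chain rule:
#   dl/dS = E' G E (off-diagonal free entries doubled),
#   dl/dM = E' g,
#   dl/dA = 2 E' G E S B' + E' g M' B'.
logLikGradient <- function(model, pats, ptab, labs) {
  n <- length(model@variables)
  ImA <- diag(n) - model@A
  B <- tryCatch(solve(ImA), error = function(e) NULL)
  if (is.null(B)) return(rep(0, length(labs)))
  obs <- match(model@observed, model@variables)
  E <- B[obs, , drop = FALSE]
  Sigma <- E %*% model@S %*% t(E)
  mu <- as.vector(E %*% model@M)
  p <- length(obs)
  G <- matrix(0, p, p)
  g <- numeric(p)
  for (pt in pats) {
    o <- pt$obs
    So <- Sigma[o, o, drop = FALSE]
    ch <- tryCatch(chol(So), error = function(e) NULL)
    if (is.null(ch)) return(rep(0, length(labs)))
    Sinv <- chol2inv(ch)
    muo <- mu[o]
    C <- pt$sxx - pt$n * (outer(pt$xbar, muo) + outer(muo, pt$xbar)) +
      pt$n * outer(muo, muo)
    G[o, o] <- G[o, o] - 0.5 * pt$n * Sinv + 0.5 * Sinv %*% C %*% Sinv
    g[o] <- g[o] + as.vector(Sinv %*% (pt$n * (pt$xbar - muo)))
  }
  EtG <- t(E) %*% G
  rawS <- EtG %*% E
  gM <- as.vector(t(E) %*% g)
  gA <- 2 * rawS %*% model@S %*% t(B) + (t(E) %*% g) %*% t(model@M) %*% t(B)
  grad <- numeric(length(labs))
  for (k in seq_len(nrow(ptab))) {
    li <- ptab$labIdx[k]
    grad[li] <- grad[li] + switch(ptab$matrix[k],
      A = gA[ptab$row[k], ptab$col[k]],
      S = if (ptab$row[k] == ptab$col[k]) rawS[ptab$row[k], ptab$row[k]]
          else 2 * rawS[ptab$row[k], ptab$col[k]],
      M = gM[ptab$row[k]])
  }
  grad
}

# Precomputed evaluation context for the optimizer hot path: plain matrices
# plus linear indices so a parameter vector can be written into (A, S, M) by
# vectorized assignment instead of S4 slot mutation.
makeEvalContext <- function(model) {
  n <- length(model@variables)
  tab <- freeParamTable(model)
  labs <- unique(tab$label)
  tab$labIdx <- match(tab$label, labs)
  aTab <- tab[tab$matrix == "A", , drop = FALSE]
  sTab <- tab[tab$matrix == "S", , drop = FALSE]
  mTab <- tab[tab$matrix == "M", , drop = FALSE]
  list(
    n = n, labs = labs, npar = length(labs),
    A0 = model@A, S0 = model@S, M0 = model@M,
    obsIdx = match(model@observed, model@variables),
    aLin = (aTab$col - 1L) * n + aTab$row, aLab = aTab$labIdx,
    sLin1 = (sTab$col - 1L) * n + sTab$row,
    sLin2 = (sTab$row - 1L) * n + sTab$col,
    sLab = sTab$labIdx,
    sFac = ifelse(sTab$row == sTab$col, 1, 2),
    mIdx = mTab$row, mLab = mTab$labIdx,
    In = diag(n)
  )
}

# Fill matrices and compute implied moments; NULL if (I - A) is singular.
evalMoments <- function(ctx, th) {
  A <- ctx$A0; S <- ctx$S0; M <- ctx$M0
  A[ctx$aLin] <- th[ctx$aLab]
  S[ctx$sLin1] <- th[ctx$sLab]
  S[ctx$sLin2] <- th[ctx$sLab]
  M[ctx$mIdx] <- th[ctx$mLab]
  B <- tryCatch(solve(ctx$In - A), error = function(e) NULL)
  if (is.null(B)) return(NULL)
  E <- B[ctx$obsIdx, , drop = FALSE]
  Sigma <- E %*% S %*% t(E)
  list(Sigma = (Sigma + t(Sigma)) / 2, mu = as.vector(E %*% M),
       B = B, E = E, S = S, M = M)
}

# Analytic score at an evalMoments() result (same algebra as logLikGradient).
evalGradient <- function(ctx, mo, pats) {
  p <- length(ctx$obsIdx)
  G <- matrix(0, p, p)
  g <- numeric(p)
  for (pt in pats) {
    o <- pt$obs
    ch <- tryCatch(chol(mo$Sigma[o, o, drop = FALSE]), error = function(e) NULL)
    if (is.null(ch)) return(rep(0, ctx$npar))
    Sinv <- chol2inv(ch)
    muo <- mo$mu[o]
    C <- pt$sxx - pt$n * (outer(pt$xbar, muo) + outer(muo, pt$xbar)) +
      pt$n * outer(muo, muo)
    G[o, o] <- G[o, o] - 0.5 * pt$n * Sinv + 0.5 * Sinv %*% C %*% Sinv
    g[o] <- g[o] + as.vector(Sinv %*% (pt$n * (pt$xbar - muo)))
  }
  Etg <- t(mo$E) %*% g
  rawS <- t(mo$E) %*% G %*% mo$E
  gA <- 2 * rawS %*% mo$S %*% t(mo$B) + Etg %*% t(mo$M) %*% t(mo$B)
  gM <- as.vector(Etg)
  grad <- numeric(ctx$npar)
  addContrib <- function(grad, vals, lab) {
    s <- rowsum(vals, lab)
    ix <- as.integer(rownames(s))
    grad[ix] <- grad[ix] + s[, 1L]
    grad
  }
  if (length(ctx$aLin)) grad <- addContrib(grad, gA[ctx$aLin], ctx$aLab)
  if (length(ctx$sLin1)) grad <- addContrib(grad, rawS[ctx$sLin1] * ctx$sFac, ctx$sLab)
  if (length(ctx$mIdx)) grad <- addContrib(grad, gM[ctx$mIdx], ctx$mLab)
  grad
}

# EM estimation of the unstructured (saturated) multivariate-normal mean and
# covariance under arbitrary missingness; ML (1/n) divisors. Closed form for
# complete data.
emSaturated <- function(X, tol = 1e-9, maxIter = 1000L) {
  bp <- buildPatterns(X)
  pats <- bp$patterns
  n <- bp$nUsed
  p <- ncol(X)
  if (length(pats) == 1L && length(pats[[1L]]$obs) == p) {
    mu <- pats[[1L]]$xbar
    Sigma <- pats[[1L]]$sxx / n - outer(mu, mu)
    Sigma <- (Sigma + t(Sigma)) / 2
    ll <- logLikFromMoments(Sigma, mu, pats)
    return(list(mu = mu, Sigma = Sigma, loglik = ll, iterations = 0L,
                nUsed = n, nPatterns = 1L))
  }
  mu <- numeric(p)
  v <- numeric(p)
  cnt <- numeric(p)
  for (pt in pats) {
    mu[pt$obs] <- mu[pt$obs] + pt$n * pt$xbar
    v[pt$obs] <- v[pt$obs] + diag(pt$sxx)
    cnt[pt$obs] <- cnt[pt$obs] + pt$n
  }
  if (any(cnt == 0)) stop("a model variable has no observed values")
  mu <- mu / cnt
  v <- pmax(v / cnt - mu^2, 1e-10)
  Sigma <- diag(v, p)
  llOld <- -Inf
  iter <- 0L
  repeat {
    iter <- iter + 1L
    sx <- numeric(p)
    sxx <- matrix(0, p, p)
    for (pt in pats) {
      o <- pt$obs
      m <- setdiff(seq_len(p), o)
      Soo <- Sigma[o, o, drop = FALSE]
      ch <- chol(Soo)
      Sinv <- chol2inv(ch)
      if (length(m)) {
        coef <- Sigma[m, o, drop = FALSE] %*% Sinv
        condCov <- Sigma[m, m, drop = FALSE] - coef %*% Sigma[o, m, drop = FALSE]
        mhat_bar <- mu[m] + as.vector(coef %*% (pt$xbar - mu[o]))
        # E[x_m x_o'] summed: coef-based; build from pattern sufficient stats
        dev <- pt$xbar - mu[o]
        Cm <- pt$sxx - pt$n * outer(pt$xbar, mu[o]) - pt$n * outer(mu[o], pt$xbar) +
          pt$n * outer(mu[o], mu[o])
        # sum over cases of xhat_m x_o' = n mu_m xbar_o' + coef (sxx - n mu_o xbar_o')
        sxo <- pt$n * outer(mu[m], pt$xbar) + coef %*% (pt$sxx - pt$n * outer(mu[o], pt$xbar))
        # sum of xhat_m xhat_m' + n condCov
        smm <- pt$n * outer(mu[m], mu[m]) +
          pt$n * (outer(mu[m], as.vector(coef %*% dev)) +
                  outer(as.vector(coef %*% dev), mu[m])) +
          coef %*% Cm %*% t(coef) + pt$n * condCov
        sx[o] <- sx[o] + pt$n * pt$xbar
        sx[m] <- sx[m] + pt$n * mu[m] + pt$n * as.vector(coef %*% dev)
        sxx[o, o] <- sxx[o, o] + pt$sxx
        sxx[m, o] <- sxx[m, o] + sxo
        sxx[o, m] <- sxx[o, m] + t(sxo)
        sxx[m, m] <- sxx[m, m] + smm
      } else {
        sx[o] <- sx[o] + pt$n * pt$xbar
        sxx[o, o] <- sxx[o, o] + pt$sxx
      }
    }
    mu <- sx / n
    Sigma <- sxx / n - outer(mu, mu)
    Sigma <- (Sigma + t(Sigma)) / 2
    ll <- logLikFromMoments(Sigma, mu, pats)
    if (is.finite(ll) && abs(ll - llOld) < tol * (abs(ll) + 1)) break
    if (iter >= maxIter) {
      warning("saturated-model EM did not fully converge")
      break
    }
    llOld <- ll
  }
  list(mu = mu, Sigma = Sigma, loglik = ll, iterations = iter,
       nUsed = n, nPatterns = length(pats))
}

# Independence (baseline) model under FIML: the likelihood factorizes, so
# per-variable ML on available cases is the exact FIML solution.
baselineLogLik <- function(X) {
  p <- ncol(X)
  ll <- 0
  for (j in seq_len(p)) {
    x <- X[, j]
    x <- x[!is.na(x)]
    m <- mean(x)
    v <- mean((x - m)^2)
    if (v <= 0) {
      warning("zero variance in baseline model for column ", j)
      v <- 1e-10
    }
    ll <- ll + sum(stats::dnorm(x, m, sqrt(v), log = TRUE))
  }
  list(loglik = ll, npar = 2L * p)
}
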