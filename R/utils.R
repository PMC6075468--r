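#' @keywords internal
#' @import methods
#' @importFrom stats coef logLik
"_PACKAGE"

# Run code under a local RNG state: seeds the generator, restores the caller's
# .Random.seed on exit so package functions don't perturb user-level randomness.
withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Normal draws truncated at +/- k SDs (inverse-CDF; deterministic given RNG state).
rnormTrunc <- function(n, mean, sd, k = 3) {
  lo <- stats::pnorm(-k)
  hi <- stats::pnorm(k)
  mean + sd * stats::qnorm(stats::runif(n, lo, hi))
}

# Multivariate normal draw via eigen square root; tolerates semidefinite
# covariance (zero variances are legal generator settings).
rmvnormEig <- function(n, mean, sigma) {
  p <- length(mean)
  if (p == 0L) return(matrix(numeric(0), n, 0))
  eg <- eigen(sigma, symmetric = TRUE)
  vals <- eg$values
  if (any(vals < -1e-8 * max(abs(vals), 1))) {
    stop("covariance matrix is not positive semidefinite")
  }
  vals[vals < 0] <- 0
  rt <- eg$vectors %*% (sqrt(vals) * t(eg$vectors))
  z <- matrix(stats::rnorm(n * p), n, p)
  out <- z %*% rt
  sweep(out, 2, mean, "+")
}

isPsd <- function(m, tol = 1e-8) {
  vals <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  all(vals >= -tol * max(abs(vals), 1))
}

# Central-difference Jacobian of a vector-valued function (used for the
# observed information via the analytic score).
numJacobian <- function(f, x, eps = 1e-5) {
  f0 <- f(x)
  J <- matrix(NA_real_, length(f0), length(x))
  for (j in seq_along(x)) {
    h <- eps * max(1, abs(x[j]))
    xp <- x; xp[j] <- xp[j] + h
    xm <- x; xm[j] <- xm[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

`%||%` <- function(a, b) if (is.null(a)) b else a
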