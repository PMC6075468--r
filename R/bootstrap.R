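#' Bias-corrected bootstrap confidence intervals for model parameters
#'
#' Resamples participants (rows) with replacement, refits the model on each
#' replicate (starting from the point estimates), and forms bias-corrected
#' percentile intervals: with `z0 = qnorm(P(boot < point))` and
#' `za = qnorm((1 + conf) / 2)`, the endpoints are the bootstrap quantiles at
#' `pnorm(2 * z0 -/+ za)`. Standardized statistics use the standardized
#' solution of each replicate. Non-converged replicates are dropped and
#' counted; more than 20% non-convergence attaches a warning. A degenerate
#' bootstrap distribution collapses the interval to the point estimate.
#'
#' @param model a [SemModel-class].
#' @param data data.frame of observed variables.
#' @param labels free-parameter labels to bootstrap.
#' @param nBoot number of replicates (the headline analysis uses 1000).
#' @param conf confidence level.
#' @param seed RNG seed (replicate resampling is deterministic given it).
#' @param standardized bootstrap the standardized (correlation-metric)
#'   estimates instead of the raw covariances.
#' @param pointFit optional pre-computed [SemFit-class] of `model` on `data`.
#' @return data.frame with columns `label`, `est`, `lower`, `upper`,
#'   `nConverged`, plus attribute `"warnings"`.
#' @export
bootstrapCI <- function(model, data, labels, nBoot = 1000L, conf = 0.95,
                        seed = NULL, standardized = TRUE, pointFit = NULL) {
  stopifnot(nBoot >= 1)
  data <- as.data.frame(data)
  if (is.null(pointFit)) {
    pointFit <- semFit(model, data, se = FALSE, indices = FALSE)
  }
  if (!pointFit@converged) stop("point fit did not converge; no bootstrap performed")
  pointVal <- extractStats(pointFit, labels, standardized)
  boots <- matrix(NA_real_, nBoot, length(labels),
                  dimnames = list(NULL, labels))
  nConv <- 0L
  withSeed(seed, {
    for (b in seq_len(nBoot)) {
      idx <- sample.int(nrow(data), nrow(data), replace = TRUE)
      fb <- tryCatch(
        semFit(model, data[idx, , drop = FALSE], start = pointFit@estimates,
               se = FALSE, indices = FALSE),
        error = function(e) NULL)
      if (!is.null(fb) && fb@converged) {
        nConv <- nConv + 1L
        boots[b, ] <- extractStats(fb, labels, standardized)
      }
    }
  })
  warns <- character(0)
  if (nConv < 0.8 * nBoot) {
    warns <- c(warns, sprintf("%d of %d bootstrap replicates failed to converge",
                              nBoot - nConv, nBoot))
  }
  za <- stats::qnorm((1 + conf) / 2)
  out <- data.frame(label = labels, est = pointVal,
                    lower = NA_real_, upper = NA_real_,
                    nConverged = nConv)
  for (j in seq_along(labels)) {
    bj <- boots[, j]
    bj <- bj[!is.na(bj)]
    if (!length(bj)) next
    if (stats::sd(bj) == 0) {
      out$lower[j] <- out$upper[j] <- pointVal[j]
      next
    }
    propLess <- mean(bj < pointVal[j])
    # guard the probit at the boundary
    propLess <- min(max(propLess, 0.5 / length(bj)), 1 - 0.5 / length(bj))
    z0 <- stats::qnorm(propLess)
    pl <- stats::pnorm(2 * z0 - za)
    pu <- stats::pnorm(2 * z0 + za)
    qs <- stats::quantile(bj, c(pl, pu), names = FALSE, type = 7)
    out$lower[j] <- qs[1]
    out$upper[j] <- qs[2]
  }
  attr(out, "warnings") <- warns
  attr(out, "replicates") <- boots
  out
}

extractStats <- function(fit, labels, standardized) {
  if (standardized) {
    std <- fit@standardized
    vapply(labels, function(l) {
      v <- std$std[std$label == l]
      if (!length(v)) NA_real_ else v[1L]
    }, numeric(1))
  } else {
    fit@estimates[labels]
  }
}
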