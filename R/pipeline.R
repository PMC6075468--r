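# Orchestration: descriptives, attrition checks, the association suite across
# outcomes, and FDR-controlled reporting.

#' Welch two-sample comparison with Cohen's d
#'
#' Welch t statistic with Satterthwaite degrees of freedom and a two-sided p;
#' Cohen's d uses the pooled-SD two-sample formula (df-weighted).
#'
#' @param x,y numeric samples (NAs dropped); each needs >= 2 values.
#' @param labels optional group labels.
#' @return data.frame with group summaries, `t`, `df`, `p`, `d`.
#' @export
compareGroups <- function(x, y, labels = c("x", "y")) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) {
    stop("degenerate group: ", labels[which.min(c(length(x), length(y)))],
         " has fewer than 2 values")
  }
  n1 <- length(x); n2 <- length(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  md <- mean(x) - mean(y)
  sp <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
  if (v1 == 0 && v2 == 0) {
    tt <- if (md == 0) 0 else sign(md) * Inf
    if (is.infinite(tt)) warning("zero variance in both samples with unequal means")
    dfw <- n1 + n2 - 2
    p <- if (md == 0) 1 else 0
    d <- if (md == 0) 0 else sign(md) * Inf
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    tt <- md / se
    dfw <- se^4 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    p <- 2 * stats::pt(-abs(tt), dfw)
    d <- md / sp
  }
  data.frame(group_x = labels[1], group_y = labels[2],
             mean_x = mean(x), sd_x = sqrt(v1), n_x = n1,
             mean_y = mean(y), sd_y = sqrt(v2), n_y = n2,
             t = tt, df = dfw, p = p, d = d)
}

#' Pearson correlation on pairwise-complete cases
#'
#' @param x,y numeric vectors.
#' @return list with `r`, `p` (t transform), `n`; `r = NA` with a warning for
#'   degenerate (constant) input.
#' @export
pearsonR <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("correlation undefined (constant input or n < 3)")
    return(list(r = NA_real_, p = NA_real_, n = n))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up adjustment: `p_(k)` becomes `min over j >= k of m * p_(j) / j`,
#' capped at 1; rejection where the adjusted p-value is at most `q`.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @param q FDR threshold.
#' @return list with `adjusted` and logical `reject`, in input order.
#' @export
bhFdr <- function(pvalues, q = 0.05) {
  if (!length(pvalues)) return(list(adjusted = numeric(0), reject = logical(0)))
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  adjusted <- stats::p.adjust(pvalues, method = "BH")
  list(adjusted = adjusted, reject = adjusted <= q)
}

outcomeSpec <- function(outcome) {
  tractsInd <- function(metric) {
    list(ind2 = sprintf("%s_%s_2", metric, tractNames()),
         ind3 = sprintf("%s_%s_3", metric, tractNames()),
         names = tractNames())
  }
  if (grepl("^tract:", outcome)) {
    parts <- strsplit(outcome, ":", fixed = TRUE)[[1]]
    if (length(parts) != 3 || !parts[2] %in% tractNames() ||
        !parts[3] %in% c("fa", "md")) {
      stop("tract outcome must be 'tract:<name>:<fa|md>'")
    }
    return(list(kind = "single", construct = paste0(parts[3], "_", parts[2]),
                ind2 = sprintf("%s_%s_2", parts[3], parts[2]),
                ind3 = sprintf("%s_%s_3", parts[3], parts[2])))
  }
  switch(outcome,
    wmh = list(kind = "single", construct = "wmh", ind2 = "wmh_2", ind3 = "wmh_3"),
    gm  = list(kind = "single", construct = "gm", ind2 = "gm_2", ind3 = "gm_3"),
    tbv = list(kind = "single", construct = "tb", ind2 = "tb_2", ind3 = "tb_3"),
    gfa = c(list(kind = "factor", construct = "gfa"), tractsInd("fa")),
    gmd = c(list(kind = "factor", construct = "gmd"), tractsInd("md")),
    pvs = list(kind = "pvs", construct = "pvs"),
    stop("unknown outcome: ", outcome))
}

buildOutcomeModel <- function(outcome, covariates = TRUE, auxiliary = TRUE,
                              residualPairs = NULL) {
  serum <- changeScoreSpec("s100b", "s100b_2", "s100b_3")
  os <- outcomeSpec(outcome)
  if (os$kind == "single") {
    spec <- changeScoreSpec(os$construct, os$ind2, os$ind3)
    model <- buildBivariateLcs(serum, spec)
    mri2 <- os$ind2; mri3 <- os$ind3
  } else if (os$kind == "factor") {
    spec <- changeScoreSpec(os$construct, os$ind2, os$ind3,
                            indicatorNames = os$names,
                            residualPairs = residualPairs)
    model <- buildBivariateLcs(serum, spec)
    mri2 <- os$ind2; mri3 <- os$ind3
  } else {
    model <- buildPvsVariant(serum, "pvs_change")
    mri2 <- mri3 <- character(0)
  }
  if (covariates) {
    map <- standardCovariateMap(mriVars2 = mri2, mriVars3 = mri3)
    if (os$kind == "pvs") {
      map[["pvs_change"]] <- c("age_mri_2", "age_mri_3", "sex",
                               "diabetes_2", "hypertension_2")
    }
    model <- addCovariates(model, map)
  }
  usesGm <- any(c("gm_2", "gm_3") %in% model@observed)
  if (auxiliary && !usesGm) model <- addAuxiliary(model, "gm_2")
  model
}

#' Fit the association suite across outcomes with FDR correction
#'
#' For each outcome, builds the appropriate bivariate change score model
#' (single-indicator for volumetrics and per-tract averages; latent factor for
#' the general FA/MD factors; observed-change variant for the PVS rating),
#' optionally adds the standard covariate corrections and the baseline
#' gray-matter auxiliary variable (skipped when GM is the outcome), fits by
#' FIML, standardizes, tests the two reserved associations by Wald z on the
#' unstandardized covariance, optionally bootstraps bias-corrected confidence
#' intervals for the standardized estimates, and applies Benjamini-Hochberg
#' FDR within the suite. Non-converged fits yield rows with missing estimates
#' and are excluded from the FDR family (counted in the `"nonconverged"`
#' attribute).
#'
#' @param table preprocessed cohort table ([preprocessCohort()]).
#' @param outcomes character vector, e.g. `c("wmh", "pvs", "gfa", "gmd",
#'   "gm", "tbv")` or `"tract:atr:fa"`.
#' @param q FDR threshold.
#' @param nBoot bootstrap replicates for the confidence intervals (0 = skip;
#'   the headline analysis uses 1000).
#' @param seed seed for the bootstrap.
#' @param covariates,auxiliary include covariate corrections / the auxiliary.
#' @param residualPairs optional extra residual pairs for the factor models
#'   (named list by outcome).
#' @param outDir optional directory: per-outcome model JSON and fit summaries
#'   are written next to the results for audit.
#' @return data.frame, one association row per outcome.
#' @export
runAssociationSuite <- function(table, outcomes, q = 0.05, nBoot = 0L,
                                seed = NULL, covariates = TRUE, auxiliary = TRUE,
                                residualPairs = list(), outDir = NULL) {
  rows <- list()
  nonconv <- 0L
  for (k in seq_along(outcomes)) {
    oc <- outcomes[k]
    model <- buildOutcomeModel(oc, covariates = covariates, auxiliary = auxiliary,
                               residualPairs = residualPairs[[oc]])
    fit <- tryCatch(semFit(model, table), error = function(e) NULL)
    row <- data.frame(outcome = oc, level_r = NA_real_, level_p = NA_real_,
                      level_ci_low = NA_real_, level_ci_high = NA_real_,
                      change_r = NA_real_, change_p = NA_real_,
                      change_ci_low = NA_real_, change_ci_high = NA_real_,
                      fdr_flag_level = NA, fdr_flag_change = NA,
                      chi2 = NA_real_, df = NA_real_, rmsea = NA_real_,
                      cfi = NA_real_, tli = NA_real_, srmr = NA_real_,
                      n_used = NA_integer_, converged = FALSE)
    if (!is.null(fit) && fit@converged) {
      rep <- model@meta$report
      std <- fit@standardized
      getStd <- function(lab) { v <- std$std[std$label == lab]; if (length(v)) v[1] else NA_real_ }
      waldP <- function(lab) {
        est <- fit@estimates[[lab]]; se <- fit@se[[lab]]
        if (is.na(se) || se == 0) return(NA_real_)
        2 * stats::pnorm(-abs(est / se))
      }
      row$level_r <- getStd(rep$level); row$level_p <- waldP(rep$level)
      row$change_r <- getStd(rep$change); row$change_p <- waldP(rep$change)
      row$chi2 <- fit@chi2; row$df <- fit@df; row$rmsea <- fit@rmsea
      row$cfi <- fit@cfi; row$tli <- fit@tli; row$srmr <- fit@srmr
      row$n_used <- fit@nUsed; row$converged <- TRUE
      if (nBoot > 0) {
        ci <- bootstrapCI(model, table, unlist(rep[c("level", "change")]),
                          nBoot = nBoot, seed = if (is.null(seed)) NULL else seed + k,
                          standardized = TRUE, pointFit = fit)
        row$level_ci_low <- ci$lower[1]; row$level_ci_high <- ci$upper[1]
        row$change_ci_low <- ci$lower[2]; row$change_ci_high <- ci$upper[2]
      }
      if (!is.null(outDir)) {
        writeSemModel(model, file.path(outDir, paste0(gsub(":", "_", oc), "_model.json")))
        fm <- fitMeasures(fit)
        writeLines(jsonlite::toJSON(fm, auto_unbox = TRUE, digits = NA),
                   file.path(outDir, paste0(gsub(":", "_", oc), "_fit.json")))
      }
    } else nonconv <- nonconv + 1L
    rows[[k]] <- row
  }
  out <- do.call(rbind, rows)
  pv <- c(out$level_p, out$change_p)
  okP <- !is.na(pv)
  if (any(okP)) {
    fdr <- bhFdr(pv[okP], q)
    rej <- rep(NA, length(pv)); adj <- rep(NA_real_, length(pv))
    rej[okP] <- fdr$reject; adj[okP] <- fdr$adjusted
    m <- nrow(out)
    out$fdr_flag_level <- rej[seq_len(m)]
    out$fdr_flag_change <- rej[m + seq_len(m)]
    out$level_p_adj <- adj[seq_len(m)]
    out$change_p_adj <- adj[m + seq_len(m)]
  }
  attr(out, "nonconverged") <- nonconv
  out
}

#' Baseline comparisons between returners and non-returners
#'
#' Welch comparisons of baseline serum, total brain, WMH and gray-matter
#' values between participants who did and did not return a wave-3 serum
#' sample, plus a two-proportion chi-square of sex by MRI participation at
#' each wave.
#'
#' @param table cohort table (raw or preprocessed).
#' @return list with `comparisons` (data.frame) and `sex_by_mri` (data.frame).
#' @export
attritionReport <- function(table) {
  ret <- !is.na(table$s100b_3)
  vars <- c(s100b = "s100b_2", tb = "tb_2", wmh = "wmh_2", gm = "gm_2")
  cmp <- do.call(rbind, lapply(names(vars), function(nm) {
    cbind(variable = nm,
          compareGroups(table[[vars[[nm]]]][ret], table[[vars[[nm]]]][!ret],
                        labels = c("returners", "nonreturners")))
  }))
  sexTab <- do.call(rbind, lapply(2:3, function(w) {
    mri <- !is.na(table[[paste0("gm_", w)]])
    tt <- table(factor(table$sex, levels = 0:1), factor(mri, levels = c(FALSE, TRUE)))
    if (any(rowSums(tt) == 0) || any(colSums(tt) == 0)) {
      return(data.frame(wave = w, chi2 = NA_real_, p = NA_real_))
    }
    ct <- suppressWarnings(stats::chisq.test(tt, correct = FALSE))
    data.frame(wave = w, chi2 = unname(ct$statistic), p = ct$p.value)
  }))
  list(comparisons = cmp, sex_by_mri = sexTab)
}

#' Wave-wise descriptive table
#'
#' Mean, SD and available N per wave for the principal observed variables,
#' plus the sex split — the "participant characteristics" table of a two-wave
#' biomarker-MRI cohort.
#'
#' @param table cohort table (untransformed volumes expected).
#' @return data.frame.
#' @export
cohortDescriptives <- function(table) {
  vars <- c("age_serum", "s100b", "mmse", "wmh", "tb", "gm")
  rows <- list()
  for (v in vars) for (w in 2:3) {
    x <- table[[paste0(v, "_", w)]]
    x <- x[!is.na(x)]
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, wave = w, n = length(x),
      mean = if (length(x)) mean(x) else NA_real_,
      sd = if (length(x) > 1) stats::sd(x) else NA_real_,
      median = if (length(x)) stats::median(x) else NA_real_)
  }
  sex <- data.frame(variable = "sex_male", wave = 2L,
                    n = sum(!is.na(table$sex)),
                    mean = mean(table$sex, na.rm = TRUE), sd = NA_real_,
                    median = NA_real_)
  rbind(do.call(rbind, rows), sex)
}
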