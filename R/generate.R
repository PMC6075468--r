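# Synthetic two-wave cohort generation.
#
# Latent construct draws are joint normal with the configured means and
# covariance; tract indicators follow intercept + loading x latent + residual
# with cross-wave residual covariance and (for bilateral tracts) an
# inter-hemisphere residual correlation, via a Kronecker covariance
# (hemisphere block x wave block). Covariate effects are added to the manifest
# variables in centered form so the configured latent means remain the
# marginal means of the manifests. All draws are deterministic given the seed.

cohortColumns <- function() {
  wave <- function(w) {
    c(sprintf(c("s100b_%d", "age_serum_%d", "age_mri_%d", "mmse_%d",
                "dementia_%d", "melanoma_%d", "diabetes_%d", "hypertension_%d",
                "wmh_%d", "tb_%d", "gm_%d"), w),
      unlist(lapply(c("fa", "md"), function(m) {
        unlist(lapply(tractNames(), function(t) {
          if (t %in% bilateralTracts()) sprintf("%s_%s_%s_%d", m, t, c("l", "r"), w)
          else sprintf("%s_%s_%d", m, t, w)
        }))
      })))
  }
  c("participant_id", "sex", "icv", wave(2L), wave(3L), "pvs_change")
}

#' Generate a complete synthetic cohort
#'
#' Draws a complete (pre-missingness, pre-artifact) two-wave cohort table
#' under a [GeneratorConfig-class]. Apply [applyMissingness()] and
#' [injectArtifacts()] afterwards to emulate attrition and assay artifacts.
#'
#' @param config a [GeneratorConfig-class].
#' @return data.frame, one row per participant (see the column dictionary in
#'   the package vignette); deterministic given `config@seed`.
#' @export
generateCohort <- function(config) {
  methods::validObject(config)
  n <- config@nParticipants
  cols <- cohortColumns()
  if (n == 0L) {
    out <- as.data.frame(matrix(numeric(0), 0, length(cols),
                                dimnames = list(NULL, cols)))
    return(out)
  }
  cd <- config@covariateDists
  ce <- config@covariateEffects
  ex <- config@exclusionDists
  out <- withSeed(config@seed, {
    df <- data.frame(participant_id = seq_len(n))
    df$sex <- stats::rbinom(n, 1, cd$sex_p_male)
    df$icv <- stats::rnorm(n, config@icvMean, config@icvSd)
    df$age_serum_2 <- rnormTrunc(n, cd$age_w2_mean, cd$age_w2_sd)
    lag <- stats::rnorm(n, cd$wave_lag_mean, cd$wave_lag_sd)
    df$age_serum_3 <- df$age_serum_2 + lag
    sl <- cd$scan_lag_days
    df$age_mri_2 <- df$age_serum_2 + stats::rnorm(n, sl[["w2_mean"]], sl[["w2_sd"]]) / 365.25
    df$age_mri_3 <- df$age_serum_3 + stats::rnorm(n, sl[["w3_mean"]], sl[["w3_sd"]]) / 365.25
    df$diabetes_2 <- df$diabetes_3 <- stats::rbinom(n, 1, cd$diabetes_prev)
    df$hypertension_2 <- df$hypertension_3 <- stats::rbinom(n, 1, cd$hypertension_prev)
    for (w in 2:3) {
      mm <- pmax(0, pmin(30, round(stats::rnorm(n, ex$mmse_mean, ex$mmse_sd))))
      low <- stats::runif(n) < ex$mmse_low_rate
      mm[low] <- sample(18:23, sum(low), replace = TRUE)
      df[[paste0("mmse_", w)]] <- mm
    }
    df$dementia_2 <- stats::rbinom(n, 1, ex$dementia_rate)
    df$dementia_3 <- pmax(df$dementia_2, stats::rbinom(n, 1, ex$dementia_rate / 2))
    df$melanoma_2 <- stats::rbinom(n, 1, ex$melanoma_rate)
    df$melanoma_3 <- pmax(df$melanoma_2, stats::rbinom(n, 1, ex$melanoma_rate / 2))

    lat <- rmvnormEig(n, config@latentMeans, config@latentCov)
    colnames(lat) <- latentNames()

    # centered covariate design per wave
    ageC2 <- df$age_serum_2 - cd$age_w2_mean
    ageC3 <- df$age_serum_3 - (cd$age_w2_mean + cd$wave_lag_mean)
    ageM2 <- df$age_mri_2 - (cd$age_w2_mean + sl[["w2_mean"]] / 365.25)
    ageM3 <- df$age_mri_3 - (cd$age_w2_mean + cd$wave_lag_mean + sl[["w3_mean"]] / 365.25)
    sexC <- df$sex - cd$sex_p_male
    diaC <- df$diabetes_2 - cd$diabetes_prev
    hypC <- df$hypertension_2 - cd$hypertension_prev
    mriEffect <- function(con, w) {
      e <- ce$mri[[con]]
      ageM <- if (w == 2L) ageM2 else ageM3
      e[["age"]] * ageM + e[["sex"]] * sexC +
        e[["diabetes"]] * diaC + e[["hypertension"]] * hypC
    }

    df$s100b_2 <- lat[, "s100b_lvl"] + ce$serum[["age"]] * ageC2 + ce$serum[["sex"]] * sexC
    df$s100b_3 <- lat[, "s100b_lvl"] + lat[, "s100b_chg"] +
      ce$serum[["age"]] * ageC3 + ce$serum[["sex"]] * sexC
    df$wmh_2 <- exp(lat[, "wmh_lvl"] + mriEffect("wmh", 2L))
    df$wmh_3 <- exp(lat[, "wmh_lvl"] + lat[, "wmh_chg"] + mriEffect("wmh", 3L))
    df$tb_2 <- lat[, "tb_lvl"] + mriEffect("tb", 2L)
    df$tb_3 <- lat[, "tb_lvl"] + lat[, "tb_chg"] + mriEffect("tb", 3L)
    df$gm_2 <- lat[, "gm_lvl"] + mriEffect("gm", 2L)
    df$gm_3 <- lat[, "gm_lvl"] + lat[, "gm_chg"] + mriEffect("gm", 3L)

    for (m in c("fa", "md")) {
      con <- if (m == "fa") "gfa" else "gmd"
      g2 <- lat[, paste0(con, "_lvl")]
      g3 <- g2 + lat[, paste0(con, "_chg")]
      eff2 <- mriEffect(con, 2L); eff3 <- mriEffect(con, 3L)
      for (t in tractNames()) {
        p <- config@tracts[[m]][[t]]
        W <- matrix(c(p[["residual_var"]], p[["cross_wave_residual_cov"]],
                      p[["cross_wave_residual_cov"]], p[["residual_var"]]), 2, 2)
        base2 <- p[["intercept"]] + p[["loading"]] * g2 + eff2
        base3 <- p[["intercept"]] + p[["loading"]] * g3 + eff3
        if (t %in% bilateralTracts()) {
          P <- matrix(c(1, config@hemisphereCor, config@hemisphereCor, 1), 2, 2)
          resid <- rmvnormEig(n, numeric(4), kronecker(P, W))
          vals <- list(l2 = base2 + resid[, 1], l3 = base3 + resid[, 2],
                       r2 = base2 + resid[, 3], r3 = base3 + resid[, 4])
          if (m == "fa") vals <- lapply(vals, function(v) pmin(pmax(v, 0), 1))
          df[[sprintf("%s_%s_l_2", m, t)]] <- vals$l2
          df[[sprintf("%s_%s_l_3", m, t)]] <- vals$l3
          df[[sprintf("%s_%s_r_2", m, t)]] <- vals$r2
          df[[sprintf("%s_%s_r_3", m, t)]] <- vals$r3
        } else {
          resid <- rmvnormEig(n, numeric(2), W)
          v2 <- base2 + resid[, 1]; v3 <- base3 + resid[, 2]
          if (m == "fa") { v2 <- pmin(pmax(v2, 0), 1); v3 <- pmin(pmax(v3, 0), 1) }
          df[[sprintf("%s_%s_2", m, t)]] <- v2
          df[[sprintf("%s_%s_3", m, t)]] <- v3
        }
      }
    }

    ratings <- as.integer(names(config@pvsProbs))
    if (config@pvsCoupling == 0) {
      df$pvs_change <- sample(ratings, n, replace = TRUE, prob = config@pvsProbs)
    } else {
      r <- config@pvsCoupling
      zc <- as.vector(scale(lat[, "s100b_chg"]))
      u <- stats::pnorm(r * zc + sqrt(1 - r^2) * stats::rnorm(n))
      cum <- cumsum(config@pvsProbs)
      cum[length(cum)] <- 1
      df$pvs_change <- ratings[findInterval(u, cum) + 1L]
    }
    df
  })
  out <- out[, cols]
  rownames(out) <- NULL
  out
}

#' Apply attrition and scan-level missingness
#'
#' Non-returners are sampled with probability
#' `plogis(attrition_intercept + attrition_slope_on_gm * z(baseline GM))` —
#' a missing-at-random mechanism tied to the observed baseline gray-matter
#' volume — and lose all wave-3 serum-visit and MRI fields (wave-2 serum is
#' never removed). Independently of all values, each wave's MRI block is
#' blanked with `scan_missing_rate` (missing completely at random). The PVS
#' change rating requires both scans and is blanked when either is missing.
#'
#' @param table a complete cohort table from [generateCohort()].
#' @param config the [GeneratorConfig-class].
#' @param seed RNG seed (default `config@seed + 1`).
#' @return the table with `NA`s inserted; deterministic given the seed.
#' @export
applyMissingness <- function(table, config, seed = config@seed + 1L) {
  methods::validObject(config)
  ms <- config@missingness
  if (ms$scan_missing_rate < 0 || ms$scan_missing_rate > 1) {
    stop("scan_missing_rate must lie in [0,1]")
  }
  n <- nrow(table)
  if (n == 0L) return(table)
  mriCols <- function(w) {
    c(sprintf(c("age_mri_%d", "wmh_%d", "tb_%d", "gm_%d"), w),
      grep(sprintf("^(fa|md)_.*_%d$", w), names(table), value = TRUE))
  }
  withSeed(seed, {
    gz <- as.vector(scale(table$gm_2))
    pDrop <- stats::plogis(ms$attrition_intercept + ms$attrition_slope_on_gm * gz)
    drop3 <- stats::runif(n) < pDrop
    scan2 <- stats::runif(n) < ms$scan_missing_rate
    scan3 <- stats::runif(n) < ms$scan_missing_rate
    w3cols <- c("s100b_3", "age_serum_3", "mmse_3", mriCols(3L))
    table[drop3, w3cols] <- NA
    table[drop3, "pvs_change"] <- NA
    table[scan2, mriCols(2L)] <- NA
    table[scan2 | scan3, "pvs_change"] <- NA
    table[scan3, mriCols(3L)] <- NA
  })
  attr(table, "dropout") <- NULL
  table
}

#' Inject assay artifacts into serum values
#'
#' With `outlier_rate`, replaces `round(rate * n_cells)` serum values (either
#' wave) by `mean + m * SD` with `m = 4 + |N(0, outlier_magnitude_sd)|`, i.e.
#' strictly above the 4-SD outlier-filter threshold of the uncontaminated
#' wave distribution. With `floor_rate`, replaces `round(rate * n)` wave-3
#' serum values by draws in `[0, 0.02)`, below the assay sensitivity
#' threshold. Injected cells are recorded in an audit log (see
#' [artifactLog()]).
#'
#' @inheritParams applyMissingness
#' @param seed RNG seed (default `config@seed + 2`).
#' @return the modified table with an `"artifact_log"` attribute.
#' @export
injectArtifacts <- function(table, config, seed = config@seed + 2L) {
  methods::validObject(config)
  ar <- config@artifacts
  log <- data.frame(participant_id = integer(0), wave = integer(0),
                    rule = character(0), old = numeric(0), new = numeric(0))
  n <- nrow(table)
  if (n == 0L) { attr(table, "artifact_log") <- log; return(table) }
  withSeed(seed, {
    injectedW3 <- integer(0)
    if (ar$outlier_rate > 0) {
      cells <- rbind(
        data.frame(row = which(!is.na(table$s100b_2)), wave = 2L),
        data.frame(row = which(!is.na(table$s100b_3)), wave = 3L))
      k <- round(ar$outlier_rate * nrow(cells))
      if (k > 0) {
        pick <- cells[sample.int(nrow(cells), k), , drop = FALSE]
        for (w in 2:3) {
          col <- paste0("s100b_", w)
          mw <- mean(table[[col]], na.rm = TRUE)
          sw <- stats::sd(table[[col]], na.rm = TRUE)
          rows <- pick$row[pick$wave == w]
          if (w == 3L) injectedW3 <- c(injectedW3, rows)
          for (r in rows) {
            old <- table[r, col]
            newv <- mw + (4 + abs(stats::rnorm(1, 0, ar$outlier_magnitude_sd)) + 1e-6) * sw
            table[r, col] <- newv
            log <- rbind(log, data.frame(participant_id = table$participant_id[r],
                                         wave = w, rule = "outlier",
                                         old = old, new = newv))
          }
        }
      }
    }
    if (ar$floor_rate > 0) {
      avail <- setdiff(which(!is.na(table$s100b_3)), injectedW3)
      m <- round(ar$floor_rate * length(avail))
      if (m > 0) {
        rows <- sample(avail, m)
        for (r in rows) {
          old <- table[r, "s100b_3"]
          newv <- stats::runif(1, 0, 0.02 - 1e-9)
          table[r, "s100b_3"] <- newv
          log <- rbind(log, data.frame(participant_id = table$participant_id[r],
                                       wave = 3L, rule = "assay_floor",
                                       old = old, new = newv))
        }
      }
    }
  })
  attr(table, "artifact_log") <- log
  table
}

#' @describeIn injectArtifacts retrieve the audit log of injected artifacts.
#' @export
artifactLog <- function(table) {
  attr(table, "artifact_log") %||%
    data.frame(participant_id = integer(0), wave = integer(0),
               rule = character(0), old = numeric(0), new = numeric(0))
}

#' Read/write a cohort table as CSV
#'
#' @param table cohort data.frame.
#' @param path file path.
#' @export
writeCohort <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname writeCohort
#' @export
readCohort <- function(path) {
  utils::read.csv(path, na.strings = c("", "NA"))
}

#' @describeIn injectArtifacts write the audit log as JSON lines.
#' @param path file path for the JSON-lines log.
#' @export
writeArtifactLog <- function(table, path) {
  log <- artifactLog(table)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(log))) {
    writeLines(jsonlite::toJSON(as.list(log[i, ]), auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
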