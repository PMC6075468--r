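# Exclusion, filtering and transformation rules with a full audit trail.

emptyExclusionLog <- function() {
  data.frame(rule = character(0), participant_id = integer(0),
             wave = integer(0), value = numeric(0))
}

#' Exclude participants by cognitive and melanoma criteria
#'
#' Removes participants with self-reported dementia or an MMSE score below 24
#' at either wave, and participants reporting melanoma at either wave. Missing
#' flags are treated as not-flagged.
#'
#' @param table cohort data.frame.
#' @return list with `table` (rows removed) and `log` (one row per removed
#'   participant per rule: `rule`, `participant_id`, `wave`, `value`).
#' @export
excludeParticipants <- function(table) {
  log <- emptyExclusionLog()
  flag <- function(x) !is.na(x) & x == 1
  low <- function(x) !is.na(x) & x < 24
  mmseDem <- flag(table$dementia_2) | flag(table$dementia_3) |
    low(table$mmse_2) | low(table$mmse_3)
  mel <- flag(table$melanoma_2) | flag(table$melanoma_3)
  if (any(mmseDem)) {
    log <- rbind(log, data.frame(rule = "mmse_dementia",
                                 participant_id = table$participant_id[mmseDem],
                                 wave = NA_integer_, value = NA_real_))
  }
  melOnly <- mel & !mmseDem
  if (any(melOnly)) {
    log <- rbind(log, data.frame(rule = "melanoma",
                                 participant_id = table$participant_id[melOnly],
                                 wave = NA_integer_, value = NA_real_))
  }
  list(table = table[!(mmseDem | mel), , drop = FALSE], log = log)
}

#' Filter serum values: one-sided outliers and assay floor
#'
#' Per wave, serum cells more than 4 SDs above that wave's mean are set
#' missing; the mean/SD are computed once on the wave's non-missing values
#' before any removal (one-sided, non-iterative). Additionally, wave-3 cells
#' below the assay sensitivity threshold of 0.02 ug/L are set missing.
#' Participant rows are retained, so the other wave remains usable under
#' FIML. A wave with fewer than 2 non-missing values is skipped with a
#' warning entry in the log.
#'
#' @param table cohort data.frame (after [excludeParticipants()]).
#' @return list with `table` and `log` (rules `outlier_4sd`, `assay_floor`,
#'   `skipped_wave`).
#' @export
filterS100b <- function(table) {
  log <- emptyExclusionLog()
  for (w in 2:3) {
    col <- paste0("s100b_", w)
    x <- table[[col]]
    ok <- !is.na(x)
    if (sum(ok) < 2) {
      warning(sprintf("wave %d has fewer than 2 serum values; outlier filter skipped", w))
      log <- rbind(log, data.frame(rule = "skipped_wave", participant_id = NA_integer_,
                                   wave = w, value = NA_real_))
      next
    }
    thr <- mean(x[ok]) + 4 * stats::sd(x[ok])
    hit <- ok & x > thr
    if (any(hit)) {
      log <- rbind(log, data.frame(rule = "outlier_4sd",
                                   participant_id = table$participant_id[hit],
                                   wave = w, value = x[hit]))
      table[hit, col] <- NA
    }
  }
  x3 <- table$s100b_3
  floorHit <- !is.na(x3) & x3 < 0.02
  if (any(floorHit)) {
    log <- rbind(log, data.frame(rule = "assay_floor",
                                 participant_id = table$participant_id[floorHit],
                                 wave = 3L, value = x3[floorHit]))
    table[floorHit, "s100b_3"] <- NA
  }
  list(table = table, log = log)
}

#' Transform volumetric MRI measures
#'
#' Optionally expresses WMH, total brain and gray-matter volumes as a
#' proportion of intracranial volume (before any log transform), then replaces
#' WMH by its natural log (to correct skewness). FA/MD are untouched. A
#' transform flag on the table guards against double application.
#'
#' @param table cohort data.frame.
#' @param icvCorrect divide volumes by intracranial volume first.
#' @return the transformed table (attribute `"mri_transformed"` set).
#' @export
transformMri <- function(table, icvCorrect = TRUE) {
  if (isTRUE(attr(table, "mri_transformed"))) {
    stop("MRI columns are already transformed")
  }
  volCols <- c("wmh_2", "wmh_3", "tb_2", "tb_3", "gm_2", "gm_3")
  for (col in volCols) {
    v <- table[[col]]
    if (any(!is.na(v) & v < 0)) stop("negative volume in ", col)
  }
  if (icvCorrect) {
    for (col in volCols) table[[col]] <- table[[col]] / table$icv
  }
  for (col in c("wmh_2", "wmh_3")) {
    v <- table[[col]]
    zero <- !is.na(v) & v == 0
    if (any(zero)) {
      warning(sum(zero), " zero WMH value(s) in ", col, " set missing (log undefined)")
      v[zero] <- NA
    }
    table[[col]] <- log(v)
  }
  attr(table, "mri_transformed") <- TRUE
  attr(table, "icv_corrected") <- icvCorrect
  table
}

#' Average bilateral tract measures
#'
#' Adds left-right tract averages (`fa_atr_2` from `fa_atr_l_2`/`fa_atr_r_2`,
#' etc.) using the mean of the available sides when one is missing. Midline
#' tracts (genu, splenium) already have single columns.
#'
#' @param table cohort data.frame.
#' @return the table with averaged columns appended.
#' @export
averageTracts <- function(table) {
  for (m in c("fa", "md")) for (t in bilateralTracts()) for (w in 2:3) {
    l <- table[[sprintf("%s_%s_l_%d", m, t, w)]]
    r <- table[[sprintf("%s_%s_r_%d", m, t, w)]]
    table[[sprintf("%s_%s_%d", m, t, w)]] <- rowMeans(cbind(l, r), na.rm = TRUE)
    table[[sprintf("%s_%s_%d", m, t, w)]][is.na(l) & is.na(r)] <- NA
  }
  table
}

#' Full preprocessing pipeline
#'
#' Applies, in order: participant exclusions, serum outlier/floor filters,
#' volumetric transforms, and left-right tract averaging.
#'
#' @param table raw cohort data.frame.
#' @param icvCorrect passed to [transformMri()].
#' @return list with `table` and the combined exclusion `log`.
#' @export
preprocessCohort <- function(table, icvCorrect = TRUE) {
  ex <- excludeParticipants(table)
  fl <- filterS100b(ex$table)
  tab <- transformMri(fl$table, icvCorrect = icvCorrect)
  tab <- averageTracts(tab)
  list(table = tab, log = rbind(ex$log, fl$log))
}

#' @describeIn preprocessCohort write an exclusion log as JSON.
#' @param log exclusion log data.frame.
#' @param path file path.
#' @export
writeExclusionLog <- function(log, path) {
  writeLines(jsonlite::toJSON(log, dataframe = "rows", auto_unbox = TRUE,
                              digits = NA, na = "null"), path)
  invisible(path)
}
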