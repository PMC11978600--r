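new_qc_report <- function(rule, removed_variables = character(0),
                          removed_values = 0L,
                          removed_participants = character(0),
                          n_before = NA_integer_, n_after = NA_integer_) {
  structure(list(rule = rule,
                 removed_variables = removed_variables,
                 removed_values = as.integer(removed_values),
                 removed_participants = removed_participants,
                 n_before = n_before, n_after = n_after),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report: %s> rows %s -> %s; -%d variables, -%d values, -%d participants\n",
              x$rule, x$n_before, x$n_after, length(x$removed_variables),
              x$removed_values, length(x$removed_participants)))
  invisible(x)
}

finite_rows <- function(table) table[is.finite(table$value), , drop = FALSE]

#' Remove cognitive tests with insufficient per-visit coverage
#'
#' A variable is retained iff every visit at which it was administered has
#' at least `min_n` participants with non-missing values. Visits where a
#' test was not administered at all do not disqualify it.
#'
#' @param table Long feature table.
#' @param min_n Minimum participants per administered visit (default 75).
#' @return A list with `table` and `qc` (a `qc_report`).
#' @export
filter_low_coverage_tests <- function(table, min_n = 75) {
  validate_feature_table(table, require_rows = TRUE)
  obs <- finite_rows(table)
  counts <- dplyr::summarise(
    dplyr::group_by(obs, .data$variable, .data$visit_index),
    n = dplyr::n_distinct(.data$participant_id), .groups = "drop")
  bad <- unique(counts$variable[counts$n < min_n])
  # variables with no finite observation anywhere fail trivially
  bad <- union(bad, setdiff(unique(table$variable), unique(obs$variable)))
  out <- table[!table$variable %in% bad, , drop = FALSE]
  list(table = out,
       qc = new_qc_report("coverage", removed_variables = bad,
                          n_before = nrow(table), n_after = nrow(out)))
}

#' Remove tests constant within the central percentile band
#'
#' Pooling all visits, a variable is removed iff the values lying between
#' its `pct_lo`-th and `pct_hi`-th percentiles (linear-interpolation
#' quantiles) are all equal.
#'
#' @param table Long feature table.
#' @param pct_lo,pct_hi Percentile band, `0 <= lo < hi <= 100`.
#' @return A list with `table` and `qc`.
#' @export
filter_constant_tests <- function(table, pct_lo = 5, pct_hi = 95) {
  stopifnot(pct_lo >= 0, pct_lo < pct_hi, pct_hi <= 100)
  obs <- finite_rows(table)
  is_const <- vapply(split(obs$value, obs$variable), function(v) {
    q <- quantile(v, c(pct_lo, pct_hi) / 100, names = FALSE, type = 7)
    band <- v[v >= q[1] & v <= q[2]]
    length(unique(band)) <= 1
  }, logical(1))
  bad <- names(is_const)[is_const]
  out <- table[!table$variable %in% bad, , drop = FALSE]
  list(table = out,
       qc = new_qc_report("constancy", removed_variables = bad,
                          n_before = nrow(table), n_after = nrow(out)))
}

#' Flag extreme values by the interquartile-range rule
#'
#' A value is flagged iff it lies outside
#' `[Q1 - multiplier * IQR, Q3 + multiplier * IQR]`, with quartiles computed
#' by linear interpolation (R type 7).
#'
#' @param values Numeric vector.
#' @param multiplier Fence multiplier (default 5).
#' @return Logical mask, TRUE = outlier; same length as `values`.
#' @export
iqr_outlier_mask <- function(values, multiplier = 5) {
  mask <- rep(FALSE, length(values))
  finite <- is.finite(values)
  if (sum(finite) < 4) {
    warning("fewer than 4 finite values; no IQR flagging applied")
    return(mask)
  }
  q <- quantile(values[finite], c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  lo <- q[1] - multiplier * iqr
  hi <- q[2] + multiplier * iqr
  mask[finite] <- values[finite] < lo | values[finite] > hi
  mask
}

#' Remove extreme outliers per variable
#'
#' Applies [iqr_outlier_mask()] per variable, pooling visits by default.
#'
#' @param table Long feature table.
#' @param multiplier Fence multiplier.
#' @param per_visit Compute fences separately per visit instead of pooled.
#' @return A list with `table` and `qc`.
#' @export
filter_iqr_outliers <- function(table, multiplier = 5, per_visit = FALSE) {
  keys <- if (per_visit) {
    paste(table$variable, table$visit_index)
  } else {
    table$variable
  }
  drop <- rep(FALSE, nrow(table))
  for (idx in split(seq_len(nrow(table)), keys)) {
    drop[idx] <- suppressWarnings(
      iqr_outlier_mask(table$value[idx], multiplier))
  }
  out <- table[!drop, , drop = FALSE]
  list(table = out,
       qc = new_qc_report("iqr", removed_values = sum(drop),
                          n_before = nrow(table), n_after = nrow(out)))
}

#' Remove participants with no usable cognitive data
#'
#' @param table Long cognitive feature table.
#' @param roster Optional full participant roster; roster members without a
#'   single non-missing observation are counted as removed even if they have
#'   no rows at all.
#' @return A list with `table` and `qc`.
#' @export
drop_empty_participants <- function(table, roster = NULL) {
  obs <- finite_rows(table)
  keep_ids <- unique(obs$participant_id)
  removed <- setdiff(unique(c(table$participant_id, roster)), keep_ids)
  out <- table[table$participant_id %in% keep_ids, , drop = FALSE]
  list(table = out,
       qc = new_qc_report("empty_participants",
                          removed_participants = removed,
                          n_before = nrow(table), n_after = nrow(out)))
}

#' Normalize regional volumes by intracranial volume
#'
#' Divides each raw volume (mm^3) by the participant's intracranial volume
#' (mm^3), yielding dimensionless head-size-corrected proportions.
#' Participants with missing or non-positive ICV are excluded and reported.
#'
#' @param volumes Long MRI feature table.
#' @param icv Tibble with `participant_id`, `icv`.
#' @return A list with `table` (normalized) and `qc`.
#' @export
icv_normalize <- function(volumes, icv) {
  i <- match(volumes$participant_id, icv$participant_id)
  icv_val <- icv$icv[i]
  bad <- !is.finite(icv_val) | icv_val <= 0
  if (any(bad)) {
    warning(sprintf(
      "%d participants with missing/non-positive ICV excluded from MRI",
      length(unique(volumes$participant_id[bad]))))
  }
  out <- volumes[!bad, , drop = FALSE]
  out$value <- out$value / icv_val[!bad]
  list(table = out,
       qc = new_qc_report(
         "icv_normalize",
         removed_participants = unique(volumes$participant_id[bad]),
         n_before = nrow(volumes), n_after = nrow(out)))
}

#' Restrict MRI/EEG tables to the cognitive analysis set
#'
#' @param cognitive Preprocessed cognitive table (defines the participant
#'   set).
#' @param mri,eeg Feature tables to align (either may be NULL).
#' @return A list with the aligned `mri` and `eeg` tables and per-modality
#'   participant `counts`.
#' @export
match_modalities <- function(cognitive, mri = NULL, eeg = NULL) {
  ids <- unique(cognitive$participant_id)
  if (length(ids) == 0) stop("cognitive table has no participants",
                             call. = FALSE)
  align <- function(tab) {
    if (is.null(tab)) return(NULL)
    if (nrow(tab) > 0 && !any(tab$participant_id %in% ids)) {
      stop("modality table shares no participants with the cognitive table",
           call. = FALSE)
    }
    tab[tab$participant_id %in% ids, , drop = FALSE]
  }
  mri_out <- align(mri)
  eeg_out <- align(eeg)
  list(mri = mri_out, eeg = eeg_out,
       counts = c(
         cognitive = length(ids),
         mri = if (is.null(mri_out)) NA_integer_
               else length(unique(mri_out$participant_id)),
         eeg = if (is.null(eeg_out)) NA_integer_
               else length(unique(eeg_out$participant_id))))
}

#' Full cognitive preprocessing pipeline
#'
#' Applies, in order: per-visit coverage filter, constant-band filter,
#' IQR outlier removal, and empty-participant drop. No values are ever
#' imputed.
#'
#' @param table Long cognitive feature table.
#' @param min_n,pct_lo,pct_hi,multiplier,per_visit Rule parameters.
#' @param roster Optional full participant roster for the drop step.
#' @return A list with `table` and `qc` (list of per-rule reports).
#' @export
preprocess_cognitive <- function(table, min_n = 75, pct_lo = 5, pct_hi = 95,
                                 multiplier = 5, per_visit = FALSE,
                                 roster = NULL) {
  s1 <- filter_low_coverage_tests(table, min_n = min_n)
  s2 <- filter_constant_tests(s1$table, pct_lo = pct_lo, pct_hi = pct_hi)
  s3 <- filter_iqr_outliers(s2$table, multiplier = multiplier,
                            per_visit = per_visit)
  s4 <- drop_empty_participants(s3$table, roster = roster)
  list(table = s4$table,
       qc = list(coverage = s1$qc, constancy = s2$qc, iqr = s3$qc,
                 participants = s4$qc))
}
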