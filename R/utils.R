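#' Evaluate an expression under a local, restored RNG state
#'
#' Thin wrapper over [withr::with_seed()] used by all stochastic components,
#' so that every generator is a pure function of its `seed` argument and
#' never disturbs the caller's RNG stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
local_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Derive a child seed from a stage seed and a small offset, kept within the
# 32-bit integer range expected by set.seed().
child_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset) * 1009L) %% 2147483562L
}

#' Validate a long-format feature table
#'
#' A feature table records one observation per row:
#' `participant_id`, `visit_index` (1-3), `age` (years), `variable`, `value`.
#' Missing observations are either absent rows or rows with `NA` values.
#'
#' @param table A data frame.
#' @param require_rows Error on an empty table?
#' @return The table, invisibly, after validation.
#' @export
validate_feature_table <- function(table, require_rows = FALSE) {
  needed <- c("participant_id", "visit_index", "age", "variable", "value")
  missing_cols <- setdiff(needed, names(table))
  if (length(missing_cols) > 0) {
    stop("feature table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (require_rows && nrow(table) == 0) {
    stop("feature table is empty", call. = FALSE)
  }
  if (nrow(table) > 0) {
    if (!all(table$visit_index %in% 1:3)) {
      stop("visit_index must be in {1, 2, 3}", call. = FALSE)
    }
    key <- paste(table$participant_id, table$visit_index, table$variable)
    if (anyDuplicated(key)) {
      stop("duplicate (participant_id, visit_index, variable) rows",
           call. = FALSE)
    }
  }
  invisible(table)
}

# Adjusted Rand index between two label vectors, delegated to mclust when
# available (it always is in the analysis environment).
ari_score <- function(a, b) {
  if (!requireNamespace("mclust", quietly = TRUE)) {
    stop("mclust is required to compute the adjusted Rand index")
  }
  mclust::adjustedRandIndex(a, b)
}
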