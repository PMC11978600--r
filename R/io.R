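#' Read a long-format feature table from CSV
#'
#' Schema: `participant_id`, `visit_index`, `age`, `variable`, `value`.
#' Duplicate (participant, visit, variable) rows are an error.
#'
#' @param path CSV file path.
#' @return A validated feature tibble.
#' @export
read_long_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           participant_id = readr::col_character(),
                           visit_index = readr::col_integer(),
                           age = readr::col_double(),
                           variable = readr::col_character(),
                           value = readr::col_double()))
  prob <- readr::problems(tab)
  if (nrow(prob) > 0) {
    stop("parse errors at lines ",
         paste(utils::head(prob$row, 5), collapse = ", "), call. = FALSE)
  }
  validate_feature_table(tab)
  tab
}

#' Write a long-format feature table to CSV
#' @param table Feature tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_long_table <- function(table, path) {
  validate_feature_table(table)
  readr::write_csv(table[, c("participant_id", "visit_index", "age",
                             "variable", "value")], path)
  invisible(path)
}
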