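#' Construct a Likert response table
#'
#' Respondents in rows, items in columns. Columns must match the item bank's
#' `item_id` set exactly and are realigned to bank order; every non-missing
#' cell must lie inside the Likert bounds.
#'
#' @param data A data frame or matrix of integer Likert responses.
#' @param bank The [item_bank] the columns refer to.
#' @param scale_min,scale_max Likert bounds (default 1..5). The method is
#'   scale-agnostic; the bounds only matter for range checks and reverse
#'   scoring.
#' @return A tibble of class `likert_tbl` with attributes `scale_min`,
#'   `scale_max`.
#' @export
likert_responses <- function(data, bank, scale_min = 1L, scale_max = 5L) {
  df <- as_tibble(as.data.frame(data))
  unknown <- setdiff(names(df), bank$item_id)
  if (length(unknown) > 0) {
    abort(paste0("response column(s) not in item bank: ",
                 paste(unknown, collapse = ", ")))
  }
  absent <- setdiff(bank$item_id, names(df))
  if (length(absent) > 0) {
    abort(paste0("response matrix is missing item(s): ",
                 paste(absent, collapse = ", ")))
  }
  df <- df[bank$item_id]
  df[] <- lapply(df, function(col) {
    if (is.character(col)) col[col == ""] <- NA
    suppressWarnings(num <- as.numeric(col))
    if (any(is.na(num) & !is.na(col) & !(col %in% c("NA")))) {
      abort("non-numeric response value encountered")
    }
    num
  })
  check_likert_range(df, scale_min, scale_max)
  new_likert_tbl(df, scale_min, scale_max)
}

new_likert_tbl <- function(df, scale_min, scale_max) {
  attr(df, "scale_min") <- as.integer(scale_min)
  attr(df, "scale_max") <- as.integer(scale_max)
  class(df) <- unique(c("likert_tbl", class(df)))
  df
}

check_likert_range <- function(df, scale_min, scale_max) {
  for (j in seq_along(df)) {
    bad <- which(!is.na(df[[j]]) & (df[[j]] < scale_min | df[[j]] > scale_max))
    if (length(bad) > 0) {
      abort(sprintf(
        "response value %s outside [%s, %s] at row %d, column '%s'",
        format(df[[j]][bad[1]]), scale_min, scale_max, bad[1], names(df)[j]))
    }
  }
  invisible(df)
}

#' @rdname likert_responses
#' @export
scale_bounds <- function(data) {
  c(min = attr(data, "scale_min") %||% 1L,
    max = attr(data, "scale_max") %||% 5L)
}

#' Read a wide-format Likert response CSV
#'
#' The header row must consist of item ids from `bank`; missing cells are the
#' empty string or a configurable token.
#'
#' @inheritParams likert_responses
#' @param path Path to a CSV file.
#' @param na Strings treated as missing (default empty and `"NA"`).
#' @return A `likert_tbl`.
#' @export
read_responses <- function(path, bank, scale_min = 1L, scale_max = 5L,
                           na = c("", "NA")) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_double()),
                        na = na, progress = FALSE)
  likert_responses(df, bank, scale_min, scale_max)
}

#' Write a Likert response table to CSV
#'
#' @param data A `likert_tbl` (or plain data frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_responses <- function(data, path) {
  readr::write_csv(as_tibble(as.data.frame(data)), path, na = "")
  invisible(path)
}

#' Response table as a plain numeric matrix
#'
#' @param data A `likert_tbl`.
#' @return Numeric matrix, columns named by item id.
#' @export
response_matrix <- function(data) {
  as.matrix(as.data.frame(data))
}
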