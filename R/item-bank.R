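#' Construct an item bank
#'
#' An item bank is the package's description of a multi-item scale: one row
#' per item, with the item's identifier, its text, the subscale (factor) it
#' belongs to, whether it is reverse keyed, and — for reverse-keyed items —
#' an optional positively worded equivalent used when the text is embedded.
#'
#' @param items A data frame with columns `item_id`, `text`, `subscale`,
#'   `reverse` and optionally `reworded_text`.
#' @return A tibble of class `item_bank`.
#' @examples
#' bank <- item_bank(tibble::tibble(
#'   item_id = c("A1", "A2", "B1", "B2"),
#'   text = c("I enjoy parties.", "I don't talk a lot.",
#'            "I am always prepared.", "I keep things tidy."),
#'   subscale = c("A", "A", "B", "B"),
#'   reverse = c(FALSE, TRUE, FALSE, FALSE),
#'   reworded_text = c(NA, "I talk a lot.", NA, NA)
#' ))
#' @export
item_bank <- function(items) {
  items <- as_tibble(items)
  required <- c("item_id", "text", "subscale", "reverse")
  missing_cols <- setdiff(required, names(items))
  if (length(missing_cols) > 0) {
    abort(paste0("item bank is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"reworded_text" %in% names(items)) {
    items$reworded_text <- NA_character_
  }
  items <- items[c(required, "reworded_text")]
  items$item_id <- as.character(items$item_id)
  items$text <- as.character(items$text)
  items$subscale <- as.character(items$subscale)
  items$reverse <- parse_reverse_flag(items$reverse)
  items$reworded_text <- as.character(items$reworded_text)
  validate_item_bank(items)
  class(items) <- c("item_bank", class(items))
  items
}

parse_reverse_flag <- function(x) {
  if (is.logical(x)) return(x)
  x <- trimws(tolower(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("1", "true", "t")] <- TRUE
  out[x %in% c("0", "false", "f")] <- FALSE
  if (anyNA(out)) {
    abort("`reverse` must be coded as one of 0, 1, true, false")
  }
  out
}

validate_item_bank <- function(items) {
  if (nrow(items) == 0) abort("item bank has no items")
  if (any(is.na(items$item_id) | items$item_id == "")) {
    abort("item_id values must be non-empty")
  }
  dup <- unique(items$item_id[duplicated(items$item_id)])
  if (length(dup) > 0) {
    abort(paste0("duplicate item_id in item bank: ",
                 paste(dup, collapse = ", ")))
  }
  if (any(is.na(items$subscale) | items$subscale == "")) {
    abort("every item needs a subscale label")
  }
  n_per <- table(items$subscale)
  if (any(n_per < 2)) {
    abort(paste0("every subscale needs at least 2 items; too small: ",
                 paste(names(n_per)[n_per < 2], collapse = ", ")))
  }
  invisible(items)
}

#' Read an item bank from CSV
#'
#' Expects a header with columns `item_id,text,subscale,reverse` and
#' optionally `reworded_text`. The reverse flag may be coded `0/1` or
#' `true/false`.
#'
#' @param path Path to a CSV file.
#' @return An [item_bank] tibble.
#' @export
read_item_bank <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  item_bank(df)
}

#' Write an item bank to CSV
#'
#' @param bank An [item_bank].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_item_bank <- function(bank, path) {
  readr::write_csv(as_tibble(bank), path, na = "")
  invisible(path)
}

#' Text used to embed each item
#'
#' Reverse-keyed items are embedded through their positively worded
#' `reworded_text` so that all items point in the direction of the construct;
#' direct items use their own text.
#'
#' @param bank An [item_bank].
#' @return Character vector, one entry per item, in bank order.
#' @export
embedding_texts <- function(bank) {
  txt <- ifelse(bank$reverse, bank$reworded_text, bank$text)
  bad <- bank$reverse & (is.na(bank$reworded_text) | bank$reworded_text == "")
  if (any(bad)) {
    abort(paste0("reverse-keyed item(s) need reworded_text before embedding: ",
                 paste(bank$item_id[bad], collapse = ", ")))
  }
  if (any(is.na(txt) | txt == "")) {
    abort(paste0("empty item text for: ",
                 paste(bank$item_id[is.na(txt) | txt == ""], collapse = ", ")))
  }
  txt
}

#' @export
print.item_bank <- function(x, ...) {
  cat(sprintf("<item_bank: %d items, %d subscales (%s)>\n",
              nrow(x), length(unique(x$subscale)),
              paste(unique(x$subscale), collapse = ", ")))
  NextMethod()
}

subscale_split <- function(bank) {
  split(bank$item_id, bank$subscale)
}
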