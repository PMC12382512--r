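#' Classical item-total short-form selection
#'
#' Within every subscale, the Pearson correlation between each item and the
#' subscale total score is computed (by default the item is included in the
#' total, matching the classical uncorrected item-total statistic); items are
#' ranked in descending order and the top `m` kept. Ties are broken by
#' lexicographic `item_id`. Items with zero variance have no defined
#' correlation and are ranked last, with a warning.
#'
#' @param data A cleaned, direct-scored `likert_tbl`.
#' @param bank The matching [item_bank].
#' @param m Items kept per subscale (default 6).
#' @param corrected If `TRUE`, use the corrected item-rest correlation (item
#'   excluded from the total).
#' @return A list of class `classical_reduction` with `short_form`
#'   ([short_form], `method_tag = "CTT"`) and `item_stats` (tibble of per-item
#'   statistics).
#' @export
ctt_select <- function(data, bank, m = 6L, corrected = FALSE) {
  X <- response_matrix(data)
  stats_tbl <- dplyr::bind_rows(lapply(split_bank(bank), function(ids) {
    S <- X[, ids, drop = FALSE]
    total <- rowSums(S)
    r <- vapply(ids, function(id) {
      x <- S[, id]
      tot <- if (corrected) total - x else total
      if (sd(x) == 0 || sd(tot) == 0) NA_real_ else cor(x, tot)
    }, numeric(1))
    tibble(item_id = ids, subscale = bank$subscale[match(ids, bank$item_id)],
           statistic = unname(r))
  }))
  if (anyNA(stats_tbl$statistic)) {
    warn(paste0("zero-variance item(s) ranked last: ",
                paste(stats_tbl$item_id[is.na(stats_tbl$statistic)], collapse = ", ")))
  }
  build_classical(stats_tbl, m, "CTT", rank_value = stats_tbl$statistic)
}

#' Principal-component loading short-form selection
#'
#' Within every subscale, a principal component analysis of the item
#' correlation matrix is computed; items are ranked by the absolute loading on
#' the first principal component (sign-aligned so the loading sum is positive)
#' and the top `m` kept.
#'
#' @inheritParams ctt_select
#' @param use_cor If `TRUE` (default) PCA is computed on the correlation
#'   matrix; otherwise on the covariance matrix.
#' @return A `classical_reduction` (`method_tag = "PCA"`); `item_stats` carries
#'   the signed first-component loadings.
#' @export
pca_select <- function(data, bank, m = 6L, use_cor = TRUE) {
  X <- response_matrix(data)
  stats_tbl <- dplyr::bind_rows(lapply(split_bank(bank), function(ids) {
    S <- X[, ids, drop = FALSE]
    C <- if (use_cor) cor(S) else cov(S)
    if (anyNA(C)) abort("undefined correlations (zero-variance item) in PCA selection")
    eig <- eigen(C, symmetric = TRUE)
    v <- eig$vectors[, 1]
    if (sum(v) < 0) v <- -v
    loading <- v * sqrt(max(eig$values[1], 0))
    tibble(item_id = ids, subscale = bank$subscale[match(ids, bank$item_id)],
           statistic = loading)
  }))
  build_classical(stats_tbl, m, "PCA", rank_value = abs(stats_tbl$statistic))
}

split_bank <- function(bank) {
  split(bank$item_id, bank$subscale)
}

build_classical <- function(stats_tbl, m, tag, rank_value) {
  stats_tbl$.rank_value <- rank_value
  picks <- stats_tbl |>
    dplyr::group_by(.data$subscale) |>
    dplyr::arrange(dplyr::desc(!is.na(.data$.rank_value)),
                   dplyr::desc(.data$.rank_value), .data$item_id,
                   .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::filter(.data$rank <= m) |>
    dplyr::ungroup()
  sf <- short_form(
    tibble(item_id = picks$item_id, group = picks$subscale,
           statistic = picks$statistic, rank = picks$rank),
    tag, m)
  stats_tbl$.rank_value <- NULL
  structure(list(short_form = sf, item_stats = stats_tbl),
            class = "classical_reduction")
}

#' @export
print.classical_reduction <- function(x, ...) {
  cat(sprintf("<classical_reduction (%s): %d items selected>\n",
              method_tag(x$short_form), nrow(x$short_form)))
  invisible(x)
}

#' @method tidy classical_reduction
#' @export
tidy.classical_reduction <- function(x, ...) {
  dplyr::left_join(x$item_stats,
                   tibble(item_id = x$short_form$item_id,
                          rank = x$short_form$rank, selected = TRUE),
                   by = "item_id") |>
    dplyr::mutate(selected = !is.na(.data$selected))
}
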