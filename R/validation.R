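#' Cronbach's alpha
#'
#' \eqn{\alpha = \frac{k}{k-1}\left(1 - \frac{\sum_i \sigma^2_i}{\sigma^2_{total}}\right)}
#' for a k-item scale. Population variances (denominator n) are used
#' throughout; the ratio makes the estimate identical under either variance
#' convention, but the convention is fixed so every reported value is
#' well-defined. Alpha is at most 1 and can be negative for incoherent scales.
#'
#' @param x Numeric matrix or data frame of item scores (respondents in rows),
#'   at least 2 items and 2 respondents.
#' @return A single numeric value.
#' @examples
#' x <- cbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4))
#' cronbach_alpha(x)  # perfectly correlated items: 1
#' @export
cronbach_alpha <- function(x) {
  X <- as.matrix(x)
  k <- ncol(X); n <- nrow(X)
  if (k < 2) abort("Cronbach's alpha needs at least 2 items")
  if (n < 2) abort("Cronbach's alpha needs at least 2 respondents")
  if (anyNA(X)) abort("Cronbach's alpha requires complete data")
  pvar <- function(v) mean((v - mean(v))^2)
  total_var <- pvar(rowSums(X))
  if (total_var == 0) abort("zero total-score variance; alpha undefined")
  k / (k - 1) * (1 - sum(apply(X, 2, pvar)) / total_var)
}

#' Per-factor Cronbach's alpha
#'
#' @param data A cleaned, direct-scored `likert_tbl`.
#' @param bank The matching [item_bank].
#' @param items Optional character vector restricting each subscale to a
#'   subset (e.g. a short form's items); default uses all bank items.
#' @return Tibble with columns `factor`, `alpha`; the across-factor mean is in
#'   attribute `"mean_alpha"`.
#' @export
factor_alphas <- function(data, bank, items = NULL) {
  X <- response_matrix(data)
  items <- items %||% bank$item_id
  out <- dplyr::bind_rows(lapply(sort(unique(bank$subscale)), function(f) {
    ids <- intersect(bank$item_id[bank$subscale == f], items)
    tibble(factor = f, n_items = length(ids),
           alpha = cronbach_alpha(X[, ids, drop = FALSE]))
  }))
  attr(out, "mean_alpha") <- mean(out$alpha)
  out
}

#' Per-factor sum scores
#'
#' Factor scores are sums of the (direct-scored) item responses.
#'
#' @inheritParams factor_alphas
#' @return Numeric matrix, one column per subscale plus a `total` column.
#' @export
factor_scores <- function(data, bank, items = NULL) {
  X <- response_matrix(data)
  items <- items %||% bank$item_id
  factors <- sort(unique(bank$subscale))
  S <- vapply(factors, function(f) {
    ids <- intersect(bank$item_id[bank$subscale == f], items)
    if (length(ids) == 0) abort(sprintf("no items for subscale '%s'", f))
    rowSums(X[, ids, drop = FALSE])
  }, numeric(nrow(X)))
  cbind(S, total = rowSums(S))
}

#' Convergent validity of a short form
#'
#' Pearson correlations between short-form and full-scale factor sum scores,
#' per factor, plus the total-score correlation and the across-factor mean.
#'
#' @inheritParams factor_alphas
#' @param short A [short_form] (or character vector of selected item ids).
#' @return Tibble with columns `factor`, `r`; attributes `"mean_r"` (mean of
#'   the per-factor correlations) and `"total_r"` (total-score correlation).
#' @export
convergent_correlations <- function(data, short, bank) {
  ids <- short_form_ids(short)
  full <- factor_scores(data, bank)
  reduced <- factor_scores(data, bank, items = ids)
  factors <- setdiff(colnames(full), "total")
  r <- vapply(factors, function(f) {
    if (sd(full[, f]) == 0 || sd(reduced[, f]) == 0) {
      abort(sprintf("constant factor score for '%s'; correlation undefined", f))
    }
    cor(reduced[, f], full[, f])
  }, numeric(1))
  out <- tibble(factor = factors, r = unname(r))
  attr(out, "mean_r") <- mean(r)
  attr(out, "total_r") <- cor(reduced[, "total"], full[, "total"])
  out
}

short_form_ids <- function(short) {
  if (inherits(short, "short_form")) short$item_id else as.character(short)
}

#' Structural correlation matrices
#'
#' Two factor-level correlation matrices: the intercorrelations among the
#' full-scale factor scores, and the cross-correlations between full-scale and
#' short-form factor scores (whose diagonal holds the convergent validities).
#' Their visual similarity is the usual structural-consistency check for a
#' short form.
#'
#' @inheritParams convergent_correlations
#' @return List of class `correlation_matrices` with `original` (symmetric)
#'   and `original_by_short`.
#' @export
correlation_matrices <- function(data, short, bank) {
  ids <- short_form_ids(short)
  full <- factor_scores(data, bank)
  reduced <- factor_scores(data, bank, items = ids)
  factors <- setdiff(colnames(full), "total")
  orig <- cor(full[, factors, drop = FALSE])
  cross <- cor(full[, factors, drop = FALSE], reduced[, factors, drop = FALSE])
  structure(list(original = orig, original_by_short = cross),
            class = "correlation_matrices")
}

#' Write correlation matrices to CSV
#'
#' @param x A `correlation_matrices` object.
#' @param original_path,cross_path Output paths (either may be `NULL` to
#'   skip).
#' @return `x`, invisibly.
#' @export
write_correlation_matrices <- function(x, original_path = NULL, cross_path = NULL) {
  save_one <- function(m, path) {
    df <- cbind(factor = rownames(m), as.data.frame(m))
    readr::write_csv(as_tibble(df), path)
  }
  if (!is.null(original_path)) save_one(x$original, original_path)
  if (!is.null(cross_path)) save_one(x$original_by_short, cross_path)
  invisible(x)
}

#' Regression error metrics
#'
#' `MAE = mean|y - yhat|`, `RMSE = sqrt(mean((y - yhat)^2))`,
#' `R2 = 1 - SS_res / SS_tot`, and `MAPE = 100 * mean(|y - yhat| / y)` in
#' percent. Observations with `y = 0` are excluded from MAPE (with a warning
#' reporting how many; this cannot occur for sums of 1-and-up Likert scores).
#'
#' @param y Observed values.
#' @param yhat Predicted values, same length.
#' @return Tibble with one row: `MAE`, `RMSE`, `R2`, `MAPE`.
#' @examples
#' regression_metrics(c(10, 20), c(12, 18))
#' @export
regression_metrics <- function(y, yhat) {
  if (length(y) != length(yhat)) abort("y and yhat must have the same length")
  err <- y - yhat
  mae <- mean(abs(err))
  rmse <- sqrt(mean(err^2))
  r2 <- 1 - sum(err^2) / sum((y - mean(y))^2)
  nz <- y != 0
  if (!all(nz)) {
    warn(sprintf("%d observation(s) with target 0 excluded from MAPE", sum(!nz)))
  }
  mape <- 100 * mean(abs(err[nz]) / abs(y[nz]))
  tibble(MAE = mae, RMSE = rmse, R2 = r2, MAPE = mape)
}
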