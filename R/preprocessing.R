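#' Remove respondents with any missing item response
#'
#' Listwise deletion: only fully observed rows are kept. Counts are appended
#' to the table's cleaning log.
#'
#' @param data A `likert_tbl` (see [likert_responses()]).
#' @return The filtered `likert_tbl`; inspect the log with [cleaning_log()].
#' @export
remove_missing <- function(data) {
  bounds <- scale_bounds(data)
  X <- response_matrix(data)
  keep <- stats::complete.cases(X)
  if (!any(keep)) abort("all respondents have missing responses; nothing to analyze")
  out <- new_likert_tbl(as_tibble(as.data.frame(X[keep, , drop = FALSE])),
                        bounds["min"], bounds["max"])
  log <- cleaning_log(data)
  log$n_input <- log$n_input %||% nrow(X)
  log$n_removed_missing <- sum(!keep)
  log$n_retained <- sum(keep)
  log$steps <- c(log$steps, "missing")
  set_cleaning_log(out, log)
}

#' Flag and drop multivariate outliers by Mahalanobis distance
#'
#' Squared Mahalanobis distances to the sample mean,
#' \eqn{D^2 = (x-\bar x)^\top S^{-1} (x-\bar x)} with the classical sample
#' covariance \eqn{S}, are compared against the chi-square quantile
#' \eqn{\chi^2_{p,\,1-\alpha}}. Rows strictly above the threshold are removed;
#' ties at the threshold are retained.
#'
#' @param data A complete (no missing cells) `likert_tbl`.
#' @param alpha Significance level of the chi-square cutoff (default 0.01).
#' @return The filtered `likert_tbl` with updated cleaning log.
#' @export
mahalanobis_filter <- function(data, alpha = 0.01) {
  X <- response_matrix(data)
  if (anyNA(X)) abort("mahalanobis_filter requires a complete matrix; run remove_missing() first")
  n <- nrow(X); p <- ncol(X)
  if (n <= p) abort(sprintf("need more respondents (%d) than items (%d) for a sample covariance", n, p))
  S <- cov(X)
  d2 <- tryCatch(
    mahalanobis(X, colMeans(X), S),
    error = function(e) {
      warn("singular covariance; applying ridge jitter to the diagonal")
      eps <- 1e-8 * sum(diag(S)) / p
      mahalanobis(X, colMeans(X), S + diag(eps, p))
    }
  )
  thr <- qchisq(1 - alpha, df = p)
  keep <- d2 <= thr
  bounds <- scale_bounds(data)
  out <- new_likert_tbl(as_tibble(as.data.frame(X[keep, , drop = FALSE])),
                        bounds["min"], bounds["max"])
  log <- cleaning_log(data)
  log$n_input <- log$n_input %||% n
  log$n_removed_outlier <- sum(!keep)
  log$n_retained <- sum(keep)
  log$chi2_threshold <- thr
  log$alpha <- alpha
  log$steps <- c(log$steps, "outlier")
  set_cleaning_log(out, log)
}

#' Flip reverse-keyed items to direct scoring
#'
#' For every reverse-keyed item, responses are mapped
#' \eqn{x \mapsto (\mathrm{min} + \mathrm{max}) - x} (6 − x on a 1..5 scale);
#' direct items are untouched. Applying the operation twice restores the
#' original table.
#'
#' @param data A `likert_tbl`.
#' @param bank The matching [item_bank].
#' @return The direct-scored `likert_tbl`.
#' @export
apply_reverse_scoring <- function(data, bank) {
  bounds <- scale_bounds(data)
  flipsum <- bounds["min"] + bounds["max"]
  out <- data
  rev_ids <- intersect(bank$item_id[bank$reverse], names(out))
  for (id in rev_ids) out[[id]] <- flipsum - out[[id]]
  log <- cleaning_log(data)
  log$steps <- c(log$steps, "reverse")
  set_cleaning_log(new_likert_tbl(out, bounds["min"], bounds["max"]), log)
}

#' Full preprocessing pipeline
#'
#' Fixed order: listwise missing removal, Mahalanobis outlier exclusion at
#' `alpha`, then reverse-score flipping. The order is recorded in the log.
#'
#' @inheritParams mahalanobis_filter
#' @inheritParams apply_reverse_scoring
#' @return A cleaned, direct-scored `likert_tbl`.
#' @export
clean_responses <- function(data, bank, alpha = 0.01) {
  data |>
    remove_missing() |>
    mahalanobis_filter(alpha = alpha) |>
    apply_reverse_scoring(bank)
}

#' Cleaning log of a response table
#'
#' @param data A `likert_tbl`.
#' @return A list with counts `n_input`, `n_removed_missing`,
#'   `n_removed_outlier`, `n_retained`, the chi-square threshold used, and the
#'   order of applied steps.
#' @export
cleaning_log <- function(data) {
  log <- attr(data, "cleaning_log") %||% list(steps = character())
  log
}

set_cleaning_log <- function(data, log) {
  log$n_removed_missing <- log$n_removed_missing %||% 0L
  log$n_removed_outlier <- log$n_removed_outlier %||% 0L
  attr(data, "cleaning_log") <- log
  data
}
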