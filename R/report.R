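#' Assemble a full validation report for a short form
#'
#' Bundles every validation quantity the package computes for a short form:
#' per-factor and mean Cronbach's alpha (short and full form), per-factor and
#' mean convergent correlations, the cluster-to-factor alignment (when the
#' short form came out of the semantic pipeline), per-item silhouettes, and
#' held-out prediction metrics.
#'
#' @inheritParams convergent_correlations
#' @param alignment Optional `alignment_result`.
#' @param silhouettes Optional silhouette tibble from [silhouette_scores()].
#' @param prediction Optional `prediction_result` from
#'   [predict_original_scores()].
#' @return A list of class `validation_report`.
#' @export
validation_report <- function(data, short, bank, alignment = NULL,
                              silhouettes = NULL, prediction = NULL) {
  ids <- short_form_ids(short)
  alphas_short <- factor_alphas(data, bank, items = ids)
  alphas_full <- factor_alphas(data, bank)
  conv <- convergent_correlations(data, short, bank)
  rep <- list(
    method = if (inherits(short, "short_form")) method_tag(short) else NA_character_,
    n_respondents = nrow(data),
    items = ids,
    alpha = list(per_factor = alphas_short,
                 mean = attr(alphas_short, "mean_alpha"),
                 full_per_factor = alphas_full,
                 full_mean = attr(alphas_full, "mean_alpha")),
    convergent = list(per_factor = conv, mean = attr(conv, "mean_r"),
                      total = attr(conv, "total_r")),
    alignment = alignment,
    silhouettes = silhouettes,
    prediction = prediction
  )
  structure(rep, class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report (%s): %d items, n = %d>\n",
              x$method, length(x$items), x$n_respondents))
  cat(sprintf("  mean alpha (short) %.3f | mean alpha (full) %.3f | mean convergent r %.3f\n",
              x$alpha$mean, x$alpha$full_mean, x$convergent$mean))
  if (!is.null(x$alignment)) {
    cat(sprintf("  alignment accuracy %.3f\n", x$alignment$accuracy))
  }
  if (!is.null(x$prediction)) print(x$prediction$metrics)
  invisible(x)
}

#' @method glance validation_report
#' @export
glance.validation_report <- function(x, ...) {
  tibble(method = x$method, n_items = length(x$items),
         mean_alpha = x$alpha$mean, mean_convergent_r = x$convergent$mean,
         total_r = x$convergent$total,
         accuracy = if (is.null(x$alignment)) NA_real_ else x$alignment$accuracy,
         mean_silhouette = if (is.null(x$silhouettes)) NA_real_ else
           attr(x$silhouettes, "mean_silhouette"))
}

#' Serialize a validation report to JSON
#'
#' The JSON schema is stable: scalar summaries as numbers, per-factor tables
#' as arrays of records, confusion matrices as named row objects. A report
#' written and re-read round-trips its numeric content exactly.
#'
#' @param report A `validation_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path) {
  x <- list(
    method = report$method,
    n_respondents = report$n_respondents,
    items = report$items,
    alpha = list(
      per_factor = report$alpha$per_factor,
      mean = report$alpha$mean,
      full_per_factor = report$alpha$full_per_factor,
      full_mean = report$alpha$full_mean
    ),
    convergent = list(per_factor = report$convergent$per_factor,
                      mean = report$convergent$mean,
                      total = report$convergent$total)
  )
  if (!is.null(report$alignment)) {
    x$alignment <- list(
      confusion = as.data.frame(cbind(cluster = rownames(report$alignment$confusion),
                                      as.data.frame(report$alignment$confusion))),
      mapping = as.list(report$alignment$mapping),
      accuracy = report$alignment$accuracy
    )
  }
  if (!is.null(report$silhouettes)) {
    x$silhouettes <- list(per_item = report$silhouettes,
                          mean = attr(report$silhouettes, "mean_silhouette"))
  }
  if (!is.null(report$prediction)) {
    x$prediction <- list(metrics = report$prediction$metrics,
                         n_train = report$prediction$n_train,
                         n_test = report$prediction$n_test)
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a serialized validation report
#'
#' @param path Path to a JSON file written by [write_validation_report()].
#' @return A `validation_report`-shaped list (tables as tibbles).
#' @export
read_validation_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$items <- as.character(x$items)
  x$alpha$per_factor <- as_tibble(x$alpha$per_factor)
  x$alpha$full_per_factor <- as_tibble(x$alpha$full_per_factor)
  x$convergent$per_factor <- as_tibble(x$convergent$per_factor)
  if (!is.null(x$silhouettes)) {
    sil <- as_tibble(x$silhouettes$per_item)
    attr(sil, "mean_silhouette") <- x$silhouettes$mean
    x$silhouettes <- sil
  }
  if (!is.null(x$prediction)) x$prediction$metrics <- as_tibble(x$prediction$metrics)
  if (!is.null(x$alignment)) {
    conf <- x$alignment$confusion
    m <- as.matrix(conf[setdiff(names(conf), "cluster")])
    rownames(m) <- conf$cluster
    x$alignment <- structure(list(confusion = m,
                                  mapping = unlist(x$alignment$mapping),
                                  accuracy = x$alignment$accuracy),
                             class = "alignment_result")
  }
  structure(x, class = "validation_report")
}

#' Bundled reference results for the IPIP-50
#'
#' Plain-text copies of published reference results from a transformer-based
#' embedding reduction of the public IPIP-50 Big-Five item pool, shipped with
#' the package so worked examples and regression checks run without the
#' original (very large) response dump or an embedding model:
#'
#' * `"confusion"` — cluster-by-factor confusion matrix of the five semantic
#'   clusters against the Big Five factor labels (clusters in rows).
#' * `"shortform"` — the 30 selected items with cluster label, original
#'   subscale, per-item silhouette and centroid distance.
#' * `"validity"` — per-factor convergent validity of the CTT/PCA, GA and TE
#'   short forms against the full scale.
#' * `"alphas"` — per-factor Cronbach's alpha of the full scale and the three
#'   short forms.
#'
#' @param which One of `"confusion"`, `"shortform"`, `"validity"`, `"alphas"`.
#' @return A tibble, except `"confusion"` which returns a count matrix.
#' @examples
#' align_confusion(ipip50_reference("confusion"))
#' @export
ipip50_reference <- function(which = c("confusion", "shortform", "validity", "alphas")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0("ipip50_te_", which, ".csv"),
                      package = "shortform", mustWork = TRUE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (which == "confusion") {
    m <- as.matrix(df[setdiff(names(df), "cluster")])
    rownames(m) <- as.character(df$cluster)
    return(m)
  }
  df
}
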