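#' Construct a short-form selection table
#'
#' @param selections Tibble with columns `item_id`, `group`, `rank` and
#'   optionally `distance`, `silhouette`.
#' @param method_tag One of `"TE"`, `"CTT"`, `"PCA"`, `"GA"`.
#' @param m Configured per-group selection size.
#' @return A tibble of class `short_form`.
#' @export
short_form <- function(selections, method_tag, m = NA_integer_) {
  selections <- as_tibble(selections)
  if (anyDuplicated(selections$item_id)) abort("short form selects an item twice")
  if (!method_tag %in% c("TE", "CTT", "PCA", "GA")) {
    abort("method_tag must be one of TE, CTT, PCA, GA")
  }
  attr(selections, "method_tag") <- method_tag
  attr(selections, "m") <- as.integer(m)
  class(selections) <- unique(c("short_form", class(selections)))
  selections
}

#' @rdname short_form
#' @param x A `short_form`.
#' @export
method_tag <- function(x) attr(x, "method_tag")

#' Select the items nearest each cluster centroid
#'
#' Within every cluster, items are ranked by cosine distance to the cluster
#' centroid (ascending); the `m` nearest are kept. Ties are broken by
#' lexicographic `item_id`. Clusters with fewer than `m` items contribute all
#' their items, with a warning.
#'
#' @param X The [embedding_matrix] the clustering was computed in (same
#'   space).
#' @param sol A `cluster_solution` from [kmeans_cluster()].
#' @param m Items to keep per cluster (default 6).
#' @return A [short_form] (`method_tag = "TE"`) with columns `item_id`,
#'   `group` (cluster label), `distance`, `rank`.
#' @export
select_items <- function(X, sol, m = 6L) {
  if (!identical(space_tag(X), sol$space_tag)) {
    abort("embedding space differs from the space the clustering used")
  }
  M <- unclass(X)
  ids <- rownames(M)
  picks <- lapply(sort(unique(sol$labels)), function(g) {
    rows <- which(sol$labels == g)
    d <- cosine_distance(M[rows, , drop = FALSE],
                         sol$centroids[as.character(g), ])
    ord <- order(d, ids[rows])
    if (length(rows) < m) {
      warn(sprintf("cluster %s has %d items, fewer than m = %d; keeping all",
                   g, length(rows), m))
    }
    keep <- ord[seq_len(min(m, length(rows)))]
    tibble(item_id = ids[rows][keep], group = g,
           distance = d[keep], rank = seq_along(keep))
  })
  short_form(dplyr::bind_rows(picks), "TE", m)
}

#' Run the full transformer-embedding reduction pipeline
#'
#' Composition of the semantic reduction stages: dimensionality reduction of
#' the item embeddings, K-means clustering into `k` groups, selection of the
#' `m` items nearest each centroid by cosine distance, silhouette diagnostics,
#' and Hungarian alignment of clusters against the bank's subscale labels.
#'
#' @param bank An [item_bank].
#' @param E A raw [embedding_matrix] aligned to `bank`.
#' @param k Number of clusters (default: number of subscales in the bank).
#' @param m Items kept per cluster (default 6).
#' @param r Reduced dimensionality (default 5).
#' @param seed Integer seed driving clustering restarts.
#' @param reduce_method Passed to [reduce_dim()].
#' @param silhouette_metric Passed to [silhouette_scores()].
#' @return A `te_reduction` list: `short_form` (with per-item silhouettes
#'   joined), `solution`, `alignment`, `silhouettes`, and the reduced space
#'   `reduced`.
#' @export
run_te_reduction <- function(bank, E, k = NULL, m = 6L, r = 5L, seed = 1L,
                             reduce_method = "pca",
                             silhouette_metric = "euclidean") {
  k <- k %||% length(unique(bank$subscale))
  if (k < 2) abort("the reduction pipeline needs k >= 2 clusters")
  if (!identical(rownames(E), bank$item_id)) {
    abort("embedding rows must match the item bank (same ids, same order)")
  }
  Xr <- reduce_dim(E, r = r, method = reduce_method, seed = seed)
  sol <- kmeans_cluster(Xr, k = k, seed = seed)
  sf <- select_items(Xr, sol, m = m)
  sil <- silhouette_scores(Xr, sol, metric = silhouette_metric)
  sf <- dplyr::left_join(sf, sil[c("item_id", "silhouette")], by = "item_id")
  sf <- short_form(sf, "TE", m)
  align <- hungarian_align(sol$labels[bank$item_id], bank$subscale)
  structure(list(short_form = sf, solution = sol, alignment = align,
                 silhouettes = sil, reduced = Xr),
            class = "te_reduction")
}

#' @export
print.te_reduction <- function(x, ...) {
  cat(sprintf("<te_reduction: %d items selected, alignment accuracy %.3f, mean silhouette %.3f>\n",
              nrow(x$short_form), x$alignment$accuracy,
              attr(x$silhouettes, "mean_silhouette")))
  invisible(x)
}

#' @method glance te_reduction
#' @export
glance.te_reduction <- function(x, ...) {
  tibble(n_selected = nrow(x$short_form),
         k = x$solution$k,
         accuracy = x$alignment$accuracy,
         mean_silhouette_all = attr(x$silhouettes, "mean_silhouette"),
         mean_silhouette_selected = mean(x$short_form$silhouette),
         inertia = x$solution$inertia)
}

#' @method tidy te_reduction
#' @export
tidy.te_reduction <- function(x, ...) as_tibble(x$short_form)
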