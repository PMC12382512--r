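#' K-means clustering of item embeddings
#'
#' Standard K-means (within-cluster sum of squares objective) with k-means++
#' initialization and multiple restarts; the restart with the lowest
#' within-cluster sum of squares wins. Cluster labels are integers `0..k-1`, the
#' convention used when matching clusters against factor labels.
#'
#' @param X An [embedding_matrix] (usually the reduced space).
#' @param k Number of clusters; `k <= nrow(X)`.
#' @param seed Integer seed; fixed seed plus fixed input gives an identical
#'   solution.
#' @param n_init Number of random restarts.
#' @return A `cluster_solution`: list with `labels` (named integer vector,
#'   `0..k-1`), `centroids` (k x r matrix, row `j` the mean of the vectors
#'   labelled `j`), `k`, `inertia` (total within-cluster sum of squares) and
#'   `space_tag`.
#' @export
kmeans_cluster <- function(X, k, seed = 1L, n_init = 10L) {
  if (k < 1) abort("k must be at least 1")
  if (k > nrow(X)) abort("k cannot exceed the number of items")
  M <- unclass(X)
  if (k == nrow(M)) {
    labels <- seq_len(k) - 1L
    names(labels) <- rownames(M)
    centroids <- M
    rownames(centroids) <- as.character(labels)
    return(structure(list(labels = labels, centroids = centroids,
                          k = as.integer(k), inertia = 0,
                          space_tag = space_tag(X)),
                     class = "cluster_solution"))
  }
  # k-means++ seeding, best of n_init restarts by within-cluster sum of squares
  fit <- withr_seed(seed, {
    best <- NULL
    for (attempt in seq_len(n_init)) {
      centers <- kmeanspp_centers(M, k)
      cand <- tryCatch(kmeans(M, centers = centers, iter.max = 100L),
                       error = function(e) NULL, warning = function(w) NULL)
      if (is.null(cand) || any(tabulate(cand$cluster, nbins = k) == 0)) next
      if (is.null(best) || cand$tot.withinss < best$tot.withinss) best <- cand
    }
    best
  })
  if (is.null(fit)) abort("K-means produced an empty cluster in every restart")
  labels <- as.integer(fit$cluster) - 1L
  names(labels) <- rownames(M)
  centroids <- fit$centers
  rownames(centroids) <- as.character(seq_len(k) - 1L)
  structure(list(labels = labels, centroids = centroids, k = as.integer(k),
                 inertia = fit$tot.withinss, space_tag = space_tag(X)),
            class = "cluster_solution")
}

# k-means++ initial centers: first uniform, then proportional to the squared
# distance to the nearest already-chosen center
kmeanspp_centers <- function(M, k) {
  n <- nrow(M)
  idx <- sample.int(n, 1)
  d2 <- rowSums(sweep(M, 2, M[idx, ])^2)
  for (j in seq_len(k - 1)) {
    probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    nxt <- sample.int(n, 1, prob = probs)
    idx <- c(idx, nxt)
    d2 <- pmin(d2, rowSums(sweep(M, 2, M[nxt, ])^2))
  }
  M[idx, , drop = FALSE]
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("<cluster_solution: k = %d, %d items, inertia = %.4g, space = %s>\n",
              x$k, length(x$labels), x$inertia, x$space_tag))
  print(table(cluster = x$labels))
  invisible(x)
}

#' Per-item silhouette scores
#'
#' For item `i` with mean distance `a(i)` to its own cluster (excluding
#' itself) and `b(i)` the smallest mean distance to any other cluster,
#' `s(i) = (b(i) - a(i)) / max(a(i), b(i))`. Items in singleton clusters get
#' `s = 0`. Values lie in `[-1, 1]`; larger means tighter, better-separated
#' clusters.
#'
#' @param X The [embedding_matrix] the clustering was computed in.
#' @param sol A `cluster_solution` (or an integer/character label vector in
#'   row order of `X`).
#' @param metric `"euclidean"` (default) or `"cosine"`.
#' @return A tibble with columns `item_id`, `cluster`, `silhouette`; the mean
#'   silhouette is stored in attribute `"mean_silhouette"`.
#' @export
silhouette_scores <- function(X, sol, metric = c("euclidean", "cosine")) {
  metric <- match.arg(metric)
  labels <- if (inherits(sol, "cluster_solution")) sol$labels else sol
  M <- unclass(X)
  if (length(labels) != nrow(M)) abort("one label per item required")
  uniq <- sort(unique(labels))
  if (length(uniq) < 2) abort("silhouettes need at least 2 clusters")
  D <- pairwise_distances(M, metric)
  n <- nrow(M)
  # mean distance from every point to every cluster, vectorized over clusters
  member <- vapply(uniq, function(g) as.numeric(labels == g), numeric(n))
  sums <- D %*% member                      # n x k total distance to cluster g
  sizes <- colSums(member)
  own <- match(labels, uniq)
  s <- numeric(n)
  for (i in seq_len(n)) {
    size_own <- sizes[own[i]]
    if (size_own == 1) { s[i] <- 0; next }
    a <- sums[i, own[i]] / (size_own - 1)   # exclude self (self-distance 0)
    b <- min(sums[i, -own[i]] / sizes[-own[i]])
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  ids <- rownames(M) %||% as.character(seq_len(n))
  out <- tibble(item_id = ids, cluster = labels, silhouette = s)
  attr(out, "mean_silhouette") <- mean(s)
  out
}

pairwise_distances <- function(M, metric) {
  if (metric == "euclidean") {
    as.matrix(stats::dist(M))
  } else {
    nrm <- sqrt(rowSums(M^2))
    if (any(nrm == 0)) abort("cosine distance undefined for a zero-norm vector")
    S <- (M / nrm) %*% t(M / nrm)
    D <- 1 - S
    D[D < 0] <- 0
    diag(D) <- 0
    D
  }
}

#' Cosine distance between item vectors and a centroid
#'
#' `1 - x . c / (||x|| ||c||)`; invariant to positive rescaling of either
#' argument.
#'
#' @param M Numeric matrix of item vectors (rows).
#' @param centroid Numeric vector.
#' @return Numeric vector of distances in `[0, 2]`.
#' @export
cosine_distance <- function(M, centroid) {
  M <- as.matrix(M)
  nx <- sqrt(rowSums(M^2))
  nc <- sqrt(sum(centroid^2))
  if (nc == 0 || any(nx == 0)) abort("cosine distance undefined for a zero-norm vector")
  as.numeric(1 - (M %*% centroid) / (nx * nc))
}
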