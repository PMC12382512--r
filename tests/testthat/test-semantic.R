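test_that("dimensionality reduction honors its shape and determinism contracts", {
  gen <- gen_embeddings(k = 5, per_cluster = 10, d = 64, separation = 6, seed = 2)
  E <- gen$embeddings
  R1 <- reduce_dim(E, r = 5)
  expect_identical(dim(R1), c(50L, 5L))
  expect_identical(space_tag(R1), "reduced")
  R2 <- reduce_dim(E, r = 5)
  expect_identical(unclass(R1), unclass(R2))   # bitwise-identical rerun

  # structure check: clusters recoverable downstream in the reduced space
  sol <- kmeans_cluster(R1, k = 5, seed = 1)
  expect_equal(hungarian_align(sol$labels, gen$labels)$accuracy, 1.0)

  expect_identical(reduce_dim(E, r = 64, method = "none"), E)
  expect_error(reduce_dim(E, r = 64), "below input dimension")
  expect_error(reduce_dim(E, r = 70, method = "none"), "equal to the input")
})

test_that("k-means recovers well-separated blobs and satisfies centroid identities", {
  set.seed(4)
  blob1 <- matrix(rnorm(40, mean = 0, sd = 0.1), 20, 2)
  blob2 <- matrix(rnorm(40, mean = 5, sd = 0.1), 20, 2)
  X <- embedding_matrix(rbind(blob1, blob2), sprintf("p%02d", 1:40))
  sol <- kmeans_cluster(X, k = 2, seed = 1)
  truth <- rep(0:1, each = 20)
  expect_equal(hungarian_align(sol$labels, truth)$accuracy, 1.0)
  # centroid j is the mean of its members
  for (g in 0:1) {
    expect_equal(sol$centroids[as.character(g), ],
                 colMeans(unclass(X)[sol$labels == g, ]),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
  # k = p: every point its own cluster, zero inertia
  solp <- kmeans_cluster(X[1:6, ], k = 6, seed = 1)
  expect_equal(solp$inertia, 0)
  expect_equal(sort(unname(solp$labels)), 0:5)
})

test_that("centroid-nearest selection matches a brute-force cosine ranking", {
  # six unit vectors at hand-checkable angles around the first axis
  ang <- c(0.05, 0.3, 0.6, 0.9, 1.2, 1.5)
  M <- cbind(cos(ang), sin(ang))
  X <- embedding_matrix(M, paste0("v", 1:6))
  sol <- structure(list(labels = setNames(rep(0L, 6), rownames(M)),
                        centroids = matrix(c(1, 0), 1, dimnames = list("0", NULL)),
                        k = 1L, inertia = 0, space_tag = "raw"),
                   class = "cluster_solution")
  sf <- select_items(X, sol, m = 3)
  oracle <- order(sapply(1:6, function(i) 1 - sum(M[i, ] * c(1, 0)) /
                           sqrt(sum(M[i, ]^2))))
  expect_equal(sf$item_id, paste0("v", oracle[1:3]))
  expect_equal(sf$rank, 1:3)
  expect_equal(sf$distance, sort(1 - cos(ang))[1:3], tolerance = 1e-12)

  # scale invariance: rescaling one vector leaves its cosine distance unchanged
  M2 <- M; M2[3, ] <- 7.5 * M2[3, ]
  X2 <- embedding_matrix(M2, paste0("v", 1:6))
  sf2 <- select_items(X2, sol, m = 3)
  expect_equal(sf2$item_id, sf$item_id)
  expect_equal(sf2$distance, sf$distance, tolerance = 1e-12)

  # an item exactly at the centroid has distance 0 and rank 1
  M3 <- rbind(c(1, 0), M[-1, ])
  sf3 <- select_items(embedding_matrix(M3, paste0("v", 1:6)), sol, m = 1)
  expect_equal(sf3$distance, 0)
  expect_equal(sf3$rank, 1L)
})

test_that("selection ties break lexicographically and small clusters warn", {
  M <- rbind(c(1, 0), c(1, 0), c(0, 1))   # first two identical
  X <- embedding_matrix(M, c("b_item", "a_item", "c_item"))
  sol <- structure(list(labels = setNames(c(0L, 0L, 0L), rownames(M)),
                        centroids = matrix(c(1, 0), 1, dimnames = list("0", NULL)),
                        k = 1L, inertia = 0, space_tag = "raw"),
                   class = "cluster_solution")
  sf <- select_items(X, sol, m = 2)
  expect_equal(sf$item_id, c("a_item", "b_item"))
  expect_warning(select_items(X, sol, m = 5), "fewer than m")
})

test_that("silhouettes match the naive double-loop oracle and cluster::silhouette", {
  set.seed(11)
  for (metric in c("euclidean", "cosine")) {
    M <- matrix(rnorm(25 * 3), 25)
    rownames(M) <- sprintf("i%02d", 1:25)
    labels <- sample(0:2, 25, replace = TRUE)
    X <- embedding_matrix(M, rownames(M))
    got <- silhouette_scores(X, setNames(labels, rownames(M)), metric = metric)
    expect_equal(got$silhouette, naive_silhouette(M, labels, metric),
                 tolerance = 1e-12)
  }
  M <- matrix(rnorm(20 * 4), 20); rownames(M) <- sprintf("i%02d", 1:20)
  labels <- rep(0:3, each = 5)
  got <- silhouette_scores(embedding_matrix(M, rownames(M)),
                           setNames(labels, rownames(M)))
  ref <- cluster::silhouette(labels + 1L, stats::dist(M))
  expect_equal(got$silhouette, as.numeric(ref[, "sil_width"]), tolerance = 1e-10)
})

test_that("silhouette edge geometry behaves as defined", {
  # two tight, far-apart pairs: all silhouettes near 1
  M <- rbind(c(0, 0), c(0, 0.01), c(10, 10), c(10, 10.01))
  X <- embedding_matrix(M, paste0("p", 1:4))
  s <- silhouette_scores(X, setNames(c(0, 0, 1, 1), rownames(M)))
  expect_true(all(s$silhouette > 0.9))
  expect_true(all(s$silhouette >= -1 & s$silhouette <= 1))

  # a point equidistant between its own and the nearest other cluster: s = 0
  M2 <- rbind(c(0, 0), c(2, 0), c(1, 0))
  s2 <- silhouette_scores(embedding_matrix(cbind(M2, 0), paste0("q", 1:3)),
                          c(0, 1, 0))
  expect_equal(s2$silhouette[3], 0)
  # singleton cluster convention
  expect_equal(s2$silhouette[2], 0)
  expect_error(silhouette_scores(X, rep(0, 4)), "2 clusters")
})

test_that("Hungarian alignment equals exhaustive permutation search", {
  set.seed(21)
  for (rep in 1:100) {
    k <- sample(2:5, 1)
    m <- matrix(rpois(k * k, lambda = 5), k,
                dimnames = list(paste0("c", 1:k), paste0("f", 1:k)))
    res <- align_confusion(m)
    matched <- sum(m[cbind(seq_len(k), match(res$mapping, colnames(m)))])
    expect_equal(matched, brute_force_assignment(m))
    expect_equal(res$accuracy, matched / sum(m))
    expect_setequal(res$mapping, colnames(m))   # a permutation
  }
  # k = 7 spot check
  m7 <- matrix(rpois(49, 4), 7, dimnames = list(paste0("c", 1:7), paste0("f", 1:7)))
  expect_equal(sum(m7[cbind(1:7, match(align_confusion(m7)$mapping, colnames(m7)))]),
               brute_force_assignment(m7))
})

test_that("alignment handles diagonal, label-vector and degenerate inputs", {
  d <- diag(c(5, 3, 7)); dimnames(d) <- list(0:2, c("X", "Y", "Z"))
  res <- align_confusion(d)
  expect_equal(unname(res$mapping), c("X", "Y", "Z"))
  expect_equal(res$accuracy, 1.0)

  res2 <- hungarian_align(c(0, 0, 1, 1, 1), c("A", "A", "B", "B", "A"))
  expect_equal(unname(res2$mapping[c("0", "1")]), c("A", "B"))
  expect_equal(res2$accuracy, 4 / 5)
  expect_error(hungarian_align(integer(0), character(0)), "empty")
})

test_that("the full pipeline recovers generator clusters and rejects k = 1", {
  gen <- gen_embeddings(k = 5, per_cluster = 10, d = 48, separation = 6, seed = 7)
  bank <- item_bank(tibble::tibble(
    item_id = names(gen$labels), text = paste("text", names(gen$labels)),
    subscale = paste0("F", gen$labels), reverse = FALSE))
  te <- run_te_reduction(bank, gen$embeddings, k = 5, m = 6, r = 5, seed = 3)
  expect_equal(te$alignment$accuracy, 1.0)
  expect_equal(nrow(te$short_form), 30)
  expect_equal(unname(table(te$short_form$group)), rep(6L, 5), ignore_attr = TRUE)
  expect_true(all(c("silhouette", "distance", "rank") %in% names(te$short_form)))
  expect_error(run_te_reduction(bank, gen$embeddings, k = 1), "k >= 2")

  # m larger than the smallest cluster: warn, smaller short form
  w <- capture_warnings(sf <- select_items(te$reduced, te$solution, m = 11))
  expect_true(all(grepl("fewer than m", w)) && length(w) > 0)
  expect_lte(nrow(sf), 55)
})

test_that("selection is invariant to within-cluster input order", {
  gen <- gen_embeddings(k = 3, per_cluster = 8, d = 16, separation = 6, seed = 5)
  X <- reduce_dim(gen$embeddings, r = 4)
  sol <- kmeans_cluster(X, k = 3, seed = 1)
  sf <- select_items(X, sol, m = 4)
  perm <- sample(nrow(X))
  Xp <- embedding_matrix(unclass(X)[perm, ], rownames(X)[perm], "reduced")
  solp <- list(labels = sol$labels[rownames(Xp)], centroids = sol$centroids,
               k = sol$k, inertia = sol$inertia, space_tag = sol$space_tag)
  class(solp) <- "cluster_solution"
  sfp <- select_items(Xp, solp, m = 4)
  expect_equal(dplyr::arrange(as.data.frame(sf), item_id),
               dplyr::arrange(as.data.frame(sfp), item_id))
})
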