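test_that("generated responses are reproducible and respect the Likert range", {
  spec <- synthetic_spec(n_respondents = 400, seed = 3)
  g1 <- gen_responses(spec)
  g2 <- gen_responses(spec)
  expect_identical(as.data.frame(g1$responses), as.data.frame(g2$responses))
  X <- response_matrix(g1$responses)
  expect_true(all(X >= 1 & X <= 5))
  expect_equal(dim(X), c(400L, 50L))
  expect_equal(nrow(g1$bank), 50)
  expect_equal(sort(unique(g1$truth$factor)), sort(unique(g1$bank$subscale)))
  # reverse items are stored flipped and carry reworded text
  expect_true(all(!is.na(g1$bank$reworded_text[g1$bank$reverse])))
})

test_that("observed alpha tracks the compound-symmetry closed form", {
  # equal loadings 0.7 on 6 items: latent inter-item r = 0.49; categorization
  # attenuates it, so alpha is compared through the *observed* mean inter-item
  # correlation plugged into the same closed form
  spec <- synthetic_spec(
    n_respondents = 5000,
    factors = tibble::tibble(label = c("F1", "F2"), n_items = 6L,
                             loadings = list(rep(0.7, 6), rep(0.7, 6))),
    factor_cor = 0.2, reverse_fraction = 0, seed = 11)
  g <- gen_responses(spec)
  X <- response_matrix(g$responses)
  for (f in c("F1", "F2")) {
    ids <- g$bank$item_id[g$bank$subscale == f]
    C <- cor(X[, ids])
    rbar <- mean(C[upper.tri(C)])
    closed <- 6 * rbar / (1 + 5 * rbar)
    expect_lt(abs(cronbach_alpha(X[, ids]) - closed), 0.05)
  }
})

test_that("zero loadings give uncorrelated items", {
  spec <- synthetic_spec(
    n_respondents = 5000,
    factors = tibble::tibble(label = c("Z1", "Z2"), n_items = 5L,
                             loadings = list(rep(1e-6, 5), rep(1e-6, 5))),
    factor_cor = 0, reverse_fraction = 0, seed = 21)
  g <- gen_responses(spec)
  C <- cor(response_matrix(g$responses))
  expect_lt(max(abs(C[upper.tri(C)])), 0.05)
})

test_that("the latent correlation structure converges to the loading model", {
  spec <- synthetic_spec(
    n_respondents = 20000,
    factors = tibble::tibble(label = c("F1", "F2"), n_items = 5L,
                             loadings = list(seq(0.75, 0.45, length.out = 5),
                                             seq(0.75, 0.45, length.out = 5))),
    factor_cor = 0.2, reverse_fraction = 0, seed = 31)
  g <- gen_responses(spec)
  lam <- g$truth$loading
  phi <- spec$factor_cor
  fidx <- match(g$truth$factor, c("F1", "F2"))
  target <- outer(seq_along(lam), seq_along(lam), Vectorize(function(i, j) {
    if (i == j) 1 else lam[i] * lam[j] * phi[fidx[i], fidx[j]]
  }))
  emp <- cor(g$latent)
  expect_lt(max(abs(emp - target)), 0.05)

  # discretization keeps the sign and attenuates the magnitude
  disc <- cor(response_matrix(apply_reverse_scoring(g$responses, g$bank)))
  off <- upper.tri(emp)
  expect_true(all(abs(disc[off]) <= abs(emp[off]) + 0.02))
  big <- abs(emp[off]) > 0.1
  expect_true(all(sign(disc[off][big]) == sign(emp[off][big])))
})

test_that("synthetic embeddings are unit norm with controllable separation", {
  gen <- gen_embeddings(k = 5, per_cluster = 10, d = 32, separation = 10, seed = 2)
  expect_equal(sqrt(rowSums(unclass(gen$embeddings)^2)), rep(1, 50),
               tolerance = 1e-9, ignore_attr = TRUE)
  sol <- kmeans_cluster(reduce_dim(gen$embeddings, r = 5), k = 5, seed = 1)
  expect_equal(hungarian_align(sol$labels, gen$labels)$accuracy, 1.0)

  # separation 0: labels carry no signal, accuracy near chance
  acc <- vapply(1:20, function(s) {
    g0 <- gen_embeddings(k = 5, per_cluster = 10, d = 32, separation = 0, seed = s)
    s0 <- kmeans_cluster(reduce_dim(g0$embeddings, r = 5), k = 5, seed = s)
    hungarian_align(s0$labels, g0$labels)$accuracy
  }, numeric(1))
  expect_lte(mean(acc), 0.4)

  expect_error(gen_embeddings(k = 40, per_cluster = 2, d = 3, separation = 5,
                              min_angle = 80, max_tries = 20), "could not place")
  expect_error(gen_embeddings(k = 2, per_cluster = 2, d = 8, separation = -1),
               "non-negative")
})

test_that("invalid synthetic specifications are rejected", {
  expect_error(synthetic_spec(factor_cor = matrix(c(1, 0.9, 0.2, 1), 2)),
               "symmetric")
  bad <- matrix(c(1, 0.99, -0.99, 0.99, 1, 0.99, -0.99, 0.99, 1), 3)
  expect_error(synthetic_spec(
    factors = tibble::tibble(label = c("a", "b", "c"), n_items = 3L,
                             loadings = list(rep(.5, 3), rep(.5, 3), rep(.5, 3))),
    factor_cor = bad), "positive semi-definite")
  expect_error(synthetic_spec(thresholds = c(0, 0, 1)), "strictly increasing")
  expect_error(synthetic_spec(reverse_fraction = 1.2), "reverse_fraction")
})
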