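#' Specification for a synthetic multi-factor Likert data set
#'
#' Describes the generating model for [gen_responses()]: correlated
#' standard-normal factors, per-item loadings, normal-quantile cutpoints that
#' discretize the latent item scores to Likert categories, and a fraction of
#' reverse-keyed items. The default emulates a five-factor, 50-item,
#' five-point personality inventory: 5 factors of 10 items, loadings spread
#' over 0.45-0.75, factor intercorrelations 0.2, cutpoints at normal quantiles
#' \{0.1, 0.3, 0.7, 0.9\}, and 5,000 respondents — large enough for stable
#' reliability estimates while staying desk-scale.
#'
#' @param n_respondents Number of respondents.
#' @param factors Tibble with columns `label`, `n_items`, and list column
#'   `loadings` (per-item loadings in (0,1)); default 5 x 10 with loadings
#'   evenly spread over `loading_range`.
#' @param factor_cor Either a full correlation matrix (symmetric PSD, unit
#'   diagonal) or a single off-diagonal value.
#' @param thresholds Strictly increasing cutpoints on the latent item scale.
#' @param reverse_fraction Fraction of items stored reverse-keyed (their
#'   stored responses are flipped, so preprocessing has real work to do).
#' @param loading_range Range used for the default loadings.
#' @param seed Integer seed.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_respondents = 5000L,
                           factors = NULL,
                           factor_cor = 0.2,
                           thresholds = qnorm(c(0.1, 0.3, 0.7, 0.9)),
                           reverse_fraction = 0.2,
                           loading_range = c(0.45, 0.75),
                           seed = 1L) {
  if (is.null(factors)) {
    labels <- c("EXT", "EST", "AGR", "CSN", "OPN")
    factors <- tibble(
      label = labels, n_items = 10L,
      loadings = lapply(labels, function(l)
        seq(loading_range[2], loading_range[1], length.out = 10))
    )
  }
  n_f <- nrow(factors)
  if (length(factor_cor) == 1) {
    R <- matrix(factor_cor, n_f, n_f); diag(R) <- 1
  } else {
    R <- as.matrix(factor_cor)
  }
  if (!isSymmetric(R) || any(diag(R) != 1)) {
    abort("factor correlation matrix must be symmetric with unit diagonal")
  }
  if (any(eigen(R, symmetric = TRUE, only.values = TRUE)$values < -1e-10)) {
    abort("factor correlation matrix must be positive semi-definite")
  }
  if (any(diff(thresholds) <= 0)) abort("thresholds must be strictly increasing")
  if (reverse_fraction < 0 || reverse_fraction > 1) {
    abort("reverse_fraction must lie in [0, 1]")
  }
  for (lam in factors$loadings) {
    if (any(lam <= 0 | lam >= 1)) abort("loadings must lie in (0, 1)")
  }
  structure(list(n_respondents = as.integer(n_respondents), factors = factors,
                 factor_cor = R, thresholds = thresholds,
                 reverse_fraction = reverse_fraction, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic Likert response matrix with known structure
#'
#' Latent factors are drawn multivariate normal with the spec's correlation
#' matrix; each item's latent score is
#' \eqn{y_{ij} = \lambda_j f_i + \sqrt{1-\lambda_j^2}\,\varepsilon_{ij}} with
#' standard-normal noise, discretized to `1 + #(cutpoints below y)`.
#' Reverse-keyed items are *stored* flipped (`(min+max) - x`), mirroring how a
#' raw data export of a real inventory looks before direct scoring.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `bank` (an [item_bank]; reverse items carry
#'   `reworded_text`), `responses` (a `likert_tbl`), `truth` (tibble of
#'   per-item factor assignment, loading, reverse flag), and `latent` (the
#'   continuous item scores before discretization and reversal, for
#'   calibration checks).
#' @export
gen_responses <- function(spec = synthetic_spec()) {
  n <- spec$n_respondents
  n_f <- nrow(spec$factors)
  K <- length(spec$thresholds) + 1L
  withr_seed(spec$seed, {
    Lc <- chol(spec$factor_cor)
    F_mat <- matrix(rnorm(n * n_f), n, n_f) %*% Lc
    items <- list(); cols <- list(); latent <- list()
    for (fi in seq_len(n_f)) {
      lab <- spec$factors$label[fi]
      lam <- spec$factors$loadings[[fi]]
      n_items <- spec$factors$n_items[fi]
      n_rev <- floor(spec$reverse_fraction * n_items)
      rev_idx <- if (n_rev > 0) sample.int(n_items, n_rev) else integer(0)
      for (j in seq_len(n_items)) {
        y <- lam[j] * F_mat[, fi] + sqrt(1 - lam[j]^2) * rnorm(n)
        x <- 1L + rowSums(outer(y, spec$thresholds, `>`))
        reverse <- j %in% rev_idx
        if (reverse) x <- (1L + K) - x
        id <- sprintf("%s%d", lab, j)
        items[[id]] <- tibble(
          item_id = id,
          text = sprintf("%s statement %d (%s)", lab, j,
                         if (reverse) "reversed wording" else "direct wording"),
          subscale = lab, reverse = reverse,
          reworded_text = if (reverse) sprintf("%s statement %d (direct rewording)", lab, j) else NA_character_,
          loading = lam[j]
        )
        cols[[id]] <- x
        latent[[id]] <- y
      }
    }
    meta <- dplyr::bind_rows(items)
    bank <- item_bank(meta[c("item_id", "text", "subscale", "reverse", "reworded_text")])
    responses <- likert_responses(tibble::as_tibble(cols), bank,
                                  scale_min = 1L, scale_max = K)
    truth <- tibble(item_id = meta$item_id, factor = meta$subscale,
                    loading = meta$loading, reverse = meta$reverse)
    list(bank = bank, responses = responses, truth = truth,
         latent = do.call(cbind, latent))
  })
}

#' Generate synthetic item embeddings with known cluster structure
#'
#' Cluster centers are drawn on the unit sphere, redrawn until every pairwise
#' angle exceeds `min_angle`; item vectors are the center plus isotropic
#' Gaussian noise with expected norm `1/separation`, re-normalized to the
#' sphere. Since centers at `min_angle` of 60 degrees are at least unit
#' distance apart, `separation` is (a lower bound on) the between- to
#' within-cluster distance ratio. With `separation = 0` the vectors are pure
#' noise and the labels carry no geometric signal.
#'
#' @param k Number of clusters.
#' @param per_cluster Items per cluster.
#' @param d Embedding dimensionality.
#' @param separation Center-to-noise ratio; larger = tighter clusters.
#' @param seed Integer seed.
#' @param min_angle Minimum pairwise center angle in degrees (default 60).
#' @param max_tries Rejection-sampling budget for the centers.
#' @return List with `embeddings` (an [embedding_matrix], unit rows) and
#'   `labels` (integer vector `0..k-1`).
#' @export
gen_embeddings <- function(k, per_cluster, d, separation = 5, seed = 1L,
                           min_angle = 60, max_tries = 1000L) {
  if (separation < 0) abort("separation must be non-negative")
  if (d < 2) abort("embeddings need at least 2 dimensions")
  withr_seed(seed, {
    cos_max <- cos(min_angle * pi / 180)
    centers <- NULL
    for (try in seq_len(max_tries)) {
      C <- matrix(rnorm(k * d), k, d)
      C <- C / sqrt(rowSums(C^2))
      G <- C %*% t(C)
      if (k == 1 || max(G[upper.tri(G)]) < cos_max) { centers <- C; break }
    }
    if (is.null(centers)) {
      abort(sprintf("could not place %d centers at pairwise angle >= %g deg in %d tries",
                    k, min_angle, max_tries))
    }
    labels <- rep(seq_len(k) - 1L, each = per_cluster)
    # per-coordinate scale so the noise vector's expected norm is 1/separation
    noise_scale <- if (separation > 0) 1 / (separation * sqrt(d)) else Inf
    V <- t(vapply(seq_along(labels), function(i) {
      eps <- rnorm(d)
      v <- if (is.finite(noise_scale)) {
        centers[labels[i] + 1L, ] + noise_scale * eps
      } else {
        eps
      }
      v / sqrt(sum(v^2))
    }, numeric(d)))
    ids <- sprintf("it%02d", seq_along(labels))
    list(embeddings = embedding_matrix(V, ids, "raw"), labels = setNames(labels, ids))
  })
}
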