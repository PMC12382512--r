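#' Reduce embedding dimensionality before clustering
#'
#' High-dimensional sentence embeddings are projected to a small number of
#' components before K-means. The default reducer is principal components
#' (centered, unscaled), which is deterministic for a given input and keeps
#' the directions of largest variance — for item banks whose items form a few
#' semantic groups those directions carry the between-group structure.
#' `method = "none"` passes the input through unchanged (requires `r` equal to
#' the input dimensionality) and exists so every downstream step can be tested
#' in a fully hand-checkable space.
#'
#' @param E An [embedding_matrix].
#' @param r Target dimensionality; must satisfy `r < ncol(E)` (except for
#'   `"none"`) and `nrow(E) >= r + 2`.
#' @param method `"pca"` or `"none"`.
#' @param seed Integer seed, accepted for interface stability with stochastic
#'   reducers; the bundled methods are deterministic.
#' @return An [embedding_matrix] with `space_tag = "reduced"` (the `"none"`
#'   method returns its input unchanged).
#' @export
reduce_dim <- function(E, r = 5L, method = c("pca", "none"), seed = 1L) {
  method <- match.arg(method)
  d <- ncol(E)
  if (method == "none") {
    if (r != d) abort("method 'none' requires r equal to the input dimensionality")
    return(E)
  }
  if (r >= d) abort(sprintf("target dimension r = %d must be below input dimension d = %d", r, d))
  if (nrow(E) < r + 2) abort("too few items for the requested dimensionality")
  X <- unclass(E)
  pc <- prcomp(X, center = TRUE, scale. = FALSE, rank. = r)
  scores <- pc$x[, seq_len(r), drop = FALSE]
  # fix component signs (largest-magnitude loading positive) so results are
  # reproducible across BLAS builds
  for (j in seq_len(r)) {
    v <- pc$rotation[, j]
    if (v[which.max(abs(v))] < 0) scores[, j] <- -scores[, j]
  }
  embedding_matrix(scores, rownames(E), "reduced")
}
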