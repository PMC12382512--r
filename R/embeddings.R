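#' Construct an embedding matrix
#'
#' One real-valued vector per item, aligned to an item bank. Embeddings carry
#' a `space_tag` distinguishing raw model output from a reduced
#' (low-dimensional) view.
#'
#' @param x Numeric matrix, rows in item order.
#' @param item_ids Character vector of item ids, one per row.
#' @param space_tag `"raw"` or `"reduced"`.
#' @return A numeric matrix of class `embedding_matrix` with row names set to
#'   the item ids.
#' @export
embedding_matrix <- function(x, item_ids = rownames(x), space_tag = "raw") {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(item_ids)) abort("embedding matrix needs item ids")
  if (length(item_ids) != nrow(x)) {
    abort("one item id per embedding row required")
  }
  if (ncol(x) < 2) abort("embeddings need at least 2 dimensions")
  if (!all(is.finite(x))) abort("embedding matrix contains non-finite entries")
  if (!space_tag %in% c("raw", "reduced")) {
    abort("space_tag must be 'raw' or 'reduced'")
  }
  rownames(x) <- as.character(item_ids)
  attr(x, "space_tag") <- space_tag
  class(x) <- c("embedding_matrix", class(x))
  x
}

#' @rdname embedding_matrix
#' @export
space_tag <- function(x) attr(x, "space_tag") %||% "raw"

#' Read an item embedding matrix from TSV
#'
#' Tab-separated, first column `item_id`, remaining columns numeric vector
#' components. Rows are reordered to bank order; every bank item must be
#' present.
#'
#' @param path Path to a TSV file.
#' @param bank The [item_bank] the rows refer to.
#' @return An [embedding_matrix] with `space_tag = "raw"`.
#' @export
read_embeddings <- function(path, bank) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    item_id = readr::col_character(), .default = readr::col_character()
  ), progress = FALSE)
  if (!"item_id" %in% names(df)) abort("embedding TSV needs an item_id column")
  absent <- setdiff(bank$item_id, df$item_id)
  if (length(absent) > 0) {
    abort(paste0("embedding file is missing item(s): ",
                 paste(absent, collapse = ", ")))
  }
  df <- df[match(bank$item_id, df$item_id), ]
  vals <- df[setdiff(names(df), "item_id")]
  num <- suppressWarnings(vapply(vals, as.numeric, numeric(nrow(df))))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    abort(sprintf("non-numeric embedding value at item '%s', dimension %d",
                  df$item_id[bad[1]], bad[2]))
  }
  embedding_matrix(matrix(num, nrow = nrow(df)), df$item_id, "raw")
}

#' Write an embedding matrix to TSV
#'
#' @param E An [embedding_matrix].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(E, path) {
  df <- as.data.frame(unclass(E))
  names(df) <- paste0("d", seq_len(ncol(df)))
  df <- cbind(item_id = rownames(E), df)
  readr::write_tsv(as_tibble(df), path, progress = FALSE)
  invisible(path)
}

#' Embed item texts through a pluggable backend
#'
#' Produces one semantic vector per item, in bank order. Reverse-keyed items
#' are embedded through their positively worded `reworded_text`. Three
#' backends are provided:
#'
#' * `"file"` — load precomputed vectors from a TSV (see [read_embeddings()]);
#'   this is how output of any external sentence-embedding model (e.g. a
#'   sentence-T5 checkpoint) enters the pipeline.
#' * `"synthetic"` — deterministic pseudo-embeddings: each subscale gets a
#'   direction on the unit sphere and each item's vector is a text-hash-seeded
#'   perturbation of its subscale direction. Useful for tests and examples.
#' * `"model"` — reserved for an in-session sentence-embedding model; not
#'   bundled, so this backend errors with a pointer to the file backend.
#'
#' @param bank An [item_bank].
#' @param backend One of `"file"`, `"synthetic"`, `"model"`.
#' @param path TSV path for the file backend.
#' @param dims Dimensionality for the synthetic backend.
#' @param noise Perturbation scale for the synthetic backend (smaller = tighter
#'   subscale clusters).
#' @param seed Integer seed for the synthetic backend's subscale directions.
#' @param model_id Identifier of the external model (file/model backends;
#'   recorded only).
#' @param normalize If `TRUE` (default), rows are scaled to unit L2 norm so
#'   cosine and Euclidean geometry agree up to a monotone transform.
#' @return An [embedding_matrix], `space_tag = "raw"`.
#' @export
embed_items <- function(bank, backend = c("file", "synthetic", "model"),
                        path = NULL, dims = 64L, noise = 0.2, seed = 1L,
                        model_id = NULL, normalize = TRUE) {
  backend <- match.arg(backend)
  texts <- embedding_texts(bank)
  E <- switch(backend,
    file = {
      if (is.null(path)) abort("file backend needs `path`")
      read_embeddings(path, bank)
    },
    synthetic = synthetic_text_embeddings(bank, texts, dims, noise, seed),
    model = abort(paste0(
      "no sentence-embedding model is bundled with this package; ",
      "compute embeddings externally (e.g. with a sentence-T5 model) and ",
      "load them with backend = 'file'"))
  )
  if (normalize) E <- l2_normalize(E)
  E
}

synthetic_text_embeddings <- function(bank, texts, dims, noise, seed) {
  labels <- sort(unique(bank$subscale))
  centers <- withr_seed(seed, {
    C <- matrix(rnorm(length(labels) * dims), nrow = length(labels))
    C / sqrt(rowSums(C^2))
  })
  rownames(centers) <- labels
  vecs <- t(vapply(seq_len(nrow(bank)), function(i) {
    h <- text_hash(paste(bank$subscale[i], texts[i], sep = "\r"))
    delta <- withr_seed((h + seed) %% .Machine$integer.max, rnorm(dims))
    centers[bank$subscale[i], ] + noise * delta
  }, numeric(dims)))
  embedding_matrix(vecs, bank$item_id, "raw")
}

# small deterministic string hash (polynomial rolling hash mod 2^31 - 1)
text_hash <- function(s) {
  v <- utf8ToInt(enc2utf8(s))
  h <- 0
  for (x in v) h <- (h * 31 + x) %% 2147483647
  as.integer(h)
}

l2_normalize <- function(E) {
  nrm <- sqrt(rowSums(unclass(E)^2))
  if (any(nrm == 0)) abort("cannot normalize a zero-norm embedding vector")
  embedding_matrix(unclass(E) / nrm, rownames(E), space_tag(E))
}

# evaluate `code` under a local RNG seed without disturbing the caller's RNG
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647))
  code
}
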