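#' Align semantic clusters with factor labels (Hungarian algorithm)
#'
#' Builds the cluster-by-factor confusion matrix and finds the one-to-one
#' cluster-to-factor mapping that maximizes the total matched count, via the
#' Hungarian (optimal assignment) algorithm. Accuracy is the matched count
#' divided by the total number of items.
#'
#' @param cluster_labels Vector of cluster assignments (any atomic type).
#' @param factor_labels Vector of true factor/subscale labels, same length.
#' @return An `alignment_result`: list with `confusion` (clusters in rows,
#'   factors in columns), `mapping` (named character vector, cluster ->
#'   factor), and `accuracy` in `[0, 1]`.
#' @examples
#' hungarian_align(c(0, 0, 1, 1), c("A", "A", "B", "B"))
#' @export
hungarian_align <- function(cluster_labels, factor_labels) {
  if (length(cluster_labels) == 0 || length(factor_labels) == 0) {
    abort("empty label vectors")
  }
  if (length(cluster_labels) != length(factor_labels)) {
    abort("cluster and factor labels must have the same length")
  }
  confusion <- table(cluster = as.character(cluster_labels),
                     factor = as.character(factor_labels))
  confusion <- matrix(as.numeric(confusion), nrow = nrow(confusion),
                      dimnames = dimnames(confusion))
  align_confusion(confusion)
}

#' @describeIn hungarian_align Align directly from a cluster-by-factor count
#'   matrix (rows clusters, columns factors). Non-square matrices are padded
#'   with zero-count dummy rows or columns before assignment.
#' @param confusion A non-negative count matrix, clusters in rows and factors
#'   in columns.
#' @export
align_confusion <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (any(confusion < 0)) abort("confusion matrix must be non-negative")
  if (sum(confusion) == 0) abort("confusion matrix has no counts")
  padded <- pad_square(confusion)
  assignment <- clue::solve_LSAP(padded, maximum = TRUE)
  rows <- rownames(padded); cols <- colnames(padded)
  mapping <- setNames(cols[as.integer(assignment)], rows)
  mapping <- mapping[seq_len(nrow(confusion))]
  matched <- sum(padded[cbind(seq_along(assignment), as.integer(assignment))])
  structure(list(confusion = confusion, mapping = mapping,
                 accuracy = matched / sum(confusion)),
            class = "alignment_result")
}

pad_square <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  if (nr == nc) return(m)
  if (nr < nc) {
    pad <- matrix(0, nc - nr, nc)
    rownames(pad) <- paste0(".dummy", seq_len(nc - nr))
    rbind(m, pad)
  } else {
    pad <- matrix(0, nr, nr - nc)
    colnames(pad) <- paste0(".dummy", seq_len(nr - nc))
    cbind(m, pad)
  }
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result: accuracy %.3f>\n", x$accuracy))
  cat("mapping:\n")
  print(x$mapping)
  invisible(x)
}

#' @method tidy alignment_result
#' @export
tidy.alignment_result <- function(x, ...) {
  tibble(cluster = names(x$mapping), factor = unname(x$mapping),
         matched = vapply(names(x$mapping), function(cl) {
           f <- x$mapping[[cl]]
           if (f %in% colnames(x$confusion)) x$confusion[cl, f] else 0
         }, numeric(1)),
         total = rowSums(x$confusion)[names(x$mapping)])
}

#' @method glance alignment_result
#' @export
glance.alignment_result <- function(x, ...) {
  tibble(accuracy = x$accuracy, n_items = sum(x$confusion),
         k = nrow(x$confusion))
}
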