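#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_point geom_line
#'   geom_text facet_wrap labs scale_fill_gradient2 theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Heatmaps of the structural correlation matrices
#'
#' @param object A `correlation_matrices` object.
#' @param ... Unused.
#' @return A ggplot: original-by-original and original-by-short factor
#'   correlations side by side.
#' @method autoplot correlation_matrices
#' @export
autoplot.correlation_matrices <- function(object, ...) {
  melt <- function(m, panel) {
    tibble(row = rep(rownames(m), times = ncol(m)),
           col = rep(colnames(m), each = nrow(m)),
           r = as.numeric(m), panel = panel)
  }
  df <- dplyr::bind_rows(melt(object$original, "original x original"),
                         melt(object$original_by_short, "original x short"))
  ggplot(df, aes(x = .data$col, y = .data$row, fill = .data$r)) +
    geom_tile() +
    geom_text(aes(label = sprintf("%.2f", .data$r)), size = 3) +
    scale_fill_gradient2(limits = c(-1, 1), low = "#2166ac", mid = "white",
                         high = "#b2182b") +
    facet_wrap(~panel) +
    labs(x = NULL, y = NULL, fill = "r") +
    theme_minimal()
}

#' Reduced-space view of a semantic reduction
#'
#' First two reduced dimensions, points colored by cluster, selected items
#' emphasized.
#'
#' @param object A `te_reduction`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot te_reduction
#' @export
autoplot.te_reduction <- function(object, ...) {
  M <- unclass(object$reduced)
  df <- tibble(item_id = rownames(M), x = M[, 1], y = M[, 2],
               cluster = factor(object$solution$labels[rownames(M)]),
               selected = rownames(M) %in% object$short_form$item_id)
  ggplot(df, aes(x = .data$x, y = .data$y, color = .data$cluster)) +
    geom_point(aes(shape = .data$selected, size = .data$selected)) +
    ggplot2::scale_size_manual(values = c(`FALSE` = 1.5, `TRUE` = 3)) +
    labs(x = "component 1", y = "component 2",
         title = "Item embeddings (reduced space)") +
    theme_minimal()
}

#' Best-fitness trajectory of a genetic-algorithm run
#'
#' @param object A `ga_result`.
#' @param ... Unused.
#' @return A ggplot of best fitness per generation, one line per factor.
#' @method autoplot ga_result
#' @export
autoplot.ga_result <- function(object, ...) {
  ggplot(object$history,
         aes(x = .data$generation, y = .data$best_fitness,
             color = .data$factor)) +
    geom_line() +
    labs(x = "generation", y = "best fitness") +
    theme_minimal()
}

#' Item information curves of a graded-response fit
#'
#' @param object A `grm_fit`.
#' @param theta Grid of trait values to plot over.
#' @param ... Unused.
#' @return A ggplot of Fisher information per item across the trait range.
#' @method autoplot grm_fit
#' @export
autoplot.grm_fit <- function(object, theta = seq(-4, 4, by = 0.1), ...) {
  keep <- which(!object$params$degenerate)
  df <- dplyr::bind_rows(lapply(keep, function(j) {
    tibble(item_id = object$params$item_id[j], theta = theta,
           information = grm_item_information(object$params$a[j],
                                              object$params$b[[j]], theta))
  }))
  ggplot(df, aes(x = .data$theta, y = .data$information,
                 color = .data$item_id)) +
    geom_line() +
    labs(x = expression(theta), y = "item information") +
    theme_minimal()
}
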