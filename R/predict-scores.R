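#' Predict full-scale subscale scores from short-form responses
#'
#' Trains a three-layer feed-forward regressor (input -> 64 -> 32 -> output,
#' ReLU, Adam, mean-squared-error loss) to predict the full-scale per-factor
#' sum scores from the short form's item responses, and reports held-out
#' error metrics. A deterministic linear-regression baseline fitted on the
#' same split is always reported alongside, so the network's contribution is
#' never read off in isolation.
#'
#' Inputs and targets are standardized internally for training; predictions
#' are mapped back to the raw score scale before any metric is computed.
#' Metrics are pooled over all target columns on the held-out split.
#'
#' @inheritParams convergent_correlations
#' @param targets `"subscales"` (default): the per-factor full-scale sum
#'   scores are predicted jointly. `"items"`: every original item response is
#'   predicted instead.
#' @param hidden Sizes of the two hidden layers.
#' @param lr,epochs,batch_size Adam learning rate, training epochs, minibatch
#'   size.
#' @param train_fraction Fraction of respondents in the training split
#'   (default 0.8).
#' @param seed Integer seed for the split, shuffling and weight
#'   initialization.
#' @return A list of class `prediction_result`: `metrics` (tibble, one row per
#'   model: `network` and `linear`), `n_train`, `n_test`.
#' @export
predict_original_scores <- function(data, short, bank,
                                    targets = c("subscales", "items"),
                                    hidden = c(64L, 32L), lr = 1e-3,
                                    epochs = 20L, batch_size = 256L,
                                    train_fraction = 0.8, seed = 1L) {
  targets <- match.arg(targets)
  ids <- short_form_ids(short)
  X <- response_matrix(data)[, ids, drop = FALSE]
  Y <- if (targets == "subscales") {
    fs <- factor_scores(data, bank)
    fs[, setdiff(colnames(fs), "total"), drop = FALSE]
  } else {
    response_matrix(data)
  }
  n <- nrow(X)
  if (n < 10) abort("too few respondents to split for prediction")
  idx_train <- withr_seed(seed, sample.int(n, size = floor(train_fraction * n)))
  idx_test <- setdiff(seq_len(n), idx_train)

  mu_x <- colMeans(X[idx_train, , drop = FALSE])
  sd_x <- pmax(apply(X[idx_train, , drop = FALSE], 2, sd), 1e-8)
  mu_y <- colMeans(Y[idx_train, , drop = FALSE])
  sd_y <- pmax(apply(Y[idx_train, , drop = FALSE], 2, sd), 1e-8)
  Xs <- sweep(sweep(X, 2, mu_x), 2, sd_x, `/`)
  Ys <- sweep(sweep(Y, 2, mu_y), 2, sd_y, `/`)

  net <- mlp_train(Xs[idx_train, , drop = FALSE], Ys[idx_train, , drop = FALSE],
                   hidden = hidden, lr = lr, epochs = epochs,
                   batch_size = batch_size, seed = seed)
  pred_net <- sweep(sweep(mlp_predict(net, Xs[idx_test, , drop = FALSE]),
                          2, sd_y, `*`), 2, mu_y, `+`)

  # linear baseline: ordinary least squares per target on the same split
  Xtr <- cbind(1, X[idx_train, , drop = FALSE])
  Xte <- cbind(1, X[idx_test, , drop = FALSE])
  B <- qr.coef(qr(Xtr), Y[idx_train, , drop = FALSE])
  B[is.na(B)] <- 0
  pred_lin <- Xte %*% B

  y_test <- as.numeric(Y[idx_test, , drop = FALSE])
  metrics <- dplyr::bind_rows(
    dplyr::mutate(regression_metrics(y_test, as.numeric(pred_net)),
                  model = "network", .before = 1),
    dplyr::mutate(regression_metrics(y_test, as.numeric(pred_lin)),
                  model = "linear", .before = 1)
  )
  structure(list(metrics = metrics, n_train = length(idx_train),
                 n_test = length(idx_test), targets = targets),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("<prediction_result: %s targets, %d train / %d test>\n",
              x$targets, x$n_train, x$n_test))
  print(x$metrics)
  invisible(x)
}

#' @method tidy prediction_result
#' @export
tidy.prediction_result <- function(x, ...) x$metrics
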