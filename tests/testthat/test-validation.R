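test_that("Cronbach's alpha matches its closed forms", {
  # two perfectly correlated equal-variance items
  x <- cbind(a = c(1, 2, 3, 4, 5), b = c(1, 2, 3, 4, 5))
  expect_equal(cronbach_alpha(x), 1)

  # two uncorrelated equal-variance items (constructed orthogonal)
  y <- cbind(a = c(1, 1, -1, -1), b = c(1, -1, 1, -1))
  expect_equal(cronbach_alpha(y), 0)

  # compound symmetry: k items, common correlation r -> kr / (1 + (k-1) r)
  k <- 6; r <- 0.4
  Sigma <- matrix(r, k, k); diag(Sigma) <- 1
  set.seed(2)
  X <- MASS::mvrnorm(200, mu = rep(0, k), Sigma = Sigma, empirical = TRUE)
  expect_equal(cronbach_alpha(X), k * r / (1 + (k - 1) * r), tolerance = 1e-10)
  expect_equal(k * r / (1 + (k - 1) * r), 0.8)

  expect_error(cronbach_alpha(matrix(1, 5, 3)), "zero total-score variance")
  expect_error(cronbach_alpha(matrix(1:10, 10, 1)), "2 items")
})

test_that("alpha follows the compound-symmetry closed form across k and r", {
  set.seed(31)
  for (k in c(3, 5, 8)) {
    for (r in c(0.2, 0.5, 0.7)) {
      Sigma <- matrix(r, k, k); diag(Sigma) <- 1
      X <- MASS::mvrnorm(150, rep(0, k), Sigma, empirical = TRUE)
      expect_equal(cronbach_alpha(X), k * r / (1 + (k - 1) * r),
                   tolerance = 1e-10)
    }
  }
})

test_that("convergent correlations equal an independent correlation oracle", {
  gen <- gen_responses(synthetic_spec(n_respondents = 800, seed = 4))
  resp <- apply_reverse_scoring(gen$responses, gen$bank)
  sel <- ctt_select(resp, gen$bank, m = 6)$short_form
  conv <- convergent_correlations(resp, sel, gen$bank)
  X <- response_matrix(resp)
  hand_r <- sapply(sort(unique(gen$bank$subscale)), function(f) {
    full_ids <- gen$bank$item_id[gen$bank$subscale == f]
    short_ids <- intersect(sel$item_id, full_ids)
    u <- rowSums(X[, short_ids]); v <- rowSums(X[, full_ids])
    sum((u - mean(u)) * (v - mean(v))) /
      sqrt(sum((u - mean(u))^2) * sum((v - mean(v))^2))
  })
  expect_equal(conv$r, unname(hand_r), tolerance = 1e-12)
  expect_equal(attr(conv, "mean_r"), mean(hand_r), tolerance = 1e-12)

  # short form = full form: every correlation is 1
  conv_full <- convergent_correlations(resp, gen$bank$item_id, gen$bank)
  expect_equal(conv_full$r, rep(1, 5))
  expect_equal(attr(conv_full, "total_r"), 1)
})

test_that("structural correlation matrices behave as contracts require", {
  gen <- gen_responses(synthetic_spec(n_respondents = 5000, seed = 8))
  resp <- apply_reverse_scoring(gen$responses, gen$bank)
  sel <- ctt_select(resp, gen$bank, m = 6)$short_form

  cm_full <- correlation_matrices(resp, gen$bank$item_id, gen$bank)
  expect_equal(cm_full$original, cm_full$original_by_short)
  expect_equal(cm_full$original, t(cm_full$original))

  cm <- correlation_matrices(resp, sel, gen$bank)
  conv <- convergent_correlations(resp, sel, gen$bank)
  expect_equal(unname(diag(cm$original_by_short)), conv$r, tolerance = 1e-12)
  # the short form preserves the between-factor correlation pattern
  off <- upper.tri(cm$original)
  expect_lt(max(abs(cm$original[off] - cm$original_by_short[off])), 0.1)

  perm <- sample(nrow(resp))
  respp <- likert_responses(as.data.frame(resp)[perm, ], gen$bank)
  cmp <- correlation_matrices(respp, sel, gen$bank)
  expect_equal(cmp$original, cm$original, tolerance = 1e-12)
})

test_that("regression metrics match hand-evaluated formulas and identities", {
  perfect <- regression_metrics(c(3, 7, 9), c(3, 7, 9))
  expect_equal(perfect$MAE, 0); expect_equal(perfect$RMSE, 0)
  expect_equal(perfect$R2, 1); expect_equal(perfect$MAPE, 0)

  hand <- regression_metrics(c(10, 20), c(12, 18))
  expect_equal(hand$MAE, 2)
  expect_equal(hand$RMSE, 2)
  expect_equal(hand$MAPE, 15)
  expect_equal(hand$R2, 0.84)

  y <- c(2, 4, 9, 1)
  expect_equal(regression_metrics(y, rep(mean(y), 4))$R2, 0)

  expect_warning(m0 <- regression_metrics(c(0, 10), c(1, 9)), "excluded from MAPE")
  expect_equal(m0$MAPE, 10)

  # RMSE >= MAE on arbitrary data (Jensen)
  set.seed(6)
  for (i in 1:20) {
    y <- rnorm(30); yh <- rnorm(30)
    m <- regression_metrics(y, yh)
    expect_gte(m$RMSE, m$MAE)
  }
})

test_that("score prediction reports both network and linear baseline on held-out data", {
  gen <- gen_responses(synthetic_spec(n_respondents = 2000, seed = 10))
  resp <- apply_reverse_scoring(gen$responses, gen$bank)
  sel <- ctt_select(resp, gen$bank, m = 6)$short_form
  pred <- predict_original_scores(resp, sel, gen$bank, epochs = 10L, seed = 1)
  expect_equal(pred$metrics$model, c("network", "linear"))
  expect_equal(pred$n_train + pred$n_test, nrow(resp))
  expect_true(all(pred$metrics$MAE >= 0))
  expect_true(all(pred$metrics$RMSE >= pred$metrics$MAE))
  expect_true(all(pred$metrics$R2 <= 1))
  # the targets carry strong linear signal: the baseline must be close to (or
  # better than) the trained network
  lin <- pred$metrics$R2[pred$metrics$model == "linear"]
  net <- pred$metrics$R2[pred$metrics$model == "network"]
  expect_gte(lin, net - 0.05)
  expect_gt(net, 0.5)

  # determinism under a fixed seed
  pred2 <- predict_original_scores(resp, sel, gen$bank, epochs = 10L, seed = 1)
  expect_equal(pred$metrics, pred2$metrics, tolerance = 1e-12)
})

test_that("validation reports assemble and round-trip through JSON", {
  gen <- gen_responses(synthetic_spec(n_respondents = 600, seed = 14))
  resp <- apply_reverse_scoring(gen$responses, gen$bank)
  te_emb <- embed_items(gen$bank, backend = "synthetic", dims = 24, noise = 0.1)
  te <- run_te_reduction(gen$bank, te_emb, r = 5, seed = 2)
  rep <- validation_report(resp, te$short_form, gen$bank,
                           alignment = te$alignment,
                           silhouettes = te$silhouettes)
  expect_true(rep$alpha$mean <= 1)
  expect_true(rep$convergent$mean <= 1 && rep$convergent$mean >= -1)
  expect_gte(rep$alignment$accuracy, 0)

  path <- withr::local_tempfile(fileext = ".json")
  write_validation_report(rep, path)
  back <- read_validation_report(path)
  expect_equal(back$alpha$mean, rep$alpha$mean)
  expect_equal(back$alpha$per_factor$alpha, rep$alpha$per_factor$alpha)
  expect_equal(back$convergent$per_factor$r, rep$convergent$per_factor$r)
  expect_equal(back$alignment$accuracy, rep$alignment$accuracy)
  expect_equal(unname(back$alignment$mapping), unname(rep$alignment$mapping))
  expect_equal(back$alignment$confusion, rep$alignment$confusion,
               ignore_attr = TRUE)
})

test_that("correlation matrices export to CSV and read back", {
  gen <- gen_responses(synthetic_spec(n_respondents = 300, seed = 20))
  resp <- apply_reverse_scoring(gen$responses, gen$bank)
  cm <- correlation_matrices(resp, gen$bank$item_id[seq(1, 50, by = 2)], gen$bank)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_correlation_matrices(cm, p1, p2)
  back <- readr::read_csv(p1, show_col_types = FALSE)
  expect_equal(as.matrix(back[-1]), cm$original, ignore_attr = TRUE)
})
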