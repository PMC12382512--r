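# shared fixtures and independent oracles, all built in code

make_bank <- function(n_per = c(A = 4, B = 4), reverse = character()) {
  reverse_ids <- reverse
  rows <- lapply(names(n_per), function(lab) {
    ids <- paste0(lab, seq_len(n_per[[lab]]))
    tibble::tibble(
      item_id = ids,
      text = paste("I do thing", ids),
      subscale = lab,
      reverse = ids %in% reverse_ids,
      reworded_text = ifelse(ids %in% reverse_ids,
                             paste("I do not avoid thing", ids),
                             NA_character_)
    )
  })
  item_bank(dplyr::bind_rows(rows))
}

make_responses <- function(bank, n = 20, seed = 1) {
  set.seed(seed)
  df <- as.data.frame(matrix(sample(1:5, n * nrow(bank), replace = TRUE),
                             nrow = n, dimnames = list(NULL, bank$item_id)))
  likert_responses(df, bank)
}

# a small one-factor data set plus GRM fits, shared across GA tests
ga_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      bank <- make_bank(c(S = 8))
      set.seed(99)
      lam <- c(0.85, 0.8, 0.75, 0.7, 0.6, 0.5, 0.4, 0.3)
      n <- 500
      f <- rnorm(n)
      df <- as.data.frame(1 + sapply(lam, function(l)
        rowSums(outer(l * f + sqrt(1 - l^2) * rnorm(n),
                      qnorm(c(0.1, 0.3, 0.7, 0.9)), `>`))))
      names(df) <- bank$item_id
      resp <- likert_responses(df, bank)
      grm <- fit_grm_by_subscale(resp, bank)
      cache <<- list(bank = bank, resp = resp, grm = grm)
    }
    cache
  }
})

# exhaustive-permutation oracle for the assignment problem (maximization)
brute_force_assignment <- function(m) {
  k <- nrow(m)
  best <- -Inf
  for (perm in all_perms(seq_len(k))) {
    v <- sum(m[cbind(seq_len(k), perm)])
    if (v > best) best <- v
  }
  best
}

all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

# naive double-loop silhouette oracle
naive_silhouette <- function(M, labels, metric = "euclidean") {
  n <- nrow(M)
  dfun <- function(i, j) {
    if (metric == "euclidean") sqrt(sum((M[i, ] - M[j, ])^2))
    else 1 - sum(M[i, ] * M[j, ]) / sqrt(sum(M[i, ]^2) * sum(M[j, ]^2))
  }
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels[i]
    mates <- setdiff(which(labels == own), i)
    if (length(mates) == 0) { s[i] <- 0; next }
    a <- mean(sapply(mates, function(j) dfun(i, j)))
    b <- Inf
    for (g in setdiff(unique(labels), own)) {
      members <- which(labels == g)
      b <- min(b, mean(sapply(members, function(j) dfun(i, j))))
    }
    s[i] <- (b - a) / max(a, b)
  }
  s
}

# simulate graded responses from known parameters
simulate_grm <- function(a, b, n, seed = 1) {
  set.seed(seed)
  theta <- rnorm(n)
  X <- sapply(seq_along(a), function(j) {
    P <- grm_category_probs(a[j], b[[j]], theta)
    apply(P, 1, function(p) sample.int(length(p), 1, prob = p))
  })
  colnames(X) <- paste0("i", seq_along(a))
  X
}
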