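#' Quadrature grid over the latent trait
#'
#' Equally spaced nodes with standard-normal density weights, renormalized to
#' sum to one. This is the numerical stand-in for the N(0,1) prior on the
#' latent trait used to identify the graded response model.
#'
#' @param n_nodes Number of nodes (default 61).
#' @param bounds Range of the grid on the latent scale (default `c(-6, 6)`).
#' @return A list of class `theta_grid` with `nodes` and `weights`.
#' @export
theta_grid <- function(n_nodes = 61L, bounds = c(-6, 6)) {
  nodes <- seq(bounds[1], bounds[2], length.out = n_nodes)
  w <- dnorm(nodes)
  structure(list(nodes = nodes, weights = w / sum(w)), class = "theta_grid")
}

# cumulative response curves P*_k(theta) = P(X >= k+1 | theta), k = 1..K-1
grm_pstar <- function(a, b, theta) {
  stats::plogis(outer(theta, b, function(t, bk) a * (t - bk)))
}

#' Graded-response-model category probabilities
#'
#' Samejima's logistic form: cumulative curves
#' \eqn{P^*_k(\theta) = 1/(1+e^{-a(\theta-b_k)})} with \eqn{P^*_0 = 1},
#' \eqn{P^*_K = 0}, and category probabilities
#' \eqn{P(X = k) = P^*_{k-1} - P^*_k}.
#'
#' @param a Discrimination, `a > 0` (a = 0 gives a flat, uninformative item).
#' @param b Strictly increasing numeric vector of K-1 category thresholds.
#' @param theta Latent trait value(s).
#' @return Matrix `length(theta)` x `K` of category probabilities; each row
#'   sums to 1.
#' @examples
#' grm_category_probs(1.5, c(-1, 0, 1), theta = 0)
#' @export
grm_category_probs <- function(a, b, theta) {
  check_thresholds(b)
  ps <- grm_pstar(a, b, theta)
  K <- length(b) + 1L
  cum <- cbind(1, ps, 0)
  probs <- cum[, 1:K, drop = FALSE] - cum[, 2:(K + 1), drop = FALSE]
  colnames(probs) <- as.character(seq_len(K))
  probs
}

check_thresholds <- function(b) {
  if (length(b) < 1 || any(diff(b) <= 0)) {
    abort("category thresholds must be strictly increasing")
  }
  invisible(b)
}

#' Fisher information of a graded item
#'
#' \eqn{I(\theta) = \sum_k (P_k')^2 / P_k} with \eqn{P_k'} the derivative of
#' the category probability with respect to the latent trait. Always
#' non-negative; zero everywhere when `a = 0`.
#'
#' @inheritParams grm_category_probs
#' @return Numeric vector of information values, one per `theta`.
#' @export
grm_item_information <- function(a, b, theta) {
  check_thresholds(b)
  ps <- grm_pstar(a, b, theta)
  K <- length(b) + 1L
  cum <- cbind(1, ps, 0)
  dcum <- cbind(0, a * ps * (1 - ps), 0)   # d P*_k / d theta (boundaries flat)
  probs <- cum[, 1:K, drop = FALSE] - cum[, 2:(K + 1), drop = FALSE]
  dprobs <- dcum[, 1:K, drop = FALSE] - dcum[, 2:(K + 1), drop = FALSE]
  rowSums(dprobs^2 / pmax(probs, 1e-300))
}

#' Fit a graded response model by marginal maximum likelihood (EM)
#'
#' Estimates per-item discrimination and ordered category thresholds for one
#' subscale under a standard-normal latent trait, integrating the trait out on
#' a fixed quadrature grid. The E-step computes each respondent's posterior
#' over the grid; the M-step maximizes the expected complete-data
#' log-likelihood item by item (BFGS with analytic gradients), with threshold
#' order enforced through a log-gap reparameterization
#' \eqn{b_k = b_1 + \sum_{j<k} e^{g_j}}. The marginal log-likelihood is
#' non-decreasing across iterations.
#'
#' Unobserved categories are collapsed away before fitting (the returned
#' `categories` field records which raw scores each fitted category
#' corresponds to). Items in which everyone chose the same category cannot be
#' scaled; they are flagged degenerate and left unestimated, with a warning.
#'
#' @param data A complete `likert_tbl` (or numeric matrix), typically the
#'   columns of one subscale.
#' @param grid A [theta_grid()].
#' @param max_iter Maximum EM iterations (default 500).
#' @param tol Convergence threshold on the largest absolute parameter change
#'   (default 1e-4).
#' @return A `grm_fit`: list with `params` (tibble: `item_id`, `a`, list
#'   column `b`, `degenerate`), `loglik` (final marginal log-likelihood),
#'   `loglik_history`, `converged`, `iterations`, `categories`, `grid`.
#' @export
fit_grm <- function(data, grid = theta_grid(), max_iter = 500L, tol = 1e-4) {
  X <- if (is.matrix(data)) data else response_matrix(data)
  if (anyNA(X)) abort("fit_grm requires complete responses")
  if (nrow(X) < 2) abort("fit_grm needs at least 2 respondents")
  ids <- colnames(X) %||% paste0("item", seq_len(ncol(X)))
  p <- ncol(X)

  cat_values <- lapply(seq_len(p), function(j) sort(unique(X[, j])))
  degenerate <- vapply(cat_values, length, integer(1)) < 2
  if (any(degenerate)) {
    warn(paste0("degenerate item(s) with a single observed category left unestimated: ",
                paste(ids[degenerate], collapse = ", ")))
  }
  active <- which(!degenerate)
  if (length(active) == 0) abort("no estimable items")
  Xc <- vapply(seq_len(p), function(j) match(X[, j], cat_values[[j]]), integer(nrow(X)))

  nodes <- grid$nodes; logw <- log(grid$weights); Q <- length(nodes)
  a_hat <- rep(1, p)
  b_hat <- lapply(seq_len(p), function(j) {
    K <- length(cat_values[[j]])
    if (K < 2) return(NA_real_)
    cum <- cumsum(tabulate(Xc[, j], nbins = K))[1:(K - 1)] / nrow(X)
    b <- qnorm(pmin(pmax(cum, 1e-3), 1 - 1e-3))
    # enforce strict increase in case of clamping ties
    cummax_fix(b)
  })

  ll_hist <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    # ---- E-step ----
    L <- matrix(rep(logw, each = nrow(X)), nrow = nrow(X))
    logP <- vector("list", p)
    for (j in active) {
      Pj <- grm_category_probs(a_hat[j], b_hat[[j]], nodes)  # Q x K
      logP[[j]] <- log(pmax(Pj, 1e-300))
      L <- L + t(logP[[j]])[Xc[, j], , drop = FALSE]         # n x Q
    }
    mx <- apply(L, 1, max)
    post <- exp(L - mx)
    rs <- rowSums(post)
    ll <- sum(log(rs) + mx)
    post <- post / rs
    ll_hist <- c(ll_hist, ll)

    # ---- M-step (per item) ----
    delta <- 0
    for (j in active) {
      K <- length(cat_values[[j]])
      r_kq <- rowsum(post, group = Xc[, j], reorder = TRUE)  # K x Q expected counts
      if (nrow(r_kq) < K) {    # categories can vanish from a quadrature subset only in theory
        full <- matrix(0, K, Q); full[as.integer(rownames(r_kq)), ] <- r_kq; r_kq <- full
      }
      fit_j <- grm_mstep_item(a_hat[j], b_hat[[j]], r_kq, nodes)
      delta <- max(delta, abs(fit_j$a - a_hat[j]), max(abs(fit_j$b - b_hat[[j]])))
      a_hat[j] <- fit_j$a
      b_hat[[j]] <- fit_j$b
    }
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  if (!converged) {
    warn(sprintf("GRM EM did not reach tol = %g within %d iterations (last change %.2g)",
                 tol, max_iter, delta))
  }
  params <- tibble(item_id = ids,
                   a = ifelse(degenerate, NA_real_, a_hat),
                   b = lapply(seq_len(p), function(j) if (degenerate[j]) NA_real_ else b_hat[[j]]),
                   degenerate = degenerate)
  structure(list(params = params, loglik = ll_hist[length(ll_hist)],
                 loglik_history = ll_hist, converged = converged,
                 iterations = iter, categories = setNames(cat_values, ids),
                 grid = grid, n = nrow(X)),
            class = "grm_fit")
}

cummax_fix <- function(b, gap = 1e-3) {
  for (k in seq_along(b)[-1]) if (b[k] <= b[k - 1]) b[k] <- b[k - 1] + gap
  b
}

# maximize sum_kq r[k,q] log P_k(theta_q) over (a, b) for one item;
# parameterized as (log a, b_1, log gaps) to keep a > 0 and b ordered
grm_mstep_item <- function(a0, b0, r_kq, nodes) {
  K <- nrow(r_kq)
  par0 <- c(log(max(a0, 1e-6)), b0[1],
            if (K > 2) log(pmax(diff(b0), 1e-6)))
  # clamp so exp() can neither overflow nor underflow to a zero gap
  clamp <- function(par) {
    par[1] <- min(max(par[1], -10), 5)
    par[2] <- min(max(par[2], -50), 50)
    if (length(par) > 2) par[-(1:2)] <- pmin(pmax(par[-(1:2)], -15), 10)
    par
  }
  unpack <- function(par) {
    par <- clamp(par)
    a <- exp(par[1])
    b <- par[2] + c(0, cumsum(exp(par[-(1:2)])))
    list(a = a, b = b)
  }
  negF <- function(par) {
    q <- unpack(par)
    P <- grm_category_probs(q$a, q$b, nodes)          # Q x K
    -sum(r_kq * t(pmax(log(pmax(P, 1e-300)), -700)))
  }
  negG <- function(par) {
    par <- clamp(par)
    q <- unpack(par); a <- q$a; b <- q$b
    ps <- grm_pstar(a, b, nodes)                      # Q x (K-1)
    cum <- cbind(1, ps, 0)
    P <- pmax(cum[, 1:K, drop = FALSE] - cum[, 2:(K + 1), drop = FALSE], 1e-300)
    ratio <- t(r_kq) / P                              # Q x K: r_kq / P_kq
    # coefficient of dP*_k for k = 1..K-1: r_{k+1}/P_{k+1} - r_k/P_k
    cc <- ratio[, 2:K, drop = FALSE] - ratio[, 1:(K - 1), drop = FALSE]
    W <- cc * ps * (1 - ps)                           # Q x (K-1)
    dF_da <- sum(W * outer(nodes, b, `-`))
    dF_db <- -a * colSums(W)                          # length K-1
    g_loga <- a * dF_da
    g_b1 <- sum(dF_db)
    g_gaps <- if (K > 2) {
      vapply(seq_len(K - 2), function(jj) {
        exp(par[2 + jj]) * sum(dF_db[(jj + 1):(K - 1)])
      }, numeric(1))
    } else NULL
    -c(g_loga, g_b1, g_gaps)
  }
  opt <- optim(par0, negF, negG, method = "BFGS",
               control = list(maxit = 50, reltol = 1e-10))
  out <- unpack(opt$par)
  # never step downhill: BFGS from the current point cannot end worse, but a
  # failed line search returns the start, which is fine for a GEM step
  if (negF(opt$par) > negF(par0)) out <- list(a = exp(par0[1]),
                                              b = par0[2] + c(0, cumsum(exp(par0[-(1:2)]))))
  out
}

#' @export
print.grm_fit <- function(x, ...) {
  cat(sprintf("<grm_fit: %d items, n = %d, logLik = %.2f, %s after %d EM iterations>\n",
              nrow(x$params), x$n, x$loglik,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' @method tidy grm_fit
#' @export
tidy.grm_fit <- function(x, ...) {
  dplyr::bind_rows(lapply(seq_len(nrow(x$params)), function(j) {
    if (x$params$degenerate[j]) {
      return(tibble(item_id = x$params$item_id[j], term = "a", estimate = NA_real_))
    }
    b <- x$params$b[[j]]
    tibble(item_id = x$params$item_id[j],
           term = c("a", paste0("b", seq_along(b))),
           estimate = c(x$params$a[j], b))
  }))
}

#' @method glance grm_fit
#' @export
glance.grm_fit <- function(x, ...) {
  tibble(logLik = x$loglik, n = x$n, n_items = nrow(x$params),
         iterations = x$iterations, converged = x$converged)
}

#' Item information at a trait level for every item of a fit
#'
#' @param fit A `grm_fit`.
#' @param theta Trait level (default 0, the population mean).
#' @return Named numeric vector (NA for degenerate items).
#' @export
grm_information_at <- function(fit, theta = 0) {
  vapply(seq_len(nrow(fit$params)), function(j) {
    if (fit$params$degenerate[j]) return(NA_real_)
    grm_item_information(fit$params$a[j], fit$params$b[[j]], theta)
  }, numeric(1)) |> setNames(fit$params$item_id)
}
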