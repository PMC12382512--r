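#' Genetic-algorithm configuration
#'
#' Operator settings for [run_ga()]. Defaults: population 100, 100
#' generations, tournament selection of size 3, uniform set-crossover with
#' repair, per-individual swap mutation at rate 0.1, elitism 1.
#'
#' @param population_size Individuals per generation (>= 2).
#' @param generations Number of generations.
#' @param crossover_rate Probability a selected pair is crossed.
#' @param mutation_rate Probability an individual receives a swap mutation.
#' @param tournament_size Tournament size for parent selection.
#' @param elitism_count Top individuals copied unchanged into the next
#'   generation (>= 1 guarantees a non-decreasing best-fitness trajectory).
#' @param seed Integer seed; identical seeds give identical runs.
#' @param m Items selected per factor.
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(population_size = 100L, generations = 100L,
                      crossover_rate = 0.9, mutation_rate = 0.1,
                      tournament_size = 3L, elitism_count = 1L,
                      seed = 1L, m = 6L) {
  if (population_size < 2) abort("population_size must be at least 2")
  for (r in c(crossover_rate, mutation_rate)) {
    if (r < 0 || r > 1) abort("rates must lie in [0, 1]")
  }
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 tournament_size = as.integer(tournament_size),
                 elitism_count = as.integer(elitism_count),
                 seed = as.integer(seed), m = as.integer(m)),
            class = "ga_config")
}

#' Four-component fitness of a candidate item subset
#'
#' The fitness is the raw, unweighted sum of four components: (a) the Pearson
#' correlation between short-form and full-scale factor total scores (averaged
#' across factors when the subset spans several), (b) Cronbach's alpha of the
#' subset (averaged across factors), (c) the mean item information at trait
#' level 0 under a graded response model fitted on the full data, and (d) the
#' mean item discrimination.
#'
#' @param subset_ids Character vector of selected item ids.
#' @param data A cleaned, direct-scored `likert_tbl`.
#' @param bank The matching [item_bank].
#' @param grm_fits A named list of `grm_fit` objects, one per subscale (see
#'   [fit_grm_by_subscale()]), fitted on the full data beforehand.
#' @return A list of class `ga_candidate` with `items`, `components` (named:
#'   `r_total`, `alpha`, `mean_info_at_0`, `mean_discrimination`) and
#'   `fitness` (their sum).
#' @export
ga_fitness <- function(subset_ids, data, bank, grm_fits) {
  X <- response_matrix(data)
  sub_bank <- bank[bank$item_id %in% subset_ids, ]
  factors <- unique(sub_bank$subscale)
  r_vals <- alpha_vals <- numeric(0)
  for (f in factors) {
    full_ids <- bank$item_id[bank$subscale == f]
    short_ids <- sub_bank$item_id[sub_bank$subscale == f]
    full_total <- rowSums(X[, full_ids, drop = FALSE])
    short_total <- rowSums(X[, short_ids, drop = FALSE])
    if (sd(full_total) == 0 || sd(short_total) == 0) {
      abort("zero-variance total score; fitness undefined")
    }
    r_vals <- c(r_vals, cor(short_total, full_total))
    alpha_vals <- c(alpha_vals, cronbach_alpha(X[, short_ids, drop = FALSE]))
  }
  a_all <- info_all <- numeric(0)
  for (f in factors) {
    fit <- grm_fits[[f]]
    if (is.null(fit)) abort(sprintf("no GRM fit supplied for subscale '%s'", f))
    ids_f <- intersect(subset_ids, fit$params$item_id)
    a_all <- c(a_all, fit$params$a[match(ids_f, fit$params$item_id)])
    info_all <- c(info_all, grm_information_at(fit, 0)[ids_f])
  }
  components <- c(r_total = mean(r_vals), alpha = mean(alpha_vals),
                  mean_info_at_0 = mean(info_all), mean_discrimination = mean(a_all))
  structure(list(items = sort(subset_ids), components = components,
                 fitness = sum(components)),
            class = "ga_candidate")
}

#' Fit graded response models subscale by subscale
#'
#' Convenience wrapper used before a GA run: one [fit_grm()] per subscale on
#' the full (cleaned, direct-scored) data.
#'
#' @inheritParams ga_fitness
#' @param grid A [theta_grid()].
#' @param ... Passed to [fit_grm()].
#' @return Named list of `grm_fit` objects, one per subscale label.
#' @export
fit_grm_by_subscale <- function(data, bank, grid = theta_grid(), ...) {
  X <- response_matrix(data)
  lapply(subscale_split(bank), function(ids) {
    fit_grm(X[, ids, drop = FALSE], grid = grid, ...)
  })
}

#' Genetic-algorithm short-form search
#'
#' Evolves, independently for every subscale, a size-`m` item subset that
#' maximizes the four-component fitness of [ga_fitness()], then concatenates
#' the per-factor winners. Tournament selection, uniform set-crossover with
#' repair (children are filled/trimmed back to size `m`), swap mutation, and
#' elitism; with `elitism_count >= 1` the best fitness per generation never
#' decreases.
#'
#' @inheritParams ga_fitness
#' @param cfg A [ga_config()].
#' @return A list of class `ga_result`: `short_form` ([short_form],
#'   `method_tag = "GA"`), `best` (the winning `ga_candidate` over the full
#'   concatenated selection), and `history` (tibble of best fitness per factor
#'   and generation).
#' @export
run_ga <- function(data, bank, grm_fits, cfg = ga_config()) {
  X <- response_matrix(data)
  factors <- sort(unique(bank$subscale))
  history <- list()
  picks <- list()
  for (fi in seq_along(factors)) {
    f <- factors[fi]
    ids <- sort(bank$item_id[bank$subscale == f])
    if (length(ids) < cfg$m) {
      abort(sprintf("subscale '%s' has fewer than m = %d items", f, cfg$m))
    }
    # covariance-based fitness: algebraically identical to ga_fitness() but
    # free of any per-evaluation pass over the n respondents
    Cf <- cov(X[, ids, drop = FALSE])
    var_full <- sum(Cf)
    if (var_full == 0) abort("zero-variance total score; fitness undefined")
    info_f <- grm_information_at(grm_fits[[f]], 0)
    a_f <- setNames(grm_fits[[f]]$params$a, grm_fits[[f]]$params$item_id)
    fit_fun <- function(subset) {
      idx <- match(subset, ids)
      Cs <- Cf[idx, idx, drop = FALSE]
      var_short <- sum(Cs)
      if (var_short == 0) abort("zero-variance total score; fitness undefined")
      r <- sum(Cf[idx, , drop = FALSE]) / sqrt(var_short * var_full)
      k <- length(idx)
      alpha <- k / (k - 1) * (1 - sum(diag(Cs)) / var_short)
      r + alpha + mean(info_f[subset]) + mean(a_f[subset])
    }
    res <- withr_seed(cfg$seed + fi - 1L,
                      ga_evolve(ids, cfg, fit_fun))
    picks[[f]] <- res$best
    history[[f]] <- tibble(factor = f,
                           generation = seq_along(res$trajectory),
                           best_fitness = res$trajectory)
  }
  all_items <- unlist(picks, use.names = FALSE)
  best <- ga_fitness(all_items, data, bank, grm_fits)
  sf <- short_form(
    dplyr::bind_rows(lapply(factors, function(f) {
      tibble(item_id = sort(picks[[f]]), group = f,
             rank = seq_along(picks[[f]]))
    })), "GA", cfg$m)
  structure(list(short_form = sf, best = best,
                 history = dplyr::bind_rows(history), config = cfg),
            class = "ga_result")
}

# core evolutionary loop over size-m subsets of `ids` (RNG already seeded)
ga_evolve <- function(ids, cfg, fit_fun) {
  m <- cfg$m
  pop <- replicate(cfg$population_size, sort(sample(ids, m)), simplify = FALSE)
  fitness <- vapply(pop, fit_fun, numeric(1))
  trajectory <- numeric(cfg$generations)
  for (gen in seq_len(cfg$generations)) {
    ord <- order(fitness, decreasing = TRUE)
    elite <- pop[ord[seq_len(min(cfg$elitism_count, length(pop)))]]
    children <- list()
    while (length(children) < cfg$population_size - length(elite)) {
      p1 <- pop[[tournament(fitness, cfg$tournament_size)]]
      p2 <- pop[[tournament(fitness, cfg$tournament_size)]]
      child <- if (runif(1) < cfg$crossover_rate) {
        crossover_sets(p1, p2, m)
      } else p1
      if (runif(1) < cfg$mutation_rate) child <- swap_mutate(child, ids)
      children[[length(children) + 1L]] <- sort(child)
    }
    pop <- c(elite, children)
    fitness <- vapply(pop, fit_fun, numeric(1))
    trajectory[gen] <- max(fitness)
  }
  list(best = pop[[which.max(fitness)]], trajectory = trajectory)
}

tournament <- function(fitness, size) {
  idx <- sample.int(length(fitness), min(size, length(fitness)))
  idx[which.max(fitness[idx])]
}

# uniform set-crossover with repair: keep the intersection, fill the rest
# randomly from the symmetric difference, trim/fill back to size m
crossover_sets <- function(p1, p2, m) {
  core <- intersect(p1, p2)
  rest <- setdiff(union(p1, p2), core)
  need <- m - length(core)
  if (need > 0) {
    core <- c(core, sample(rest, min(need, length(rest))))
  }
  if (length(core) > m) core <- sample(core, m)
  core
}

swap_mutate <- function(subset, ids) {
  out <- setdiff(ids, subset)
  if (length(out) == 0) return(subset)
  drop <- sample(seq_along(subset), 1)
  subset[drop] <- sample(out, 1)
  subset
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("<ga_result: %d items selected, fitness %.4f (r %.3f, alpha %.3f, info %.3f, a %.3f)>\n",
              nrow(x$short_form), x$best$fitness,
              x$best$components["r_total"], x$best$components["alpha"],
              x$best$components["mean_info_at_0"],
              x$best$components["mean_discrimination"]))
  invisible(x)
}

#' @method tidy ga_result
#' @export
tidy.ga_result <- function(x, ...) as_tibble(x$short_form)

#' @method glance ga_result
#' @export
glance.ga_result <- function(x, ...) {
  tibble(fitness = x$best$fitness,
         r_total = unname(x$best$components["r_total"]),
         alpha = unname(x$best$components["alpha"]),
         mean_info_at_0 = unname(x$best$components["mean_info_at_0"]),
         mean_discrimination = unname(x$best$components["mean_discrimination"]),
         n_selected = nrow(x$short_form))
}
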