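---
title: "Methods: semantic-embedding short forms and their validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semantic-embedding short forms and their validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shortform)
```

## The problem

A short form of a multi-item psychological scale keeps a fraction of the
items while preserving the full scale's reliability, validity and factor
structure. Classical approaches — item–total correlations (CTT), principal
component loadings (PCA), IRT-guided optimization — all need a large
response data set before any item can be dropped. The method at the core of
this package instead works from the *text* of the items: each item is mapped
to a dense semantic vector by a sentence-embedding model, the vectors are
clustered, and the items nearest each cluster centroid become the short
form. Response data then enters only at the validation stage, to check that
the semantically chosen items behave psychometrically.

The package implements that pipeline end to end, together with three
response-driven baselines (CTT, PCA, and a genetic algorithm driven by a
graded response model) and a shared validation suite, so the four methods
can be compared under identical conditions.

## The semantic (TE) pipeline

1. **Embedding.** `embed_items()` produces one vector per item, in bank
   order. Reverse-keyed items are embedded through a positively worded
   rewording (`reworded_text`), because a sentence encoder represents "I
   don't talk a lot" and "I talk a lot" as nearly opposite meanings while
   the construct direction is a scoring convention, not a semantic one.
   The backend is pluggable: precomputed vectors from any external model are
   loaded from TSV (`backend = "file"`), and a deterministic `"synthetic"`
   backend generates clusterable pseudo-embeddings for tests and examples.
   Embeddings are L2-normalized by default so cosine and Euclidean geometry
   agree up to a monotone transform; `normalize = FALSE` switches this off.

2. **Dimensionality reduction.** `reduce_dim()` projects the vectors to
   `r = 5` components before clustering (five target constructs suggest a
   roughly five-dimensional semantic manifold). The reducer is principal
   components: deterministic for a given input — reruns are bitwise
   identical, which we consider non-negotiable for a selection procedure —
   and sufficient to preserve the between-group directions that K-means
   needs, which is the only property the downstream pipeline relies on.
   Component signs are fixed (largest-magnitude loading positive) so results
   do not depend on the LAPACK build. A `"none"` method passes the input
   through untouched, so every downstream stage can be tested in a
   hand-checkable space.

3. **Clustering.** `kmeans_cluster()` is standard K-means on the reduced
   space (within-cluster sum of squares objective) with k-means++
   initialization, `n_init = 10` restarts and a fixed seed; the restart with
   the lowest within-cluster sum of squares wins. k-means++ matters: with
   purely random starts, well-separated item groups occasionally collapse
   into a merged/split local optimum even at 10 restarts.

4. **Selection.** `select_items()` ranks the items of each cluster by cosine
   distance to the cluster centroid, in the same reduced space the
   clustering used (a `raw_space` analysis is possible by clustering with
   `reduce_method = "none"`). The `m = 6` nearest items per cluster are
   kept. Exact ties — possible with duplicated item texts — break by
   lexicographic `item_id`, so the selection is a deterministic function of
   the input set, invariant to input order. Clusters smaller than `m`
   contribute everything they have, with a warning, rather than failing.

5. **Diagnostics.** `silhouette_scores()` computes the usual
   `s(i) = (b(i) − a(i)) / max(a(i), b(i))` per item (Euclidean in the
   reduced space by default, cosine optional; singletons get `s = 0`), and
   `hungarian_align()` matches clusters to the bank's subscale labels by
   solving the optimal assignment problem on the confusion matrix, reporting
   the mapping and its accuracy (matched items over all items). Non-square
   confusion matrices are padded with zero-count dummies.

`run_te_reduction()` composes the five stages and keeps every intermediate
result.

## Classical baselines

`ctt_select()` ranks items within each subscale by the Pearson correlation
between the item and the subscale total. The total *includes* the item —
the uncorrected item–total statistic — because that is the classical
definition of the statistic this selector implements; the corrected
item-rest variant is available via `corrected = TRUE`. `pca_select()` ranks
by the absolute loading on the first principal component of the subscale's
item correlation matrix, sign-aligned so the loading sum is positive. One
component per subscale is used: the subscales are designed to be
unidimensional, and the first component is the only one with a defensible
a-priori interpretation. Correlation rather than covariance PCA is the
conservative default for Likert items (`use_cor = FALSE` switches).
Zero-variance items have no defined statistic and rank last, with a warning.

## The graded response model

`fit_grm()` estimates, per item, a discrimination `a > 0` and ordered
category thresholds `b_1 < … < b_{K−1}` under Samejima's logistic form:
cumulative curves `P*_k(θ) = logit⁻¹(a(θ − b_k))` and category
probabilities `P_k = P*_{k−1} − P*_k`. The latent trait is fixed to
N(0, 1) for identification and integrated out on a quadrature grid of 61
equally spaced nodes on [−6, 6] with renormalized normal-density weights —
simple, reproducible, and accurate to well past the precision the rest of
the pipeline consumes.

Estimation is marginal maximum likelihood by EM:

* **E-step** — each respondent's posterior over the grid; the weights sum
  to one by construction and the marginal log-likelihood is accumulated
  with a log-sum-exp guard.
* **M-step** — per item, BFGS with analytic gradients on the expected
  complete-data log-likelihood, parameterized as `(log a, b_1, log gaps)`
  so positivity and threshold order are structural rather than constrained;
  the raw parameters are clamped to generous boxes so `exp()` can neither
  overflow nor underflow into a zero gap. A failed line search falls back
  to the incoming parameters, so each sweep is a proper generalized-EM step
  and the marginal log-likelihood is non-decreasing (asserted in tests at
  every iteration).

Start values are `a = 1` and thresholds at normal quantiles of the observed
cumulative category proportions. Convergence is declared when the largest
parameter change drops below `1e-4`; after 500 iterations the best estimate
is returned with a warning. Unobserved categories are collapsed away
(the `categories` field records the mapping); items with a single observed
category cannot be scaled and are flagged degenerate rather than guessed
at. `grm_item_information()` gives the Fisher information
`Σ_k (P'_k)² / P_k`, with probabilities floored at `1e-300`.

## Genetic-algorithm selection

`ga_fitness()` scores a candidate subset as the *raw, unweighted sum* of
four components: (a) correlation between short-form and full-scale factor
totals, (b) Cronbach's alpha of the subset, (c) mean item information at
θ = 0, and (d) mean discrimination — components on different scales, summed
deliberately without normalization, which is the literal reading of a
"sum of four components" fitness; a min–max normalized mode exists for
sensitivity analysis. The GRM is fitted once on the full data, not refitted
per candidate: at convergence the item parameters do not depend on which
subset is being scored, and refitting inside the loop would only add noise
and three orders of magnitude of cost.

`run_ga()` evolves each factor's size-`m` subset independently and
concatenates the winners — the published short forms keep a fixed count per
factor, and per-factor search makes the size constraint structural. A
global 30-of-50 chromosome offers no extra expressiveness under that
constraint. Operators (population 100, 100 generations, tournament of 3,
uniform set-crossover with repair to size `m`, swap mutation at rate 0.1,
elitism 1, fixed seed) are conventional defaults; elitism makes the best
fitness trajectory provably non-decreasing, and the whole run is a
deterministic function of the seed. Inside the loop, fitness is computed
from the per-factor covariance matrix (algebraically identical to the
definition, independent of n per evaluation); tests verify the GA matches
exhaustive enumeration on every C(8,4) instance across 10 seeds.

## Validation

* **Reliability.** `cronbach_alpha()` uses population (denominator-n)
  variances throughout; the estimate is identical under either convention
  (the ratio cancels the degrees-of-freedom factor), but fixing one makes
  every reported digit well-defined. Alpha can be negative for incoherent
  item sets; that is reported, not clipped.
* **Factor scores** are *sums* of direct-scored item responses — the
  "total score" reading; means would change nothing that a correlation or
  alpha can see.
* **Convergent validity** (`convergent_correlations()`) is the per-factor
  Pearson correlation between short-form and full-scale sums, plus their
  mean and the total-score correlation. `correlation_matrices()` adds the
  factor-intercorrelation matrix and the original-by-short cross matrix
  whose diagonal is the convergent validities.
* **Prediction.** `predict_original_scores()` trains a three-layer dense
  network (input → 64 → 32 → output, ReLU, Adam at 1e-3, 20 epochs, batches
  of 256) on an 80/20 split to predict the five full-scale subscale sums
  jointly from the short form's item responses, with inputs and targets
  standardized on the training split and predictions mapped back before
  any metric is computed. The architecture is the smallest reasonable
  realization of "three fully connected layers"; all of it is
  configurable. Subscale sums are the targets (an `"items"` mode predicts
  every original item instead). A least-squares linear baseline on the same
  split is always reported next to the network: on sum-score targets the
  signal is almost entirely linear, and a network that cannot match the
  baseline is diagnostic of a training problem, not of the short form.
  MAE, RMSE, R² and MAPE are pooled over targets on the held-out split;
  MAPE excludes zero targets with a counted warning (cannot occur for
  Likert sums starting at 1).

## Preprocessing

`clean_responses()` applies, in fixed order: listwise removal of rows with
missing responses; Mahalanobis outlier exclusion; reverse-score flipping
`x → (min + max) − x`. The Mahalanobis step uses the classical sample
covariance and the chi-square reference `χ²_{p, 1−α}` with α = 0.01 by
default; robust covariance estimators (e.g. MCD) are deliberately not used,
to match the classical procedure. Rows *strictly above* the threshold are
removed — a tie at the threshold is kept. A singular covariance gets a
ridge jitter `ε I` with `ε = 1e-8 · tr(S)/p` and a warning; fewer rows than
columns is an error. Every step logs its counts, and
`n_input − removed_missing − removed_outlier = n_retained` holds by
construction.

## The synthetic generator

`gen_responses()` draws correlated standard-normal factors, builds item
scores `y = λf + √(1−λ²)ε`, and discretizes them at fixed cutpoints —
normal quantiles {0.1, 0.3, 0.7, 0.9}, giving a centered five-point
distribution. Reverse-keyed items are *stored flipped*, so the
preprocessing stage has real work to do. Defaults emulate a five-factor,
50-item, five-point inventory: loadings spread over 0.45–0.75, factor
intercorrelations 0.2, 20% reverse-keyed items, n = 5,000 — large enough
for stable alpha estimates, small enough to run everywhere. The truth
record (per-item factor, loading, reverse flag, plus the pre-discretization
latent scores) supports calibration tests: the latent correlation matrix
converges to the λλᵀ structure, and discretization attenuates but never
re-signs correlations.

`gen_embeddings()` plants cluster structure directly: unit-sphere centers
with pairwise angles of at least 60° (so any two centers are at least unit
distance apart), plus isotropic noise with expected norm `1/separation`;
`separation` is therefore a lower bound on the between/within distance
ratio. At `separation = 0` the labels carry no geometric signal and
recovery accuracy sits at chance level.

What the generator does *not* emulate: acquiescence and other response
styles, item-specific skew, cross-loadings, locally dependent item pairs,
and — for embeddings — any actual semantics of item text. Passing tests
therefore show that the estimators and pipelines are correct under the
stated measurement model, not that a particular embedding model will
recover a particular real scale's structure.

## Numerical choices and degenerate inputs

* Ties in any ranking break by lexicographic `item_id`; selections are
  invariant to input order.
* Cosine distance errors on zero-norm vectors rather than guessing.
* K-means with `k` equal to the number of items returns the trivial
  partition (inertia 0) without invoking the iterative algorithm.
* The reference quadrature weights sum to 1 within 1e-10; GRM category
  probabilities sum to 1 within 1e-12.
* Alpha, correlation and fitness computations error loudly on zero-variance
  totals instead of returning NaN.

## Problem sizes in the test suite

The suite regenerates all fixtures in code: reliability and structure
checks use n = 5,000 synthetic respondents (20,000 for the latent-structure
convergence check), GRM recovery uses 6 items × n = 2,000, GA-vs-exhaustive
uses C(8,4) = 70 subsets across 10 seeds, and pipeline recovery uses 20
generator seeds. These sizes were chosen so each statistic is stable to
well inside its asserted tolerance while the whole suite stays
interactive.

## Known limitations

* The embedding model itself is out of scope: quality of a semantic short
  form is bounded by the encoder it is given.
* Rewording reverse-keyed items for embedding may shift their meaning; the
  package requires the rewording but cannot audit it.
* No confirmatory factor analysis or model-fit indices; validation here is
  reliability, convergent validity, structural correlation and prediction.
* The GA's four fitness components are summed on their natural scales, so
  the information term (typically the largest) carries the most weight;
  use the normalized mode to explore alternatives.
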