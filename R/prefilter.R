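#' Rescale every gene to the unit interval
#'
#' Each gene (column) is mapped affinely so that its minimum becomes 0 and
#' its maximum 1, giving every gene equal weight in the downstream
#' classifier. A constant gene, for which the map is undefined, is set to
#' all zeros: such genes carry no class information and rank last in the
#' prefilter anyway.
#'
#' @param dataset an [expression_dataset()] (or a labelled data frame,
#'   coerced via [as_expression_dataset()]).
#' @param ... passed to [as_expression_dataset()].
#' @return An `expression_dataset` with rescaled values.
#' @examples
#' d <- expression_dataset(cbind(c(1, 2, 3), c(5, 5, 5)), c("A", "A", "B"))
#' normalize_expression(d)$values
#' @export
normalize_expression <- function(dataset, ...) {
  dataset <- as_expression_dataset(dataset, ...)
  v <- dataset$values
  lo <- apply(v, 2L, min)
  hi <- apply(v, 2L, max)
  span <- hi - lo
  const <- span == 0
  span[const] <- 1  # avoid 0/0; constant genes forced to 0 below
  out <- sweep(sweep(v, 2L, lo, "-"), 2L, span, "/")
  out[, const] <- 0
  dataset$values <- out
  dataset
}

#' Rank genes by class-discrimination strength
#'
#' Two univariate filters are available. `"kruskal_wallis"` ranks genes by
#' the p-value of the Kruskal-Wallis rank-sum statistic
#' \deqn{K = \frac{12}{N(N+1)} \sum_k n_k (\bar r_k - (N+1)/2)^2}
#' computed on mid-ranks, divided by the tie-correction factor
#' \eqn{1 - \sum_j (t_j^3 - t_j) / (N^3 - N)} when ties are present, with
#' \eqn{p = \Pr(\chi^2_{C-1} \ge K)}; lower p means higher rank.
#' `"f_test"` ranks by the Fisher score
#' \deqn{F = \frac{\sum_k n_k (\mu_k - \mu)^2}{\sum_k n_k \sigma_k^2}}
#' with population (divide-by-\eqn{n_k}) class standard deviations, so the
#' denominator is the pooled within-class sum of squared deviations; higher
#' F means higher rank. A gene with zero within-class variance but distinct
#' class means receives `Inf` and ranks first; a gene whose samples are all
#' identical scores `K = 0, p = 1` (or `F = 0`). Ties in the ranking are
#' broken by original gene index, so runs are deterministic.
#'
#' @inheritParams normalize_expression
#' @param method `"kruskal_wallis"` (default) or `"f_test"`.
#' @return A tibble with one row per gene: `gene` (identifier),
#'   `gene_index` (column in the dataset), `score` (K or F), `p_value`
#'   (Kruskal-Wallis only, otherwise `NA`), and `rank` (1 = best). Rows are
#'   ordered best-first. The method is recorded in attribute `"method"`.
#' @examples
#' d <- expression_dataset(cbind(c(1, 2, 3, 4, 5, 6), rnorm(6)),
#'                         rep(c("A", "B"), each = 3))
#' rank_genes(d)
#' @export
rank_genes <- function(dataset, method = c("kruskal_wallis", "f_test"), ...) {
  method <- match.arg(method)
  dataset <- as_expression_dataset(dataset, ...)
  if (dataset$n_samples < nlevels(dataset$labels)) {
    stop("fewer samples than classes", call. = FALSE)
  }
  if (method == "kruskal_wallis") {
    st <- kruskal_wallis_scores(dataset$values, dataset$labels)
    ord <- order(st$p_value, -st$score, seq_along(st$p_value))
    out <- tibble::tibble(
      gene = dataset$gene_ids,
      gene_index = seq_len(dataset$n_genes),
      score = st$score,
      p_value = st$p_value
    )
  } else {
    f <- f_scores_matrix(dataset$values, dataset$labels)
    ord <- order(-f, seq_along(f))
    out <- tibble::tibble(
      gene = dataset$gene_ids,
      gene_index = seq_len(dataset$n_genes),
      score = f,
      p_value = NA_real_
    )
  }
  out <- out[ord, ]
  out$rank <- seq_len(nrow(out))
  attr(out, "method") <- method
  out
}

# Vectorized Kruskal-Wallis statistic with mid-rank tie handling and the
# standard tie-correction divisor, one gene per column. Kept in-package so
# thousands of genes rank in one pass; equivalence with stats::kruskal.test
# is pinned by tests to 1e-9.
kruskal_wallis_scores <- function(values, labels) {
  N <- nrow(values)
  C <- nlevels(labels)
  score <- numeric(ncol(values))
  p_value <- numeric(ncol(values))
  for (j in seq_len(ncol(values))) {
    r <- rank(values[, j])
    rbar <- vapply(split(r, labels), mean, numeric(1))
    nk <- tabulate(labels, nbins = C)
    K <- 12 / (N * (N + 1)) * sum(nk * (rbar - (N + 1) / 2)^2)
    ties <- table(values[, j])
    tie_factor <- 1 - sum(ties^3 - ties) / (N^3 - N)
    if (tie_factor > 0) {
      K <- K / tie_factor
    } else {
      K <- 0  # every observation tied: no evidence against the null
    }
    score[j] <- K
    p_value[j] <- stats::pchisq(K, df = C - 1, lower.tail = FALSE)
  }
  list(score = score, p_value = p_value)
}

# Fisher scores for all genes at once (population-SD convention).
f_scores_matrix <- function(values, labels) {
  nk <- tabulate(labels, nbins = nlevels(labels))
  mu <- colMeans(values)
  between <- numeric(ncol(values))
  within <- numeric(ncol(values))
  for (k in seq_len(nlevels(labels))) {
    vk <- values[labels == levels(labels)[k], , drop = FALSE]
    muk <- colMeans(vk)
    between <- between + nk[k] * (muk - mu)^2
    # population variance: n_k * sigma_k^2 = class sum of squared deviations
    within <- within + colSums(sweep(vk, 2L, muk, "-")^2)
  }
  ifelse(within == 0, ifelse(between == 0, 0, Inf), between / within)
}

#' Pre-select top-ranked genes for the swarm search
#'
#' In `"percentage"` mode the top `floor(value * n)` ranked genes are kept
#' (never fewer than one). In `"threshold"` mode, genes with Kruskal-Wallis
#' p-value of at most `value` are kept (for a Fisher-score ranking, genes
#' with score strictly above `value`). Ranking order is preserved.
#'
#' @param ranking a tibble from [rank_genes()].
#' @param mode `"percentage"` (default) or `"threshold"`.
#' @param value fraction of genes to keep, or the p-value / score cut-off.
#' @return Integer vector of gene indices (columns of the original
#'   dataset), best rank first.
#' @export
preselect <- function(ranking, mode = c("percentage", "threshold"),
                      value = 0.065) {
  mode <- match.arg(mode)
  n <- nrow(ranking)
  if (mode == "percentage") {
    if (value <= 0 || value > 1) {
      stop("percentage `value` must be in (0, 1]", call. = FALSE)
    }
    keep <- max(1L, floor(value * n))
    return(ranking$gene_index[seq_len(keep)])
  }
  if (value <= 0 || value > 1 && identical(attr(ranking, "method"), "kruskal_wallis")) {
    stop("threshold `value` must be in (0, 1]", call. = FALSE)
  }
  sel <- if (identical(attr(ranking, "method"), "f_test")) {
    ranking$score > value
  } else {
    ranking$p_value <= value  # inclusive so a cut-off of 1 keeps every gene
  }
  if (!any(sel)) {
    stop("threshold keeps no genes; relax the threshold or use ",
         "percentage mode", call. = FALSE)
  }
  ranking$gene_index[sel]
}
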