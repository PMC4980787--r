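#' Select a discriminative gene subset from a labelled expression matrix
#'
#' End-to-end pipeline: per-gene unit rescaling, statistical gene ranking
#' (Kruskal-Wallis by default), pre-selection of the top `th_n` fraction,
#' and the modified bee-colony search over the surviving genes with
#' SVM-LOOCV fitness. The global best of the final iteration is returned;
#' reaching 100 percent accuracy is deliberately not a stopping rule,
#' since later iterations can find a smaller subset with the same
#' accuracy.
#'
#' @param data a labelled data frame (label column first by default), an
#'   [expression_dataset()], or a file path accepted by
#'   [read_expression_dataset()].
#' @param params a [mabc_params()] or [mabc_preset()] object.
#' @param seed integer seed; every random draw of the run flows from it.
#' @param label_column label column for data-frame/file input.
#' @param evaluator optionally, a pre-built [fitness_evaluator()] over the
#'   prefiltered genes. Supplying one skips normalization, ranking and
#'   pre-selection (used to share the memoization cache across the runs of
#'   an experiment); its gene ids must be dataset column ids.
#' @return An object of class `mabc_result`: `selected_genes` (ids),
#'   `selected_idx` (original column indices), `accuracy` (LOOCV accuracy
#'   in percent), `fitness` (in `[0, 1]`), `n_selected`, `trace` and
#'   `pheromone_trace` tibbles, `searched_genes` (ids entering the swarm),
#'   `seed` and `params`.
#' @examples
#' \donttest{
#' sim <- simulate_expression_dataset(n_samples = 40, n_genes = 60,
#'                                    n_informative = 3, seed = 7)
#' res <- mabc_select(sim$dataset,
#'                    params = mabc_preset("first", max_iter = 3, ps = 6),
#'                    seed = 1)
#' res$selected_genes
#' }
#' @export
mabc_select <- function(data, params = mabc_params(), seed = 1L,
                        label_column = 1, evaluator = NULL) {
  stopifnot(inherits(params, "mabc_params"))
  if (is.character(data) && length(data) == 1L) {
    data <- read_expression_dataset(data, label_column = label_column)
  }
  if (is.null(evaluator)) {
    dataset <- as_expression_dataset(data, label_column = label_column)
    evaluator <- prefiltered_evaluator(dataset, params)
  }
  kept_ids <- evaluator$gene_ids
  res <- run_mabc_search(evaluator, params, seed = as.integer(seed))
  sel_local <- which(res$gbest == 1L)
  acc <- mask_fitness(evaluator, res$gbest)[["accuracy"]]
  structure(
    list(
      selected_genes = kept_ids[sel_local],
      selected_idx = attr(evaluator, "original_idx")[sel_local],
      accuracy = 100 * acc,
      fitness = res$gbest_fit,
      n_selected = length(sel_local),
      trace = res$trace,
      pheromone_trace = res$pheromone_trace,
      searched_genes = kept_ids,
      seed = as.integer(seed),
      params = params
    ),
    class = "mabc_result"
  )
}

# Normalize, rank, pre-select and wrap the kept genes in an evaluator.
# The original column indices ride along as an attribute so results can
# be reported against the input dataset.
prefiltered_evaluator <- function(dataset, params) {
  norm <- normalize_expression(dataset)
  ranking <- rank_genes(norm, method = params$prefilter)
  keep <- preselect(ranking, "percentage", params$th_n)
  sub <- expression_dataset(norm$values[, keep, drop = FALSE], norm$labels,
                            gene_ids = norm$gene_ids[keep])
  ev <- fitness_evaluator(sub, w1 = params$w1, kernel = params$kernel,
                          cost = params$cost, gamma = params$gamma)
  attr(ev, "original_idx") <- keep
  ev
}

#' @export
print.mabc_result <- function(x, ...) {
  cat(sprintf(
    "<mabc_result> %d gene(s) selected, LOOCV accuracy %.2f%%, fitness %.4f (seed %d)\n",
    x$n_selected, x$accuracy, x$fitness, x$seed))
  cat("  genes:", paste(x$selected_genes, collapse = ", "), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the selected gene subset
#'
#' @param x a `mabc_result`.
#' @param ... unused.
#' @return A tibble with one row per selected gene: `gene` and
#'   `gene_index` (column in the input dataset).
#' @export
tidy.mabc_result <- function(x, ...) {
  tibble::tibble(gene = x$selected_genes,
                 gene_index = if (is.null(x$selected_idx)) NA_integer_
                              else as.integer(x$selected_idx))
}

#' One-row summary of a selection run
#'
#' @param x a `mabc_result`.
#' @param ... unused.
#' @return A tibble with `n_selected`, `accuracy` (percent), `fitness`,
#'   `iterations` and `seed`.
#' @export
glance.mabc_result <- function(x, ...) {
  tibble::tibble(
    n_selected = x$n_selected,
    accuracy = x$accuracy,
    fitness = x$fitness,
    iterations = nrow(x$trace),
    seed = x$seed
  )
}

#' Plot the search trajectory of a selection run
#'
#' Shows the global-best fitness (solid) and the global-best subset size
#' (dashed, secondary axis) per iteration.
#'
#' @param object a `mabc_result`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.mabc_result <- function(object, ...) {
  tr <- object$trace
  size_scale <- max(tr$gbest_size) / max(tr$gbest_fitness)
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$iteration)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$gbest_fitness)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$gbest_size / size_scale),
                       linetype = "dashed") +
    ggplot2::scale_y_continuous(
      name = "global-best fitness",
      sec.axis = ggplot2::sec_axis(~ . * size_scale,
                                   name = "selected genes")) +
    ggplot2::labs(x = "iteration",
                  title = "Bee-colony search trajectory") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble
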