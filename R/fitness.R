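#' Build a subset-fitness evaluator for a dataset
#'
#' The evaluator bundles the (prefiltered, normalized) expression matrix,
#' its class labels, the support-vector-machine configuration and a
#' memoization cache. A gene mask is scored by leave-one-out
#' cross-validated SVM accuracy, combined with a parsimony reward into
#' \deqn{fitness = w_1 \cdot accuracy + (1 - w_1) \cdot (n - n_s)/n}
#' where \eqn{n} is the number of genes available to the search and
#' \eqn{n_s} the number selected by the mask. Accuracy enters as a fraction
#' in \eqn{[0, 1]}, so fitness also lies in \eqn{[0, 1]}; reporting
#' functions convert to percent.
#'
#' Evaluation is deterministic: identical masks always return identical
#' values, which is why results are cached by mask bit-pattern (LOOCV
#' dominates runtime and the swarm revisits masks heavily).
#'
#' @inheritParams normalize_expression
#' @param w1 accuracy/parsimony trade-off in `[0, 1]`; 0.85 by default.
#' @param kernel SVM kernel, `"linear"` (default) or `"radial"`.
#' @param cost SVM penalty parameter C; 2000 by default.
#' @param gamma radial-kernel width; 1e-4 by default, ignored for the
#'   linear kernel.
#' @param tolerance stopping tolerance of the SMO optimizer (LIBSVM's
#'   default 0.001).
#' @param cache memoize (accuracy, fitness) by mask? Default `TRUE`.
#' @return An object of class `fitness_evaluator`.
#' @export
fitness_evaluator <- function(dataset, w1 = 0.85,
                              kernel = c("linear", "radial"),
                              cost = 2000, gamma = 1e-4, tolerance = 0.001,
                              cache = TRUE, ...) {
  kernel <- match.arg(kernel)
  dataset <- as_expression_dataset(dataset, ...)
  stopifnot(w1 >= 0, w1 <= 1, cost > 0)
  ev <- new.env(parent = emptyenv())
  ev$x <- dataset$values
  ev$y <- dataset$labels
  ev$gene_ids <- dataset$gene_ids
  ev$n_genes <- dataset$n_genes
  ev$w1 <- w1
  ev$kernel <- kernel
  ev$cost <- cost
  ev$gamma <- gamma
  ev$tolerance <- tolerance
  ev$cache <- if (cache) new.env(parent = emptyenv(), hash = TRUE) else NULL
  ev$n_evaluations <- 0L
  class(ev) <- "fitness_evaluator"
  ev
}

#' @export
print.fitness_evaluator <- function(x, ...) {
  cat(sprintf(
    "<fitness_evaluator> %d samples x %d genes, %s SVM (C = %g), w1 = %g, %d evaluation(s)\n",
    nrow(x$x), x$n_genes, x$kernel, x$cost, x$w1, x$n_evaluations))
  invisible(x)
}

# The svm() wrapper draws from R's RNG when cross-validating (it shuffles
# a fold assignment that is immaterial for leave-one-out, where the
# partition is unique). Evaluations must not perturb the search's RNG
# stream -- otherwise a cache hit and a fresh evaluation would steer the
# swarm differently -- so the global RNG state is saved and restored
# around every evaluation.
with_rng_preserved <- function(expr) {
  if (!exists(".Random.seed", globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  expr
}

svm_fit <- function(ev, x, y, ...) {
  e1071::svm(x, y, type = "C-classification", kernel = ev$kernel,
             cost = ev$cost, gamma = ev$gamma, scale = FALSE,
             tolerance = ev$tolerance, ...)
}

#' Leave-one-out cross-validated SVM accuracy of a gene mask
#'
#' For each of the N samples the SVM is trained on the other N - 1 samples
#' restricted to the selected genes and the held-out sample is predicted;
#' accuracy is the fraction of correct predictions. Multi-class problems
#' use the one-versus-one scheme of LIBSVM. Three equivalent computation
#' routes are provided and pinned equivalent by tests. `"compiled"`
#' (the default for the linear kernel) evaluates all folds in one
#' compiled pass: the kernel matrix is computed once per mask and every
#' fold warm-starts from the full-data dual solution, so the whole
#' leave-one-out costs little more than one fit; the solver is SMO with
#' LIBSVM's stopping rule and bias computation, i.e. the same model
#' e1071 fits. `"cv"` delegates all N folds to LIBSVM's internal
#' cross-validation in one e1071 call; with the fold count equal to N
#' this is exact leave-one-out with a fixed fold assignment, hence
#' deterministic (and the default for the radial kernel, which the
#' compiled engine does not cover). `"sv"` uses the exact
#' support-vector shortcut: a sample with zero Lagrange multiplier in
#' the full-data fit leaves the solution unchanged when held out and,
#' lying outside every relevant margin, is necessarily predicted
#' correctly -- so only support vectors are refit. `"fold"` runs the N
#' explicit refits.
#'
#' @param evaluator a [fitness_evaluator()].
#' @param mask integer/logical vector over the evaluator's genes; at least
#'   one gene must be selected (an empty mask is a caller bug and errors).
#' @param method `"auto"` (default: compiled for linear, cv for radial),
#'   `"compiled"`, `"cv"`, `"sv"` or `"fold"`.
#' @return Accuracy as a fraction in `[0, 1]`.
#' @export
loocv_accuracy <- function(evaluator, mask,
                           method = c("auto", "compiled", "cv", "sv",
                                      "fold")) {
  method <- match.arg(method)
  if (method == "auto") {
    method <- if (evaluator$kernel == "linear") "compiled" else "cv"
  }
  with_rng_preserved(loocv_accuracy_impl(evaluator, mask, method))
}

loocv_accuracy_impl <- function(evaluator, mask, method) {
  idx <- which(as.integer(mask) == 1L)
  if (length(idx) == 0L) {
    stop("empty gene mask: the neighborhood operator must guarantee at ",
         "least one selected gene", call. = FALSE)
  }
  x <- evaluator$x[, idx, drop = FALSE]
  y <- evaluator$y
  N <- nrow(x)
  if (method == "compiled") {
    if (evaluator$kernel != "linear") {
      stop("the compiled evaluation route covers the linear kernel only",
           call. = FALSE)
    }
    return(loocv_linear_svm_cpp(x, as.integer(y), nlevels(y),
                                evaluator$cost, evaluator$tolerance,
                                2000000L))
  }
  if (method == "cv") {
    fit <- svm_fit(evaluator, x, y, cross = N)
    return(fit$tot.accuracy / 100)
  }
  predict_one <- function(i) {
    ytr <- droplevels(y[-i])
    if (nlevels(ytr) == 1L) {
      return(as.character(ytr[1]))
    }
    fit <- svm_fit(evaluator, x[-i, , drop = FALSE], ytr)
    as.character(stats::predict(fit, x[i, , drop = FALSE]))
  }
  if (method == "fold") {
    correct <- vapply(seq_len(N), function(i) {
      predict_one(i) == as.character(y[i])
    }, logical(1))
    return(mean(correct))
  }
  full <- svm_fit(evaluator, x, y)
  correct <- rep(TRUE, N)  # non-support-vectors: exact, provably correct
  for (i in full$index) {
    correct[i] <- predict_one(i) == as.character(y[i])
  }
  mean(correct)
}

mask_key <- function(mask) {
  paste(which(as.integer(mask) == 1L), collapse = ",")
}

#' Fitness of a gene mask
#'
#' Accuracy/parsimony combination described in [fitness_evaluator()];
#' memoized by mask when the evaluator carries a cache.
#'
#' @inheritParams loocv_accuracy
#' @return A numeric vector `c(accuracy, fitness)`, both in `[0, 1]`.
#' @export
mask_fitness <- function(evaluator, mask) {
  ns <- sum(as.integer(mask))
  if (ns == 0L) {
    stop("empty gene mask: the neighborhood operator must guarantee at ",
         "least one selected gene", call. = FALSE)
  }
  key <- mask_key(mask)
  if (!is.null(evaluator$cache)) {
    hit <- get0(key, envir = evaluator$cache, inherits = FALSE)
    if (!is.null(hit)) {
      return(hit)
    }
  }
  acc <- loocv_accuracy(evaluator, mask)
  n <- evaluator$n_genes
  fit <- evaluator$w1 * acc + (1 - evaluator$w1) * (n - ns) / n
  out <- c(accuracy = acc, fitness = fit)
  evaluator$n_evaluations <- evaluator$n_evaluations + 1L
  if (!is.null(evaluator$cache)) {
    assign(key, out, envir = evaluator$cache)
  }
  out
}
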