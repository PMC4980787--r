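# Shared fixtures, built in code at test time.

# 4 samples x 2 genes with first-column labels, as CSV text.
write_toy_csv <- function(path, header = TRUE) {
  lines <- c(if (header) "class,g0,g1",
             "A,1.0,4.0", "A,2.0,3.0", "B,3.0,2.0", "B,4.0,1.0")
  writeLines(lines, path)
  path
}

toy_dataset <- function() {
  expression_dataset(cbind(c(1, 2, 3, 4), c(4, 3, 2, 1)),
                     c("A", "A", "B", "B"), gene_ids = c("g0", "g1"))
}

# Two well-separated classes on `n_informative` genes plus noise genes.
separable_dataset <- function(n_samples = 20, n_genes = 12,
                              n_informative = 2, shift = 6, seed = 11) {
  set.seed(seed)
  v <- matrix(rnorm(n_samples * n_genes), n_samples, n_genes)
  cls <- rep(c("A", "B"), each = n_samples / 2)
  v[cls == "B", seq_len(n_informative)] <-
    v[cls == "B", seq_len(n_informative)] + shift
  expression_dataset(v, cls)
}

# The binary-mask worked example used for the neighborhood and tweak
# operators: 20 genes, 10 selected.
worked_mask <- function() {
  as.integer(c(0, 1, 1, 0, 1, 0, 0, 1, 1, 0, 1, 1, 1, 0, 0, 1, 0, 1, 0, 0))
}

# One informative gene plus constant filler genes; LOOCV accuracy of any
# mask containing gene 1 is exactly 0.9 (one class-A sample sits in the
# B cluster and is misclassified in its own fold only).
fitness_arith_evaluator <- function(n_genes = 100) {
  vals <- matrix(5, nrow = 10, ncol = n_genes)
  vals[, 1] <- c(0, 0, 0, 0, 1, 1, 1, 1, 1, 1)
  d <- expression_dataset(vals, rep(c("A", "B"), each = 5))
  fitness_evaluator(normalize_expression(d))
}

tiny_params <- function(...) {
  defaults <- list(max_iter = 3L, ps = 5L, sa_iter = 4L, sahc_iter = 3L,
                   sahc_tweak = 3L, hc_iter = 4L)
  do.call(mabc_preset,
          c(list(name = "first"), utils::modifyList(defaults, list(...))))
}
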