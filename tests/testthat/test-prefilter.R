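test_that("unit rescaling maps each gene's range onto [0, 1]", {
  d <- expression_dataset(cbind(c(1, 2, 3), c(5, 5, 5), c(-2, 0, 6)),
                          c("A", "A", "B"))
  nv <- normalize_expression(d)$values
  expect_equal(nv[, 1], c(0, 0.5, 1))
  expect_equal(nv[, 2], c(0, 0, 0))  # constant gene convention
  expect_equal(nv[, 3], c(0, 0.25, 1))
  set.seed(21)
  big <- expression_dataset(matrix(rnorm(200, sd = 50), 10, 20),
                            rep(c("A", "B"), 5))
  nb <- normalize_expression(big)$values
  expect_equal(unname(apply(nb, 2, min)), rep(0, 20))
  expect_equal(unname(apply(nb, 2, max)), rep(1, 20))
})

test_that("Kruskal-Wallis statistic matches hand-worked and frozen cases", {
  # symmetric ranks: both class mean ranks equal (N+1)/2, so K = 0, p = 1
  d0 <- expression_dataset(cbind(c(1, 4, 2, 3)), c("A", "A", "B", "B"))
  r0 <- rank_genes(d0)
  expect_equal(r0$score, 0)
  expect_equal(r0$p_value, 1)
  # untied 6-sample gene: K = 12/(6*7) * (3*(2-3.5)^2 + 3*(5-3.5)^2) = 27/7
  d1 <- expression_dataset(cbind(1:6), rep(c("A", "B"), each = 3))
  r1 <- rank_genes(d1)
  expect_equal(r1$score, 27 / 7, tolerance = 1e-12)
  expect_equal(r1$p_value, 0.049534613435626, tolerance = 1e-12)  # scipy chi2.sf
  # fully tied pairs: tie correction divides K; frozen scipy reference
  d2 <- expression_dataset(cbind(c(1, 1, 2, 2)), c("A", "A", "B", "B"))
  r2 <- rank_genes(d2)
  expect_equal(r2$score, 3, tolerance = 1e-12)
  expect_equal(r2$p_value, 0.0832645166635504, tolerance = 1e-12)
  ref <- stats::kruskal.test(c(1, 1, 2, 2), factor(c("A", "A", "B", "B")))
  expect_equal(r2$score, unname(ref$statistic), tolerance = 1e-12)
})

test_that("Kruskal-Wallis agrees with the reference implementation on random tied genes", {
  set.seed(77)
  for (rep in 1:30) {
    N <- sample(6:30, 1)
    C <- sample(2:4, 1)
    labels <- factor(sample(letters[1:C], N, replace = TRUE))
    while (nlevels(droplevels(labels)) < C) {
      labels <- factor(sample(letters[1:C], N, replace = TRUE))
    }
    g <- sample(1:6, N, replace = TRUE) + rnorm(N, sd = 0.01) *
      rbinom(N, 1, 0.5)  # mixture of heavy ties and distinct values
    d <- expression_dataset(cbind(g, rnorm(N)), labels)
    r <- rank_genes(d)
    r <- r[order(r$gene_index), ]
    ref <- stats::kruskal.test(g, labels)
    expect_equal(r$score[1], unname(ref$statistic), tolerance = 1e-9)
    expect_equal(r$p_value[1], ref$p.value, tolerance = 1e-9)
  }
})

test_that("Kruskal-Wallis is invariant under strictly monotone transforms", {
  set.seed(5)
  g <- rnorm(12)
  labels <- rep(c("A", "B", "C"), each = 4)
  r1 <- rank_genes(expression_dataset(cbind(g), labels))
  r2 <- rank_genes(expression_dataset(cbind(exp(3 * g) + 2), labels))
  expect_equal(r1$score, r2$score, tolerance = 1e-12)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
})

test_that("Fisher scores reproduce hand-computed values and degenerate rules", {
  # equal class means: between-class numerator vanishes
  d0 <- expression_dataset(cbind(c(1, 3, 1, 3)), c("A", "A", "B", "B"))
  expect_equal(rank_genes(d0, method = "f_test")$score, 0)
  # hand-worked: numerator 2*.25 + 2*.25 = 1; denominator 4 * 0.01 = 0.04
  d1 <- expression_dataset(cbind(c(0, 0.2, 1, 1.2)), c("A", "A", "B", "B"))
  expect_equal(rank_genes(d1, method = "f_test")$score, 25, tolerance = 1e-12)
  # zero within-class variance with distinct means ranks first as Inf
  d2 <- expression_dataset(cbind(c(1, 1, 2, 2), c(0, 9, 4, 7)),
                           c("A", "A", "B", "B"))
  r2 <- rank_genes(d2, method = "f_test")
  expect_equal(r2$score[1], Inf)
  expect_equal(r2$gene_index[1], 1L)
})

test_that("both filters place a strongly shifted planted gene first", {
  sim <- simulate_expression_dataset(n_samples = 30, n_genes = 40,
                                     n_informative = 1, effect_size = 6,
                                     seed = 13)
  for (m in c("kruskal_wallis", "f_test")) {
    r <- rank_genes(normalize_expression(sim$dataset), method = m)
    expect_equal(r$gene_index[1], sim$informative)
  }
})

test_that("pre-selection follows the floor rule, minimum one, and thresholds", {
  sim <- simulate_expression_dataset(n_samples = 20, n_genes = 200,
                                     n_informative = 3, seed = 4)
  r <- rank_genes(sim$dataset)
  expect_length(preselect(r, "percentage", 0.065), 13L)  # floor(0.065 * 200)
  expect_length(preselect(r, "percentage", 0.1), 20L)
  expect_length(preselect(r, "percentage", 0.0001), 1L)  # never empty
  expect_equal(preselect(r, "percentage", 0.1), r$gene_index[1:20])
  expect_length(preselect(r, "threshold", 1.0), 200L)
  expect_error(preselect(r, "threshold", 1e-300), "relax")
  expect_error(preselect(r, "percentage", 0), "in \\(0, 1]")
})

test_that("ranking is deterministic under score ties", {
  d <- expression_dataset(cbind(c(1, 2, 3, 4), c(1, 2, 3, 4)),
                          c("A", "A", "B", "B"))
  r <- rank_genes(d)
  expect_equal(r$gene_index, c(1L, 2L))  # stable by original index
})
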