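test_that("a widely separated single gene scores perfect LOOCV accuracy", {
  vals <- cbind(c(rep(0, 5), rep(1, 5)) + rnorm(10, sd = 0.01), rnorm(10))
  d <- expression_dataset(vals, rep(c("A", "B"), each = 5))
  ev <- fitness_evaluator(d)
  expect_equal(loocv_accuracy(ev, c(1L, 0L)), 1.0)
})

test_that("repeated evaluation of one mask is bitwise identical", {
  d <- separable_dataset(n_samples = 16, n_genes = 8, shift = 1.5)
  ev <- fitness_evaluator(normalize_expression(d), cache = FALSE)
  mask <- c(1L, 1L, 0L, 1L, 0L, 0L, 1L, 0L)
  a1 <- loocv_accuracy(ev, mask)
  a2 <- loocv_accuracy(ev, mask)
  expect_identical(a1, a2)
  f1 <- mask_fitness(ev, mask)
  f2 <- mask_fitness(ev, mask)
  expect_identical(f1, f2)
})

test_that("all three LOOCV routes match an explicit fold-by-fold oracle", {
  set.seed(9)
  vals <- matrix(rnorm(12), 6, 2)
  vals[4:6, 1] <- vals[4:6, 1] + 1  # deliberately imperfect separation
  d <- expression_dataset(vals, rep(c("A", "B"), each = 3))
  ev <- fitness_evaluator(d)
  mask <- c(1L, 1L)
  # oracle: hand-rolled leave-one-out loop with the same SVM settings
  correct <- vapply(1:6, function(i) {
    fit <- e1071::svm(vals[-i, , drop = FALSE],
                      droplevels(d$labels[-i]), type = "C-classification",
                      kernel = "linear", cost = 2000, scale = FALSE,
                      tolerance = ev$tolerance)
    as.character(predict(fit, vals[i, , drop = FALSE])) ==
      as.character(d$labels[i])
  }, logical(1))
  oracle <- mean(correct)
  expect_equal(loocv_accuracy(ev, mask, "cv"), oracle, tolerance = 1e-15)
  expect_equal(loocv_accuracy(ev, mask, "sv"), oracle, tolerance = 1e-15)
  expect_equal(loocv_accuracy(ev, mask, "fold"), oracle, tolerance = 1e-15)
})

test_that("LOOCV routes agree across random masks on a noisy dataset", {
  set.seed(41)
  d <- separable_dataset(n_samples = 14, n_genes = 10, shift = 1)
  ev <- fitness_evaluator(normalize_expression(d), cache = FALSE)
  for (rep in 1:8) {
    mask <- rep(0L, 10)
    mask[sample(10, sample(1:4, 1))] <- 1L
    acc <- loocv_accuracy(ev, mask, "cv")
    expect_equal(loocv_accuracy(ev, mask, "sv"), acc, tolerance = 1e-15)
    expect_equal(loocv_accuracy(ev, mask, "fold"), acc, tolerance = 1e-15)
    expect_gte(acc, 0)
    expect_lte(acc, 1)
  }
})

test_that("the compiled engine reproduces LIBSVM's leave-one-out answers", {
  # binary, mixed planted/noise masks of the kind the swarm evaluates
  sim <- simulate_expression_dataset(n_samples = 40, n_genes = 30,
                                     n_informative = 3, effect_size = 4,
                                     seed = 23)
  ev <- fitness_evaluator(normalize_expression(sim$dataset), cache = FALSE)
  set.seed(24)
  for (r in 1:12) {
    m <- rep(0L, 30)
    m[unique(c(sample(sim$informative, sample(0:2, 1)),
               sample(30, sample(1:4, 1))))] <- 1L
    if (sum(m) == 0) m[1] <- 1L
    a_compiled <- loocv_accuracy(ev, m, "compiled")
    a_libsvm <- loocv_accuracy(ev, m, "cv")
    # identical answers except on optimizer-degenerate folds, where two
    # exact solvers may sit on different points of the optimal face;
    # that can move at most the odd borderline fold
    expect_lte(abs(a_compiled - a_libsvm), 1 / sim$dataset$n_samples + 1e-9)
  }
  # structured three-class data: exact agreement including the
  # one-versus-one vote
  sim3 <- simulate_expression_dataset(n_samples = 30, n_genes = 20,
                                      n_informative = 3, n_classes = 3,
                                      effect_size = 4, seed = 25)
  ev3 <- fitness_evaluator(normalize_expression(sim3$dataset), cache = FALSE)
  set.seed(26)
  for (r in 1:8) {
    m <- rep(0L, 20)
    m[unique(c(sample(sim3$informative, 2), sample(20, 2)))] <- 1L
    expect_equal(loocv_accuracy(ev3, m, "compiled"),
                 loocv_accuracy(ev3, m, "cv"), tolerance = 1e-12)
  }
})

test_that("fitness combines accuracy and parsimony exactly", {
  # accuracy 1 with every gene selected: parsimony term vanishes -> w1
  vals <- cbind(c(rep(0, 4), rep(1, 4)), c(rep(1, 4), rep(0, 4)))
  d <- expression_dataset(vals, rep(c("A", "B"), each = 4))
  ev <- fitness_evaluator(d, w1 = 0.85)
  expect_equal(mask_fitness(ev, c(1L, 1L))[["fitness"]], 0.85)
  # accuracy 0.9, n = 100, ns = 30 -> 0.85*0.9 + 0.15*0.7 = 0.87
  ev2 <- fitness_arith_evaluator(n_genes = 100)
  mask <- rep(0L, 100); mask[1:30] <- 1L
  out <- mask_fitness(ev2, mask)
  expect_equal(out[["accuracy"]], 0.9)
  expect_equal(out[["fitness"]], 0.87, tolerance = 1e-12)
})

test_that("fitness is monotone: smaller subsets win at equal accuracy", {
  ev <- fitness_arith_evaluator(n_genes = 50)
  m5 <- rep(0L, 50); m5[1:5] <- 1L
  m20 <- rep(0L, 50); m20[1:20] <- 1L
  f5 <- mask_fitness(ev, m5)
  f20 <- mask_fitness(ev, m20)
  expect_equal(f5[["accuracy"]], f20[["accuracy"]])  # filler genes are inert
  expect_gt(f5[["fitness"]], f20[["fitness"]])
  # and fitness matches the closed form given the measured accuracy
  expect_equal(f5[["fitness"]],
               0.85 * f5[["accuracy"]] + 0.15 * (50 - 5) / 50,
               tolerance = 1e-12)
})

test_that("cached and fresh evaluations are identical", {
  d <- separable_dataset(n_samples = 12, n_genes = 6, shift = 2)
  dn <- normalize_expression(d)
  cached <- fitness_evaluator(dn)
  fresh <- fitness_evaluator(dn, cache = FALSE)
  mask <- c(1L, 0L, 1L, 0L, 1L, 0L)
  warm <- mask_fitness(cached, mask)   # populates the cache
  expect_identical(mask_fitness(cached, mask), warm)
  expect_identical(mask_fitness(fresh, mask), warm)
})

test_that("an empty mask is rejected as a caller bug", {
  ev <- fitness_arith_evaluator(n_genes = 10)
  expect_error(loocv_accuracy(ev, rep(0L, 10)), "empty gene mask")
  expect_error(mask_fitness(ev, rep(0L, 10)), "empty gene mask")
})
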