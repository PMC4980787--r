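test_that("the selection sigmoid and mask initialization behave as specified", {
  expect_equal(apiselect:::sigmoid(0), 0.5)
  expect_equal(apiselect:::sigmoid(Inf), 1)
  set.seed(11)
  for (rep in 1:50) {
    expect_gte(sum(init_random_mask(rep(5, 30), alpha = 0.05)), 1L)
  }
})

test_that("empirical init selection rate matches alpha * sigmoid(pheromone)", {
  set.seed(12)
  n <- 2000
  draws <- 100
  bits <- replicate(draws, {
    m <- as.integer(runif(n) < 0.05 * apiselect:::sigmoid(rep(5, n)))
    mean(m)  # raw Bernoulli rate before the never-empty repair
  })
  expected <- 0.05 * apiselect:::sigmoid(5)
  mc_sd <- sqrt(expected * (1 - expected) / (n * draws))
  expect_lt(abs(mean(bits) - expected), 4 * mc_sd)
  # and the packaged initializer with the repair rule stays close too
  rate <- mean(replicate(draws, mean(init_random_mask(rep(5, n), 0.05))))
  expect_lt(abs(rate - expected), 4 * mc_sd + 1 / n)
})

test_that("pheromone deposition follows the update rule and clamps", {
  # unselected gene everywhere: only the inertia term survives
  out <- deposit_pheromone(pheromone = 3, w = 0.5, mask = 0L, fit = 1,
                           pbest = 0L, pbest_fit = 1, gbest = 0L,
                           gbest_fit = 1, c0 = 0.6, tmax = 5, r = c(1, 1, 1))
  expect_equal(out, 1.5)
  # selected everywhere with unit draws and fitnesses: 1 + 0.6 + 0.2 + 0.2
  out2 <- deposit_pheromone(1, w = 1, mask = 1L, fit = 1, pbest = 1L,
                            pbest_fit = 1, gbest = 1L, gbest_fit = 1,
                            c0 = 0.6, tmax = 5, r = c(1, 1, 1))
  expect_equal(out2, 2)
  # exceeding the ceiling lands exactly on tmax
  out3 <- deposit_pheromone(4.9, w = 1, mask = 1L, fit = 1, pbest = 1L,
                            pbest_fit = 1, gbest = 1L, gbest_fit = 1,
                            c0 = 0.6, tmax = 5, r = c(1, 1, 1))
  expect_equal(out3, 5)
  # vectorized over genes with per-gene membership
  out4 <- deposit_pheromone(c(1, 1), w = 1, mask = c(1L, 0L), fit = 0.5,
                            pbest = c(0L, 0L), pbest_fit = 0.5,
                            gbest = c(0L, 0L), gbest_fit = 0.5, c0 = 0.6,
                            tmax = 5, r = c(1, 1, 1))
  expect_equal(out4, c(1.3, 1))
})

test_that("inertia updates decay to zero or stay within the random band", {
  expect_equal(update_inertia(1.4, iter = 20, max_iter = 20, rule = "decay"), 0)
  expect_equal(update_inertia(1.4, 20, 20, "decay", corrected = TRUE), 0.4)
  w1 <- update_inertia(1.4, 1, 20, "decay")
  expect_equal(w1, (1.4 - 0.4) * 19 / 20.4, tolerance = 1e-12)
  set.seed(13)
  ws <- replicate(200, update_inertia(1, 1, 10, "random"))
  expect_true(all(ws >= 0.5 & ws <= 1))
})

test_that("evaporation scales by the retention factor with fixed points", {
  expect_equal(evaporate_pheromone(5, rho = 0.8), 4)
  expect_equal(evaporate_pheromone(c(1, 2, 3), rho = 1), c(1, 2, 3))
  expect_equal(evaporate_pheromone(c(0, 0), rho = 0.5), c(0, 0))
})

test_that("the pheromone ceiling grows exactly on new global bests", {
  expect_equal(update_tmax(5, rho = 0.8, gbest_fit = 1), 9)
  expect_equal(update_tmax(5, rho = 0.8, gbest_fit = 0), 5)
  tm <- 5
  for (g in seq(0.1, 0.9, by = 0.2)) {
    tm2 <- update_tmax(tm, 0.8, g)
    expect_gt(tm2, tm)
    tm <- tm2
  }
})

test_that("communication keeps the predecessor's high-pheromone genes only", {
  set.seed(14)
  n <- 30
  prev <- rep(0L, n); prev[sample(n, 12)] <- 1L
  ph <- runif(n, 0, 5)
  tmax <- 5
  out <- communicate_mask(prev, ph, tmax)
  expect_equal(which(out == 1L),
               intersect(which(prev == 1L), which(ph > tmax / 2)))
  # all pheromones at the ceiling: exact copy
  expect_equal(communicate_mask(prev, rep(tmax, n), tmax), prev)
  # empty predecessor: one repaired gene
  expect_equal(sum(communicate_mask(rep(0L, n), ph, tmax)), 1L)
})

test_that("greedy best-update keeps incumbents on ties and tracks bests", {
  bee <- list(position = c(1L, 0L), fit = 0.5, pbest = c(1L, 0L),
              pbest_fit = 0.6, trial = 3L)
  # strict improvement over pbest: everything replaced, trial reset
  up <- update_best(bee, c(0L, 1L), 0.7, gbest = c(1L, 1L), gbest_fit = 0.65)
  expect_equal(up$bee$position, c(0L, 1L))
  expect_equal(up$bee$pbest_fit, 0.7)
  expect_equal(up$bee$trial, 0L)
  expect_true(up$new_gbest)
  expect_equal(up$gbest, c(0L, 1L))
  # tie with current position: incumbent kept, trial increments
  up2 <- update_best(bee, c(0L, 1L), 0.5, c(1L, 1L), 0.9)
  expect_equal(up2$bee$position, c(1L, 0L))
  expect_equal(up2$bee$trial, 4L)
  expect_false(up2$new_gbest)
  # improvement over position but not pbest
  up3 <- update_best(bee, c(0L, 1L), 0.55, c(1L, 1L), 0.9)
  expect_equal(up3$bee$position, c(0L, 1L))
  expect_equal(up3$bee$pbest_fit, 0.6)
  expect_equal(up3$bee$trial, 4L)
})

test_that("scouts re-initialize every stagnant bee with pheromone bias", {
  d <- separable_dataset(n_samples = 12, n_genes = 8, shift = 3)
  ev <- fitness_evaluator(normalize_expression(d))
  params <- tiny_params(th_n = 1, limit = 2L, ps = 3L)
  mask <- c(1L, rep(0L, 7))
  fit <- mask_fitness(ev, mask)[["fitness"]]
  mk_bee <- function(trial) list(position = mask, fit = fit, pbest = mask,
                                 pbest_fit = fit, trial = trial)
  state <- list(bees = list(mk_bee(2L), mk_bee(0L), mk_bee(5L)),
                field = list(p = rep(5, 8), tmax = 5, tmin = 0),
                gbest = mask, gbest_fit = fit, w = 1)
  set.seed(15)
  out <- apiselect:::scout_phase(state, params, ev)
  expect_equal(out$bees[[1]]$trial, 0L)
  expect_equal(out$bees[[3]]$trial, 0L)
  expect_identical(out$bees[[2]]$position, mask)  # under the limit: untouched
  # biased re-initialization: a lone hot gene dominates scout masks
  set.seed(16)
  hot <- c(5, rep(0, 19))
  picks <- colSums(t(replicate(2000, init_random_mask(hot, 0.05))))
  expect_gt(picks[1], max(picks[-1]))
})

test_that("a full run is reproducible, monotone, and valid at one iteration", {
  d <- separable_dataset(n_samples = 16, n_genes = 20, n_informative = 2,
                         shift = 4)
  p <- tiny_params(th_n = 0.5)
  r1 <- mabc_select(d, params = p, seed = 42)
  r2 <- mabc_select(d, params = p, seed = 42)
  expect_identical(r1$selected_genes, r2$selected_genes)
  expect_identical(r1$fitness, r2$fitness)
  expect_identical(r1$trace, r2$trace)
  expect_true(all(diff(r1$trace$gbest_fitness) >= 0))
  expect_true(all(diff(r1$trace$tmax) >= 0))
  expect_gte(r1$n_selected, 1L)
  expect_gte(r1$accuracy, 0); expect_lte(r1$accuracy, 100)
  r3 <- mabc_select(d, params = tiny_params(th_n = 0.5, max_iter = 1L),
                    seed = 7)
  expect_gte(r3$n_selected, 1L)
  expect_equal(nrow(r3$trace), 1L)
})

test_that("the ablation freezes the pheromone field at its initial level", {
  d <- separable_dataset(n_samples = 16, n_genes = 20, n_informative = 2,
                         shift = 4)
  p <- basic_abc_params(tiny_params(th_n = 0.5))
  r <- mabc_select(d, params = p, seed = 3)
  expect_true(all(r$pheromone_trace$p_min == p$tmax0))
  expect_true(all(r$pheromone_trace$p_max == p$tmax0))
  expect_true(all(r$pheromone_trace$tmax == p$tmax0))
  expect_true(all(diff(r$trace$gbest_fitness) >= 0))
})

test_that("tidiers and the trajectory plot expose the run summary", {
  d <- separable_dataset(n_samples = 12, n_genes = 10, shift = 4)
  r <- mabc_select(d, params = tiny_params(th_n = 0.5), seed = 1)
  td <- tidy(r)
  expect_equal(nrow(td), r$n_selected)
  expect_true(all(c("gene", "gene_index") %in% names(td)))
  gl <- glance(r)
  expect_equal(gl$n_selected, r$n_selected)
  expect_equal(gl$accuracy, r$accuracy)
  pl <- ggplot2::autoplot(r)
  expect_s3_class(pl, "ggplot")
})
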