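# Binary-mask search operators shared by the bee phases. All draws come
# from R's global RNG so a single set.seed() makes whole runs reproducible.

# Pick one gene, probability proportional to pheromone (uniform fallback
# when the field is all-zero), and return a mask selecting only that gene.
repair_mask <- function(mask, pheromone) {
  n <- length(mask)
  prob <- if (sum(pheromone) > 0) pheromone else rep(1, n)
  pick <- sample.int(n, 1L, prob = prob)
  mask[] <- 0L
  mask[pick] <- 1L
  mask
}

#' Neighborhood operator: drop a fraction of the selected genes
#'
#' From a mask with `ns` selected genes, `k = max(1, round(nd * ns))`
#' uniformly chosen selected genes are deselected (round half-up; the rule
#' is pinned by tests). Only deselections occur -- no unselected gene is
#' ever switched on -- except when the incoming mask is empty, in which
#' case a single gene is selected with probability proportional to its
#' pheromone, so a possibly informative gene re-enters the solution.
#'
#' @param mask integer 0/1 vector over genes.
#' @param nd fraction of selected genes to drop, in `(0, 1]`.
#' @param pheromone per-gene pheromone vector (used only for the empty-mask
#'   repair).
#' @return The neighboring mask.
#' @examples
#' set.seed(1)
#' m <- c(0, 1, 1, 0, 1, 0, 0, 1, 1, 0, 1, 1, 1, 0, 0, 1, 0, 1, 0, 0)
#' sum(m) - sum(neighborhood(m, nd = 0.3, pheromone = rep(1, 20)))  # 3
#' @export
neighborhood <- function(mask, nd, pheromone) {
  stopifnot(nd > 0, nd <= 1)
  mask <- as.integer(mask)
  sel <- which(mask == 1L)
  ns <- length(sel)
  if (ns == 0L) {
    return(repair_mask(mask, pheromone))
  }
  k <- max(1L, as.integer(floor(nd * ns + 0.5)))
  k <- min(k, ns)
  drop <- if (ns == 1L) sel else sample(sel, k)
  mask[drop] <- 0L
  mask
}

#' Tweak operator: flip one mask position
#'
#' One position is chosen uniformly at random (or forced via `index`) and
#' its selection state is flipped. Applying the same index twice restores
#' the original mask.
#'
#' @param mask integer 0/1 vector.
#' @param index optional position to flip (1-based); random when `NULL`.
#' @return The tweaked mask, at Hamming distance 1 from the input.
#' @export
tweak <- function(mask, index = NULL) {
  mask <- as.integer(mask)
  if (is.null(index)) {
    index <- sample.int(length(mask), 1L)
  }
  mask[index] <- 1L - mask[index]
  mask
}

#' Local search refinement of a gene mask
#'
#' Three maximization local searches over mask space, all using the tweak
#' operator to generate candidates and all returning the best mask seen:
#'
#' * `"HC"` (hill climbing): for `iterations` rounds tweak the current
#'   mask and adopt the candidate only if its fitness strictly improves.
#' * `"SA"` (simulated annealing): improvements are always accepted;
#'   a worsening candidate is accepted with probability
#'   `exp((f_new - f_cur) / T)`, and the temperature is multiplied by
#'   `schedule` after every round. As the initial temperature approaches
#'   zero this degenerates to hill climbing.
#' * `"SAHCR"` (steepest-ascent hill climbing with replacement): each
#'   round draws `n_tweaks` tweaked candidates of the current mask and
#'   replaces the current mask by the best of them even if it is worse;
#'   the global best is tracked separately.
#'
#' A tweak that empties the mask is repaired immediately by selecting one
#' pheromone-proportional gene, so fitness is never evaluated on an empty
#' mask.
#'
#' @param start starting mask (at least one gene selected).
#' @param evaluator a [fitness_evaluator()].
#' @param method `"HC"`, `"SA"` or `"SAHCR"`.
#' @param iterations number of rounds; 0 returns `start` unchanged.
#' @param n_tweaks candidates per round (SAHCR only).
#' @param schedule multiplicative temperature factor in `(0, 1)` (SA only).
#' @param temperature initial SA temperature, in fitness units.
#' @param pheromone per-gene pheromone vector for empty-mask repair.
#' @return The best mask found (fitness at least that of `start` for HC
#'   and SAHCR).
#' @export
local_search <- function(start, evaluator, method = c("HC", "SA", "SAHCR"),
                         iterations = 10L, n_tweaks = 9L, schedule = 0.5,
                         temperature = 1.0,
                         pheromone = rep(1, length(start))) {
  method <- match.arg(method)
  stopifnot(sum(as.integer(start)) >= 1L)
  if (iterations <= 0L) {
    return(as.integer(start))
  }
  propose <- function(mask) {
    cand <- tweak(mask)
    if (sum(cand) == 0L) cand <- repair_mask(cand, pheromone)
    cand
  }
  current <- as.integer(start)
  cur_fit <- mask_fitness(evaluator, current)[["fitness"]]
  best <- current
  best_fit <- cur_fit
  if (method == "HC") {
    for (it in seq_len(iterations)) {
      cand <- propose(current)
      cand_fit <- mask_fitness(evaluator, cand)[["fitness"]]
      if (cand_fit > cur_fit) {
        current <- cand
        cur_fit <- cand_fit
      }
    }
    return(current)  # monotone: current is the best seen
  }
  if (method == "SA") {
    temp <- temperature
    for (it in seq_len(iterations)) {
      cand <- propose(current)
      cand_fit <- mask_fitness(evaluator, cand)[["fitness"]]
      delta <- cand_fit - cur_fit
      accept <- delta > 0 ||
        (temp > 0 && stats::runif(1) < exp(delta / temp))
      if (accept) {
        current <- cand
        cur_fit <- cand_fit
      }
      if (cur_fit > best_fit) {
        best <- current
        best_fit <- cur_fit
      }
      temp <- temp * schedule
    }
    return(best)
  }
  # SAHCR
  for (it in seq_len(iterations)) {
    round_best <- NULL
    round_fit <- -Inf
    for (tw in seq_len(n_tweaks)) {
      cand <- propose(current)
      cand_fit <- mask_fitness(evaluator, cand)[["fitness"]]
      if (cand_fit > round_fit) {
        round_best <- cand
        round_fit <- cand_fit
      }
    }
    current <- round_best  # replacement: adopt even when worse
    cur_fit <- round_fit
    if (cur_fit > best_fit) {
      best <- current
      best_fit <- cur_fit
    }
  }
  best
}

#' Select a food source (parent bee) by fitness
#'
#' * `"tournament"`: the fittest of `t` bees drawn uniformly with
#'   replacement.
#' * `"fps"` (fitness-proportionate / roulette wheel): index `i` drawn
#'   with probability `f_i / sum(f)`.
#' * `"sus"` (stochastic universal sampling): `n_select` evenly spaced
#'   pointers from a single uniform start select a whole slate in one
#'   pass, so every bee is chosen at least `floor(n_select * f_i / sum(f))`
#'   times (low-variance resampling).
#'
#' An all-zero fitness vector falls back to uniform selection for `"fps"`
#' and `"sus"`.
#'
#' @param fitness numeric vector of non-negative bee fitnesses.
#' @param method `"tournament"`, `"fps"` or `"sus"`.
#' @param t tournament size.
#' @param n_select slate size for `"sus"`.
#' @return One bee index, or an integer vector of `n_select` indices for
#'   `"sus"`.
#' @export
select_parent <- function(fitness, method = c("tournament", "fps", "sus"),
                          t = 5L, n_select = length(fitness)) {
  method <- match.arg(method)
  m <- length(fitness)
  stopifnot(m >= 1L, all(fitness >= 0))
  if (method == "tournament") {
    contenders <- sample.int(m, t, replace = TRUE)
    return(contenders[which.max(fitness[contenders])])
  }
  total <- sum(fitness)
  prob <- if (total > 0) fitness / total else rep(1 / m, m)
  if (method == "fps") {
    return(sample.int(m, 1L, prob = prob))
  }
  # SUS: one random start, n_select equally spaced pointers
  step <- 1 / n_select
  start <- stats::runif(1, 0, step)
  pointers <- start + step * (seq_len(n_select) - 1L)
  cum <- cumsum(prob)
  vapply(pointers, function(p) which(cum >= p - 1e-15)[1], integer(1))
}
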