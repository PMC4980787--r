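# Core swarm loop: employed -> onlooker -> scout phases over binary gene
# masks, with a max-min bounded pheromone field and a communication
# operator between successive employed bees.

sigmoid <- function(x) 1 / (1 + exp(-x))

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Pheromone-biased random mask initialization
#'
#' Each gene `d` is selected independently with probability
#' `alpha * sigmoid(p_d)`, so high-pheromone genes are favored while the
#' expected subset stays small. An all-zero draw is repaired by selecting
#' one gene with probability proportional to its pheromone, so the
#' returned mask is never empty.
#'
#' @param pheromone per-gene pheromone vector.
#' @param alpha selection-probability scale in `[0, 1]`.
#' @return An integer 0/1 mask.
#' @export
init_random_mask <- function(pheromone, alpha = 0.05) {
  n <- length(pheromone)
  mask <- as.integer(stats::runif(n) < alpha * sigmoid(pheromone))
  if (sum(mask) == 0L) {
    mask <- repair_mask(mask, pheromone)
  }
  mask
}

#' Pheromone deposition by one bee
#'
#' Every gene receives
#' `p_d <- p_d * w + r0*c0*f*x_d + r1*c1*pf*pb_d + r2*c2*gf*gb_d`
#' where `x`, `pb`, `gb` are the bee's current, personal-best and
#' global-best masks, `f`, `pf`, `gf` their fitnesses, and `r0, r1, r2`
#' fresh uniform draws shared across genes. The result is clamped to
#' `[tmin, tmax]`.
#'
#' @param pheromone per-gene pheromone vector.
#' @param w inertia weight on the retained pheromone.
#' @param mask,fit bee's current mask and its fitness.
#' @param pbest,pbest_fit bee's personal-best mask and fitness.
#' @param gbest,gbest_fit population's global-best mask and fitness.
#' @param c0 contribution weight of the current position; the personal and
#'   global best each contribute `(1 - c0) / 2`.
#' @param tmax,tmin pheromone bounds.
#' @param r optional length-3 vector of the uniform draws (for tests);
#'   drawn fresh when `NULL`.
#' @return The updated pheromone vector.
#' @export
deposit_pheromone <- function(pheromone, w, mask, fit, pbest, pbest_fit,
                              gbest, gbest_fit, c0, tmax, tmin = 0,
                              r = NULL) {
  if (is.null(r)) {
    r <- stats::runif(3)
  }
  c1 <- (1 - c0) / 2
  p <- pheromone * w +
    r[1] * c0 * fit * mask +
    r[2] * c1 * pbest_fit * pbest +
    r[3] * c1 * gbest_fit * gbest
  clamp(p, tmin, tmax)
}

#' Inertia-weight update
#'
#' `"decay"` shrinks the weight nonlinearly towards zero over the run:
#' `w <- (w - 0.4) * (max_iter - iter) / (max_iter + 0.4)` (set
#' `corrected = TRUE` for the variant
#' `(w - 0.4) * (max_iter - iter) / max_iter + 0.4`, which decays to the
#' floor 0.4 instead of 0). `"random"` redraws `w = (1 + r5) / 2`, always
#' in `[0.5, 1]`.
#'
#' @param w current inertia weight.
#' @param iter current iteration (1-based).
#' @param max_iter total iterations.
#' @param rule `"random"` or `"decay"`.
#' @param corrected use the corrected decay denominator.
#' @return The new inertia weight.
#' @export
update_inertia <- function(w, iter, max_iter, rule = c("random", "decay"),
                           corrected = FALSE) {
  rule <- match.arg(rule)
  if (rule == "random") {
    return((1 + stats::runif(1)) / 2)
  }
  if (corrected) {
    (w - 0.4) * (max_iter - iter) / max_iter + 0.4
  } else {
    (w - 0.4) * (max_iter - iter) / (max_iter + 0.4)
  }
}

#' Pheromone evaporation
#'
#' Multiplies every pheromone by the retention factor `rho` (so `1 - rho`
#' is the evaporation coefficient) and clamps at the lower bound.
#'
#' @param pheromone per-gene pheromone vector.
#' @param rho retention factor in `[0, 1]`.
#' @param tmin lower bound.
#' @return The evaporated pheromone vector.
#' @export
evaporate_pheromone <- function(pheromone, rho, tmin = 0) {
  stopifnot(rho >= 0, rho <= 1)
  pmax(pheromone * rho, tmin)
}

#' Dynamic upper-bound update
#'
#' Called whenever a new global best is found: `tmax <- tmax *
#' (1 + rho * gbest_fit)`, so the field's ceiling grows and frequent genes
#' can keep accumulating evidence instead of saturating.
#'
#' @param tmax current upper bound.
#' @param rho retention factor.
#' @param gbest_fit fitness of the new global best.
#' @return The new upper bound (never smaller than before).
#' @export
update_tmax <- function(tmax, rho, gbest_fit) {
  tmax * (1 + rho * gbest_fit)
}

#' Communication operator: inherit the predecessor's trusted genes
#'
#' Bee `i` replaces its mask by its predecessor's mask gated by the
#' pheromone field: gene `d` stays selected only if it is selected in bee
#' `i - 1` and `p_d > tmax / 2`. An all-zero result is repaired by one
#' pheromone-proportional selection.
#'
#' @param prev_mask mask of bee `i - 1`.
#' @param pheromone per-gene pheromone vector.
#' @param tmax current pheromone upper bound.
#' @return The communicated mask for bee `i`.
#' @export
communicate_mask <- function(prev_mask, pheromone, tmax) {
  mask <- as.integer(prev_mask) * as.integer(pheromone > tmax / 2)
  if (sum(mask) == 0L) {
    mask <- repair_mask(mask, pheromone)
  }
  mask
}

#' Greedy selection and best bookkeeping for one bee
#'
#' The candidate replaces the bee's position only on strict fitness
#' improvement (ties keep the incumbent). The personal best is updated on
#' strict improvement, resetting the stagnation counter; otherwise the
#' counter increments. When the personal best beats the global best, the
#' global best is replaced and the pheromone ceiling grows (see
#' [update_tmax()]).
#'
#' @param bee list with `position`, `fit`, `pbest`, `pbest_fit`, `trial`.
#' @param candidate,candidate_fit evaluated candidate mask.
#' @param gbest,gbest_fit current global best.
#' @return List with updated `bee`, `gbest`, `gbest_fit` and the flag
#'   `new_gbest`.
#' @export
update_best <- function(bee, candidate, candidate_fit, gbest, gbest_fit) {
  if (candidate_fit > bee$fit) {
    bee$position <- candidate
    bee$fit <- candidate_fit
  }
  if (candidate_fit > bee$pbest_fit) {
    bee$pbest <- candidate
    bee$pbest_fit <- candidate_fit
    bee$trial <- 0L
  } else {
    bee$trial <- bee$trial + 1L
  }
  new_gbest <- bee$pbest_fit > gbest_fit
  if (new_gbest) {
    gbest <- bee$pbest
    gbest_fit <- bee$pbest_fit
  }
  list(bee = bee, gbest = gbest, gbest_fit = gbest_fit,
       new_gbest = new_gbest)
}

# --- internal state helpers -------------------------------------------------

new_swarm_state <- function(n, params, evaluator) {
  field <- list(p = rep(params$tmax0, n), tmax = params$tmax0,
                tmin = params$tmin)
  bees <- vector("list", params$ps)
  for (i in seq_len(params$ps)) {
    pos <- init_random_mask(field$p, params$init_alpha)
    fit <- mask_fitness(evaluator, pos)[["fitness"]]
    bees[[i]] <- list(position = pos, fit = fit, pbest = pos,
                      pbest_fit = fit, trial = 0L)
  }
  gi <- which.max(vapply(bees, `[[`, numeric(1), "pbest_fit"))
  list(bees = bees, field = field, gbest = bees[[gi]]$pbest,
       gbest_fit = bees[[gi]]$pbest_fit, w = params$w)
}

maybe_update_tmax <- function(state, params, new_gbest) {
  if (new_gbest && params$use_pheromone) {
    state$field$tmax <- update_tmax(state$field$tmax, params$rho,
                                    state$gbest_fit)
  }
  state
}

apply_local_search <- function(mask, state, params, evaluator, method) {
  iterations <- switch(method, HC = params$hc_iter, SA = params$sa_iter,
                       SAHCR = params$sahc_iter)
  local_search(mask, evaluator, method = method, iterations = iterations,
               n_tweaks = params$sahc_tweak, schedule = params$schedule,
               temperature = params$sa_temperature,
               pheromone = state$field$p)
}

stage_deposit <- function(state, params) {
  if (!params$use_pheromone) {
    return(state)
  }
  for (i in seq_len(params$ps)) {
    b <- state$bees[[i]]
    state$field$p <- deposit_pheromone(
      state$field$p, state$w, b$position, b$fit, b$pbest, b$pbest_fit,
      state$gbest, state$gbest_fit, params$c0,
      tmax = state$field$tmax, tmin = state$field$tmin)
  }
  state
}

employed_phase <- function(state, params, evaluator) {
  for (i in seq_len(params$ps)) {
    bee <- state$bees[[i]]
    if (params$use_communication && i > 1L &&
        stats::runif(1) < params$r4) {
      comm <- communicate_mask(state$bees[[i - 1L]]$position,
                               state$field$p, state$field$tmax)
      bee$position <- comm
      bee$fit <- mask_fitness(evaluator, comm)[["fitness"]]
    }
    neighbor <- neighborhood(bee$position, params$nd, state$field$p)
    if (sum(neighbor) == 0L) {  # a 1-gene mask was emptied: repair
      neighbor <- repair_mask(neighbor, state$field$p)
    }
    if (stats::runif(1) < params$prob_ls) {
      neighbor <- apply_local_search(neighbor, state, params, evaluator,
                                     params$ls_e)
    }
    nfit <- mask_fitness(evaluator, neighbor)[["fitness"]]
    upd <- update_best(bee, neighbor, nfit, state$gbest, state$gbest_fit)
    state$bees[[i]] <- upd$bee
    state$gbest <- upd$gbest
    state$gbest_fit <- upd$gbest_fit
    state <- maybe_update_tmax(state, params, upd$new_gbest)
  }
  stage_deposit(state, params)
}

onlooker_phase <- function(state, params, evaluator) {
  fits <- vapply(state$bees, `[[`, numeric(1), "fit")
  sources <- if (params$selection == "sus") {
    select_parent(fits, "sus", n_select = params$ps)
  } else {
    vapply(seq_len(params$ps), function(k) {
      select_parent(fits, params$selection, t = params$t)
    }, integer(1))
  }
  for (k in seq_len(params$ps)) {
    i <- sources[k]
    bee <- state$bees[[i]]
    neighbor <- neighborhood(bee$position, params$nd, state$field$p)
    if (sum(neighbor) == 0L) {  # a 1-gene mask was emptied: repair
      neighbor <- repair_mask(neighbor, state$field$p)
    }
    if (stats::runif(1) < params$prob_ls) {
      neighbor <- apply_local_search(neighbor, state, params, evaluator,
                                     params$ls_o)
    }
    nfit <- mask_fitness(evaluator, neighbor)[["fitness"]]
    upd <- update_best(bee, neighbor, nfit, state$gbest, state$gbest_fit)
    state$bees[[i]] <- upd$bee
    state$gbest <- upd$gbest
    state$gbest_fit <- upd$gbest_fit
    state <- maybe_update_tmax(state, params, upd$new_gbest)
  }
  stage_deposit(state, params)
}

scout_phase <- function(state, params, evaluator) {
  for (i in seq_len(params$ps)) {  # no one-scout-per-cycle restriction
    if (state$bees[[i]]$trial >= params$limit) {
      pos <- init_random_mask(state$field$p, params$init_alpha)
      fit <- mask_fitness(evaluator, pos)[["fitness"]]
      bee <- state$bees[[i]]
      bee$position <- pos
      bee$fit <- fit
      bee$trial <- 0L
      upd <- update_best(bee, pos, fit, state$gbest, state$gbest_fit)
      upd$bee$trial <- 0L  # re-initialization itself is not stagnation
      state$bees[[i]] <- upd$bee
      state$gbest <- upd$gbest
      state$gbest_fit <- upd$gbest_fit
      state <- maybe_update_tmax(state, params, upd$new_gbest)
    }
  }
  stage_deposit(state, params)
}

run_mabc_search <- function(evaluator, params, seed) {
  set.seed(seed)
  n <- evaluator$n_genes
  state <- new_swarm_state(n, params, evaluator)
  trace <- vector("list", params$max_iter)
  pher_rows <- vector("list", params$max_iter)
  for (iter in seq_len(params$max_iter)) {
    stage_bounds <- function(stage) {
      tibble::tibble(iteration = iter, stage = stage,
                     p_min = min(state$field$p), p_max = max(state$field$p),
                     tmax = state$field$tmax)
    }
    state <- employed_phase(state, params, evaluator)
    b_emp <- stage_bounds("employed")
    state <- onlooker_phase(state, params, evaluator)
    b_onl <- stage_bounds("onlooker")
    state <- scout_phase(state, params, evaluator)
    b_sct <- stage_bounds("scout")
    if (params$use_pheromone) {
      state$field$p <- evaporate_pheromone(state$field$p, params$rho,
                                           state$field$tmin)
    }
    b_evp <- stage_bounds("evaporate")
    state$w <- update_inertia(state$w, iter, params$max_iter,
                              rule = params$wt_rule,
                              corrected = params$wt_decay_corrected)
    trace[[iter]] <- tibble::tibble(
      iteration = iter,
      gbest_fitness = state$gbest_fit,
      gbest_size = sum(state$gbest),
      tmax = state$field$tmax,
      inertia = state$w
    )
    pher_rows[[iter]] <- dplyr::bind_rows(b_emp, b_onl, b_sct, b_evp)
  }
  list(gbest = state$gbest, gbest_fit = state$gbest_fit,
       trace = dplyr::bind_rows(trace),
       pheromone_trace = dplyr::bind_rows(pher_rows))
}
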