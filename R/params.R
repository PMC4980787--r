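#' Search parameters for the modified bee colony
#'
#' Constructs and validates the full parameter set of the search. Defaults
#' are the tuned setting of the method (see [mabc_preset()] for the
#' alternatives). The pheromone contribution weights satisfy
#' `c0 + c1 + c2 = 1` with `c1 = c2 = (1 - c0) / 2`, so the personal and
#' global bests influence deposition equally.
#'
#' @param prob_ls probability of refining a neighbor by local search.
#' @param rho pheromone retention factor in `[0, 1]`; `1 - rho` is the
#'   evaporation coefficient.
#' @param w initial inertia weight on retained pheromone.
#' @param w1 accuracy/parsimony trade-off of the fitness (see
#'   [fitness_evaluator()]).
#' @param th_n fraction of ranked genes kept by the prefilter.
#' @param c0 deposition weight of a bee's current position.
#' @param max_iter number of swarm iterations.
#' @param limit stagnation threshold turning a bee into a scout.
#' @param nd fraction of selected genes dropped by the neighborhood
#'   operator.
#' @param ps population size (number of employed bees = onlookers).
#' @param r4 probability of applying the communication operator to an
#'   employed bee.
#' @param t tournament size.
#' @param schedule simulated-annealing cooling factor in `(0, 1)`.
#' @param sa_iter,hc_iter,sahc_iter local-search round counts for SA, HC
#'   and SAHCR.
#' @param sahc_tweak tweaks per SAHCR round.
#' @param sa_temperature initial SA temperature, in fitness units.
#' @param tmax0 initial pheromone level and initial upper bound.
#' @param tmin fixed pheromone lower bound.
#' @param init_alpha scale of the sigmoid selection probability used when
#'   (re)initializing a bee: gene `d` is selected with probability
#'   `init_alpha * sigmoid(p_d)`. The default 0.05 makes the expected
#'   initial subset about 5 percent of the searched genes.
#' @param ls_e,ls_o local-search method (`"HC"`, `"SA"`, `"SAHCR"`) for the
#'   employed and the onlooker stage.
#' @param selection parent-selection scheme for onlookers
#'   (`"tournament"`, `"fps"`, `"sus"`).
#' @param wt_rule inertia update rule: `"random"` draws
#'   `w = (1 + r5) / 2` each iteration; `"decay"` applies the nonlinear
#'   decay `w <- (w - 0.4) * (max_iter - iter) / (max_iter + 0.4)`.
#' @param wt_decay_corrected use the corrected decay denominator
#'   `(w - 0.4) * (max_iter - iter) / max_iter + 0.4` instead of the form
#'   above (whose `+ 0.4` in the denominator is most likely a typographic
#'   slip, but which is kept as the default for fidelity).
#' @param kernel,cost,gamma SVM settings (see [fitness_evaluator()]).
#' @param prefilter ranking method, `"kruskal_wallis"` or `"f_test"`.
#' @param use_pheromone enable pheromone deposition, evaporation and the
#'   dynamic upper bound. `FALSE` freezes the field at `tmax0`, making
#'   scout re-initialization uniform.
#' @param use_communication enable the communication operator. `FALSE` is
#'   equivalent to `r4 = 0`.
#' @param uph accepted for config-file compatibility and ignored.
#' @return A validated list of class `mabc_params`.
#' @seealso [mabc_preset()], [mabc_select()]
#' @export
mabc_params <- function(prob_ls = 0.7, rho = 0.8, w = 1.4, w1 = 0.85,
                        th_n = 0.065, c0 = 0.6, max_iter = 20L, limit = 35L,
                        nd = 0.035, ps = 25L, r4 = 0.5, t = 5L,
                        schedule = 0.5, sa_iter = 14L, hc_iter = 10L,
                        sahc_iter = 12L, sahc_tweak = 9L,
                        sa_temperature = 1.0, tmax0 = 5, tmin = 0,
                        init_alpha = 0.05,
                        ls_e = c("SA", "HC", "SAHCR"),
                        ls_o = c("SAHCR", "HC", "SA"),
                        selection = c("tournament", "fps", "sus"),
                        wt_rule = c("random", "decay"),
                        wt_decay_corrected = FALSE,
                        kernel = c("linear", "radial"),
                        cost = 2000, gamma = 1e-4,
                        prefilter = c("kruskal_wallis", "f_test"),
                        use_pheromone = TRUE, use_communication = TRUE,
                        uph = TRUE) {
  p <- list(
    prob_ls = prob_ls, rho = rho, w = w, w1 = w1, th_n = th_n,
    c0 = c0, c1 = (1 - c0) / 2, max_iter = as.integer(max_iter),
    limit = as.integer(limit), nd = nd, ps = as.integer(ps), r4 = r4,
    t = as.integer(t), schedule = schedule, sa_iter = as.integer(sa_iter),
    hc_iter = as.integer(hc_iter), sahc_iter = as.integer(sahc_iter),
    sahc_tweak = as.integer(sahc_tweak), sa_temperature = sa_temperature,
    tmax0 = tmax0, tmin = tmin, init_alpha = init_alpha,
    ls_e = match.arg(ls_e), ls_o = match.arg(ls_o),
    selection = match.arg(selection), wt_rule = match.arg(wt_rule),
    wt_decay_corrected = isTRUE(wt_decay_corrected),
    kernel = match.arg(kernel), cost = cost, gamma = gamma,
    prefilter = match.arg(prefilter),
    use_pheromone = isTRUE(use_pheromone),
    use_communication = isTRUE(use_communication)
  )
  unit <- c("prob_ls", "rho", "w1", "th_n", "nd", "r4", "c0", "init_alpha")
  for (nm in unit) {
    if (p[[nm]] < 0 || p[[nm]] > 1) {
      stop("`", nm, "` must lie in [0, 1]", call. = FALSE)
    }
  }
  if (p$ps < 2L) stop("`ps` must be at least 2", call. = FALSE)
  if (p$max_iter < 1L) stop("`max_iter` must be at least 1", call. = FALSE)
  if (p$limit < 1L) stop("`limit` must be at least 1", call. = FALSE)
  if (p$schedule <= 0 || p$schedule >= 1) {
    stop("`schedule` must lie in (0, 1)", call. = FALSE)
  }
  if (p$tmax0 <= p$tmin) stop("`tmax0` must exceed `tmin`", call. = FALSE)
  class(p) <- "mabc_params"
  p
}

#' Named parameter presets
#'
#' Three tuned settings are shipped. `"first"` (the default, also
#' reachable as `"default"`) is the recommended all-round setting;
#' `"second"` trades local-search probability for speed with a larger
#' population; `"third"` keeps the heavy local search everywhere and
#' switches onlooker selection to stochastic universal sampling.
#'
#' @param name `"first"`/`"default"`, `"second"` or `"third"`.
#' @param ... overrides forwarded to [mabc_params()].
#' @return A `mabc_params` object.
#' @export
mabc_preset <- function(name = c("first", "default", "second", "third"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    first = ,
    default = list(),
    second = list(prob_ls = 0.4, th_n = 0.03, sahc_iter = 16L,
                  sahc_tweak = 15L, hc_iter = 10L, c0 = 0.5, limit = 100L,
                  nd = 0.02, ps = 40L, r4 = 0.7, ls_e = "HC",
                  ls_o = "SAHCR", selection = "tournament"),
    third = list(prob_ls = 0.7, th_n = 0.03, sahc_iter = 16L,
                 sahc_tweak = 15L, c0 = 0.5, limit = 100L, nd = 0.035,
                 ps = 40L, r4 = 0.7, ls_e = "SAHCR", ls_o = "SAHCR",
                 selection = "sus")
  )
  do.call(mabc_params, utils::modifyList(base, list(...)))
}

#' Basic bee-colony ablation of a parameter set
#'
#' Disables the two additions that distinguish the modified search from a
#' basic artificial bee colony with local search: the pheromone field
#' (deposition, evaporation, dynamic upper bound, biased scouting) and the
#' communication operator. Everything else -- phases, neighborhood, local
#' search, greedy selection, scouts -- is untouched, so comparisons
#' against this ablation isolate the contribution of the two components.
#'
#' @param params a `mabc_params` object.
#' @return The ablated `mabc_params`.
#' @export
basic_abc_params <- function(params = mabc_params()) {
  stopifnot(inherits(params, "mabc_params"))
  params$use_pheromone <- FALSE
  params$use_communication <- FALSE
  params
}

#' @export
print.mabc_params <- function(x, ...) {
  cat("<mabc_params>\n")
  flat <- vapply(x, function(v) paste(format(v), collapse = ","), character(1))
  cat(paste0("  ", format(names(flat)), " = ", flat, collapse = "\n"), "\n")
  invisible(x)
}
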