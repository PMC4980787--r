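---
title: "Pheromone-guided bee-colony gene selection: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pheromone-guided bee-colony gene selection: models, parameters, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apiselect)
```

## The problem

A labelled expression matrix has `N` samples (tissues, patients) in rows
and `n` genes in columns, with `n` in the thousands and `N` rarely above a
few hundred. Only a small fraction of genes carries class information;
the rest add noise that degrades any classifier trained on all of them.
`apiselect` searches for a *minimal* gene subset that *maximally*
discriminates the classes — a wrapper feature selection: candidate
subsets are scored by the classifier they are meant to serve.

Exhaustive subset search is hopeless (the problem is NP-hard), so the
package combines three stages:

1. **Prefilter.** Univariate ranking (Kruskal-Wallis rank-sum or Fisher
   score) discards the bulk of uninformative genes; only the top `th_n`
   fraction enters the search.
2. **Swarm search.** A modified artificial bee colony explores binary
   masks over the surviving genes. Two additions distinguish it from the
   basic colony: a per-gene *pheromone* field with max-min bounds
   (memory of genes that appeared in good subsets) and a *communication
   operator* (a bee inherits its predecessor's trusted genes).
3. **Fitness.** Leave-one-out cross-validated SVM accuracy, blended with
   a parsimony reward:
   `fitness = w1 * accuracy + (1 - w1) * (n - ns) / n`.

## Models and update rules

**Normalization.** Each gene is affinely mapped so its minimum is 0 and
its maximum 1, giving genes equal footing in the kernel. A constant gene
maps to all zeros — the ratio is undefined there, and such genes are
uninformative by construction.

**Kruskal-Wallis.** Mid-ranks over all samples; the statistic
`K = 12 / (N(N+1)) * sum_k n_k (rbar_k - (N+1)/2)^2` is divided by the
tie-correction factor `1 - sum_j (t_j^3 - t_j) / (N^3 - N)` whenever ties
occur, and `p = Pr(chi^2_{C-1} >= K)`. Genes are ranked by ascending p.
A gene whose observations are all identical is assigned `K = 0, p = 1`
(no evidence against the null) instead of the undefined `0/0`.

**Fisher score.** `F = sum_k n_k (mu_k - mu)^2 / sum_k n_k sigma_k^2`
with the *population* standard-deviation convention, so the denominator
is exactly the pooled within-class sum of squared deviations. Zero
within-class variance with distinct class means yields `Inf` (ranked
first); the doubly degenerate case yields 0.

**Pheromone dynamics.** All genes start at `tmax0`. After each bee
stage, every bee deposits
`p_d <- p_d * w + r0 c0 f x_d + r1 c1 pf pb_d + r2 c2 gf gb_d`
(current mask, personal best, global best; `c0 + c1 + c2 = 1`,
`c1 = c2`), clamped to `[tmin, tmax]`. At the end of each iteration the
field evaporates by the retention factor `rho`. The ceiling is dynamic:
whenever a new global best appears, `tmax <- tmax * (1 + rho * gf)`, so
frequently selected genes can keep accumulating evidence rather than
saturating. The inertia weight `w` is redrawn as `(1 + r5)/2` each
iteration by default (`wt_rule = "random"`); the alternative `"decay"`
rule shrinks it nonlinearly to zero over the run. The decay rule is
implemented exactly as printed in its source, including the `+ 0.4`
denominator term that is most likely a typographic slip; the corrected
variant (decaying to a floor of 0.4) is available via
`wt_decay_corrected = TRUE`. We default to the random rule because the
tuned parameter tables leave the choice ambiguous; this is a documented
guess, not a tuned result.

**Communication.** With probability `r4`, employed bee `i > 1` replaces
its mask by its predecessor's mask gated at `p_d > tmax / 2`. This
shares discoveries along the chain of bees while the pheromone threshold
filters out genes that have not earned trust.

**Phases.** Employed bees: optional communication, one neighborhood
move (drop `max(1, round(nd * ns))` selected genes — the operator only
ever deselects, except that an empty mask is repaired by one
pheromone-proportional selection), optional local search with
probability `prob_ls`, then greedy selection (ties keep the incumbent —
"greedy" means strict improvement). Onlookers: a source bee is chosen by
tournament (with replacement), roulette wheel, or stochastic universal
sampling, then the same move/refine/select cycle. Scouts: any bee whose
personal best has stagnated `limit` times abandons its position and
re-initializes through the pheromone-biased sigmoid rule
(`P(select d) = alpha * sigmoid(p_d)`); several bees may scout in one
iteration. A scout keeps its personal-best memory: the global best must
never regress, and the personal best continues to feed deposition.

**Local searches.** Hill climbing (adopt strictly improving tweaks),
simulated annealing (accept worsenings with probability
`exp(delta / T)`, `T` multiplied by `schedule` each round, initial
temperature 1 in fitness units — the schedule was specified without a
starting temperature, so unit scale on a fitness in [0, 1] is the
natural choice), and steepest-ascent hill climbing with replacement
(best of `sahc_tweak` tweaks replaces the current mask even when worse;
the best-ever mask is tracked separately). All three return the best
mask seen. With the initial temperature at zero, the annealer provably
walks the hill-climber's exact trajectory — a property the tests pin.

**Fitness.** Accuracy enters as a fraction, so fitness lives in [0, 1];
user-facing reports convert accuracy to percent. The evaluator caches
results by mask bit-pattern: leave-one-out dominates runtime and the
swarm revisits masks heavily. Caching is observationally transparent
because evaluation is deterministic. An all-zero mask is a hard error
by design — each operator repairs empty masks before evaluation, and a
silent repair inside the evaluator would mask operator bugs.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `th_n` | 0.065 | fraction of ranked genes kept by the prefilter |
| `prob_ls` | 0.7 | probability of local-search refinement |
| `rho` | 0.8 | pheromone retention (1 − rho evaporates) |
| `w` | 1.4 | initial inertia weight |
| `w1` | 0.85 | accuracy weight in the fitness blend |
| `c0` | 0.6 | deposition weight of the current position |
| `max_iter` | 20 | swarm iterations |
| `limit` | 35 | stagnation threshold before scouting |
| `nd` | 0.035 | fraction of selected genes dropped per neighborhood move |
| `ps` | 25 | bees per phase |
| `r4` | 0.5 | communication probability |
| `t` | 5 | tournament size |
| `sa_iter` / `hc_iter` | 14 / 10 | annealing / hill-climbing rounds |
| `sahc_iter`, `sahc_tweak` | 12, 9 | steepest-ascent rounds and tweaks per round |
| `schedule` | 0.5 | annealing cooling factor |
| `tmax0`, `tmin` | 5, 0 | initial ceiling and fixed floor of the field |
| `init_alpha` | 0.05 | sigmoid scale at (re)initialization |
| `cost`, `gamma` | 2000, 1e-4 | SVM penalty and radial width (gamma unused for linear) |

`mabc_preset()` ships three tuned settings: `"first"` (the default,
above), `"second"` (lighter local search, larger population), and
`"third"` (heavy steepest-ascent everywhere, stochastic universal
sampling). Two published values disagree across their sources: the
annealing round count (14 in one table, 10 in another — we default to
14) and the tournament size (prose says 7, the table says 5 — we default
to 5). The config key `uph` is accepted and ignored; it appears in the
published parameter tables without a definition anywhere in the text.
`init_alpha = 0.05` makes the expected initial subset about 5 % of the
searched genes; the sigmoid keeps masks sparse while still favoring
high-pheromone genes during scouting.

## The SVM evaluator

The classifier is the soft-margin C-SVM with `C = 2000`, `gamma = 1e-4`,
linear kernel, one-versus-one for multi-class, and no class weighting
(class imbalance handling was never specified; we document rather than
invent). A wrapper search evaluates tens of thousands of masks per run
and leave-one-out multiplies every evaluation by `N`, so the package
ships a compiled leave-one-out engine for the linear kernel
(`src/loocv.cpp`) and uses LIBSVM via `e1071` both for the radial kernel
and as the independent reference the engine is tested against.

The compiled engine solves the identical dual program — equality
constraint, box `[0, C]`, LIBSVM's stopping rule (`tolerance`, default
0.001, the LIBSVM default) and its bias rule — and gets its speed from
structure, not approximation:

* the kernel matrix over all samples is computed once per mask, and each
  fold warm-starts from the full-data dual solution with the held-out
  point's weight redistributed, so most folds converge in a handful of
  SMO steps (second-order working-set selection, as in LIBSVM);
* a fold whose held-out sample has zero dual weight is skipped outright:
  removing a non-support-vector provably leaves the solution unchanged,
  and such a point lies outside the margin on its own side, so its
  prediction is correct by construction;
* subsets of pure noise genes make SMO pathological — with heavily
  overlapping classes and a large `C` it zigzags for tens of thousands
  of iterations. Solves that hit an iteration cap are handed to a
  primal-dual interior-point solver for the same QP, whose iteration
  count is small and insensitive to `C`; the linear kernel's low rank
  keeps each interior-point step at `O(N k^2)` via the Woodbury
  identity. Switching solvers is purely about speed: both solve the same
  convex program.

Three e1071-based routes remain available in `loocv_accuracy()` as
cross-checks: LIBSVM's internal cross-validation with the fold count
equal to `N` (no stratification or shuffling exists in that special
case, so it is deterministic), the support-vector shortcut, and an
explicit fold loop. Tests pin the compiled engine to LIBSVM's answers:
exactly on structured (class-separated) data including three-class
one-versus-one voting, and to within a single fold on arbitrary masks —
on degenerate noise subsets the dual optimum is a face rather than a
point and the bias an interval rather than a value, so two exact solvers
may legitimately disagree on an odd borderline fold.

One more reproducibility guard: `e1071::svm(cross = N)` draws from R's
global RNG for an immaterial fold shuffle. Evaluations save and restore
the RNG state so that cached and fresh evaluations never perturb the
search's random stream — without this, memoization would silently change
swarm trajectories.

## The synthetic benchmark

`simulate_expression_dataset()` plants `n_informative` genes whose class
means are separated by `effect_size` noise standard deviations inside an
otherwise pure-Gaussian matrix. The defaults — 60 samples, 500 genes, 5
planted genes at 4 SDs, two balanced classes — are the package's
acceptance conditions: small enough to run on a laptop, hard enough that
single genes do not reliably reach perfect accuracy (a 4-SD shift leaves
each sample a ~2 % per-fold error chance with one gene, vanishing with
two or more). Binary classes are the simplest realistic tumor-vs-normal
layout; the generator supports more via `n_classes`.

What the generator deliberately does **not** emulate: heavy-tailed and
platform-specific intensity distributions, probe-level artifacts,
correlated gene modules, and batch effects. Passing the planted-gene
recovery tests therefore demonstrates that the search machinery works —
prefilter, pheromone dynamics, communication, local search, evaluation —
not that any particular microarray study will yield biologically valid
genes. Real-data claims need real data (`read_expression_dataset()`
accepts the delimited and MATLAB matrix layouts such collections use).

`run_gene_selection_experiment()` aggregates independently seeded runs
(`seed + run - 1`, recorded per run) into best / average / SD / worst
for accuracy and subset size, the customary reporting columns, and can
run the `basic_abc` ablation — pheromone and communication disabled,
everything else identical — to isolate the contribution of the two
additions.

## Numerical and degenerate-case decisions

* Drop count in the neighborhood move: `max(1, round(nd * ns))` with
  round-half-up, pinned by tests (the worked example is consistent with
  floor, round, and ceiling; a rule had to be fixed).
* Ranking ties (equal p or F): stable order by original gene index, so
  runs are bit-reproducible.
* Threshold pre-selection keeps `p <= threshold`, so a threshold of 1
  keeps every gene.
* An all-zero fitness vector in roulette-wheel or universal sampling
  falls back to uniform selection.
* The tweak operator may empty a mask; every consumer repairs by one
  pheromone-proportional selection before evaluation.
* Greedy ties keep the incumbent; the stagnation counter increments on
  every non-improving candidate (employed and onlooker phases can each
  touch a bee once per iteration).
* Reaching 100 % accuracy is not a stopping rule — later iterations can
  find a smaller subset at the same accuracy; the run always executes
  `max_iter` iterations.

## Problem sizes used by the tests and the acceptance script

Unit tests run on 10–40-sample fixtures built in code. The acceptance
tests run the full tuned setting on a 60 × 200 dataset (pheromone
invariants, 5 runs) and on the 60 × 500 planted-gene benchmark (15 runs
of the modified search and 15 of the basic-colony ablation, sharing one
deterministic evaluation cache). The acceptance script runs 5 seeded
runs per arm on the same benchmark — enough for stable best/average
summaries at script scale; the 15-run protocol lives in the test suite.

## Known limitations

* The fitness is a single scalar blend; no Pareto view of the
  accuracy-size trade-off.
* Leave-one-out is the only supported protocol (by design — it is
  deterministic and the method's prescription); k-fold variants are out
  of scope.
* The prefilter is univariate: a gene informative only through
  interactions can be discarded before the search sees it.
* Search cost is dominated by SVM evaluations on noise-heavy masks;
  runtime on real multi-thousand-gene datasets depends mostly on `th_n`,
  `ps`, and the local-search intensity.
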