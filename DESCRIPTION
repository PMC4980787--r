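Package: apiselect
Title: Gene Subset Selection with a Pheromone-Guided Artificial Bee Colony
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Wrapper feature selection for labeled gene-expression matrices.
    Genes are first ranked by a Kruskal-Wallis rank-sum test (with tie
    correction) or by the Fisher score and pre-selected by a top fraction;
    the surviving genes are then searched by a modified artificial bee
    colony: a binary-mask swarm with per-gene pheromone trails bounded by
    max-min limits, a communication operator between successive bees, and
    hill-climbing, simulated-annealing or steepest-ascent local search.
    Candidate subsets are scored by leave-one-out cross-validated support
    vector machine accuracy combined with a parsimony reward for small
    subsets. Includes a synthetic benchmark generator with planted
    class-informative genes, seeded experiment aggregation against a basic
    bee-colony ablation, broom-style tidiers and ggplot2 plotting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    Rcpp,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
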