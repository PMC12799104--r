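Package: treerug
Title: Diagnosing Rugged Tree Landscapes in Bayesian Phylodynamic MCMC
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Convergence and mixing diagnostics for posterior samples of
    dated phylogenies from Bayesian phylodynamic analyses. Provides tree-,
    clade-, site- and branch-level MCMC diagnostics (effective sample size,
    potential scale reduction factor, standard deviation of clade
    frequencies), model-independent parsimony-score diagnostics with
    mutation mapping, multidimensional-scaling visualization of posterior
    tree space with posterior-density overlays, tip-relocation (SPR/NNI)
    valley geometry, problematic-tip ranking and pruning with re-diagnosis,
    root-to-tip regression screening, and a synthetic multimodal-posterior
    generator for validating the whole workflow at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    coda,
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
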