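Package: vcellevo
Title: Evolutionary Simulation of Virtual Cells with Whole-Genome Duplication
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An agent-based evolutionary simulator of virtual cells whose
    circular genomes encode transcription factors, metabolic enzymes and
    resource pumps wired into a gene regulatory network by discrete
    binding-motif matching. Intracellular resource and energy dynamics are
    integrated as ordinary differential equations; fitness rewards
    homeostasis of internal concentrations under fluctuating external
    resource. Populations evolve by fitness-proportional reproduction under
    point mutations, segmental duplications, deletions, translocations and
    whole-genome duplication (WGD). The package includes the full post-WGD
    analysis suite: line-of-descent tracing with exact mutation-event
    replay, ancestral gene-content conservation, effective mutation rates
    in generation bins, ohnolog/single classification, uniform and
    connectivity-binned random-deletion null models, binding-site
    conservation and relative-outdegree statistics, and rank-sum group
    comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    deSolve,
    jsonlite
Config/testthat/edition: 3
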