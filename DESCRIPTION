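Package: icilogic
Title: Logical Modelling of T-Cell Activation Under Immune-Checkpoint
    Control
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Boolean-network modelling of T-cell receptor signalling under
    co-stimulatory and co-inhibitory immune checkpoints. Provides a rule
    language and parser for logical models, exact analysis of asynchronous
    dynamics (successor states, fixed points, attractors, and a uniformized
    continuous-time Markov-chain solver for small networks), a Gillespie
    engine for stochastic ensembles with phenotype read-outs, a curated
    T-cell activation network covering PD1, CTLA4, TIGIT, LAG3, TIM3,
    CD226, ICOS and TNFR checkpoints, scenario protocols reproducing
    single-checkpoint panels, two-step lymph-node/tumour activation,
    checkpoint-inhibitor treatments and cytokine modulation, and random
    Boolean-network generators for engine validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    yaml,
    jsonlite,
    Rcpp,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
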