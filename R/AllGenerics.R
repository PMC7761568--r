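#' Node names of a network
#' @param x A [BooleanNetwork][BooleanNetwork-class].
#' @return Character vector of node names in declaration order.
#' @export
setGeneric("nodeNames", function(x) standardGeneric("nodeNames"))

#' Node role annotations
#' @param x A [BooleanNetwork][BooleanNetwork-class].
#' @return Named character vector (`input`/`internal`/`phenotype`).
#' @export
setGeneric("nodeKinds", function(x) standardGeneric("nodeKinds"))

#' Update rules of a network
#' @param x A [BooleanNetwork][BooleanNetwork-class].
#' @return Named list of parsed rule expressions.
#' @export
setGeneric("networkRules", function(x) standardGeneric("networkRules"))

#' Marginal node probabilities of an ensemble
#' @param x A [TrajectoryEnsemble][TrajectoryEnsemble-class].
#' @return Numeric matrix, nodes by time-grid points.
#' @export
setGeneric("marginals", function(x) standardGeneric("marginals"))

#' Joint phenotype-category probabilities of an ensemble
#' @param x A [TrajectoryEnsemble][TrajectoryEnsemble-class].
#' @return Numeric matrix, categories by time-grid points.
#' @export
setGeneric("phenotypeJoint", function(x) standardGeneric("phenotypeJoint"))

#' Phenotype category probabilities
#' @param x A [PhenotypeDistribution][PhenotypeDistribution-class].
#' @return Named numeric vector summing to 1.
#' @export
setGeneric("categoryProbs", function(x) standardGeneric("categoryProbs"))

#' Phenotype marginal probabilities
#' @param x A [PhenotypeDistribution][PhenotypeDistribution-class].
#' @return Named numeric vector of per-phenotype marginals.
#' @export
setGeneric("phenotypeMarginals",
           function(x) standardGeneric("phenotypeMarginals"))

#' Convergence flag of an asymptotic read-out
#' @param x A [PhenotypeDistribution][PhenotypeDistribution-class].
#' @return Logical.
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))

#' Scenario verdict table
#' @param x A [ScenarioResult][ScenarioResult-class].
#' @return Data frame of directional comparisons with PASS/FAIL outcomes.
#' @export
setGeneric("verdicts", function(x) standardGeneric("verdicts"))

#' Scenario derived statistics
#' @param x A [ScenarioResult][ScenarioResult-class].
#' @return Data frame of derived statistics.
#' @export
setGeneric("scenarioStats", function(x) standardGeneric("scenarioStats"))
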