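#' @import methods
#' @importFrom stats setNames
NULL

#' Boolean network of named nodes with logical update rules
#'
#' A `BooleanNetwork` holds an ordered set of named nodes, one parsed logical
#' update rule per node, and a role annotation (`input`, `internal` or
#' `phenotype`) for each node. Input nodes carry the identity rule, so their
#' value is constant along any trajectory; phenotype nodes are read-outs and
#' are expected to have no outgoing influence.
#'
#' @slot nodes Character vector of node names, in declaration order.
#' @slot rules Named list of parsed rule expressions (see [parseRule()]),
#'   one per node, in the same order as `nodes`.
#' @slot kind Named character vector, one of `"input"`, `"internal"`,
#'   `"phenotype"` per node.
#'
#' @seealso [booleanNetwork()], [validateNetwork()], [buildTCellNetwork()]
#' @export
setClass("BooleanNetwork",
  representation(nodes = "character", rules = "list", kind = "character"))

setValidity("BooleanNetwork", function(object) {
  msg <- character()
  if (anyDuplicated(object@nodes))
    msg <- c(msg, paste("duplicate node names:",
                        paste(unique(object@nodes[duplicated(object@nodes)]),
                              collapse = ", ")))
  if (length(object@rules) != length(object@nodes))
    msg <- c(msg, "one rule is required per node")
  if (!identical(names(object@rules), object@nodes))
    msg <- c(msg, "rule names must match node names in order")
  if (!identical(names(object@kind), object@nodes))
    msg <- c(msg, "kind annotations must match node names in order")
  if (!all(object@kind %in% c("input", "internal", "phenotype")))
    msg <- c(msg, "node kind must be input, internal or phenotype")
  if (length(msg)) msg else TRUE
})

#' Cell condition: a named environmental/localization context
#'
#' A `CellCondition` encodes one row of the condition catalogue: which ligand
#' and cytokine inputs are present (clamped to 1), which free nodes start
#' active (for ligands whose expression can decay, such as `LAG3_L`), and
#' which checkpoint receptors are not expressed in this context (clamped to
#' 0). All remaining inputs are clamped to 0 and internal nodes start at 0.
#'
#' @slot name Condition label.
#' @slot activeInputs Input nodes clamped to 1.
#' @slot initialActive Free (non-input) nodes whose initial value is 1.
#' @slot notExpressed Nodes clamped to 0 (receptor repertoire restriction).
#' @slot cellType `"CD4"`, `"CD8"` or `"generic"`.
#' @slot localization `"LN"`, `"TME"` or `"none"`.
#'
#' @seealso [tcellConditions()], [conditionInitialSpec()]
#' @export
setClass("CellCondition",
  representation(name = "character", activeInputs = "character",
                 initialActive = "character", notExpressed = "character",
                 cellType = "character", localization = "character"),
  prototype(initialActive = character(), notExpressed = character(),
            cellType = "generic", localization = "none"))

setValidity("CellCondition", function(object) {
  msg <- character()
  if (length(object@name) != 1L) msg <- c(msg, "name must be a single string")
  if (!object@cellType %in% c("CD4", "CD8", "generic"))
    msg <- c(msg, "cellType must be CD4, CD8 or generic")
  if (!object@localization %in% c("LN", "TME", "none"))
    msg <- c(msg, "localization must be LN, TME or none")
  if (length(msg)) msg else TRUE
})

#' Perturbation: a node forced to a constant value
#'
#' Models a treatment (checkpoint inhibitor, forced value 0) or an
#' overexpression (forced value 1): the node's rule is replaced by the
#' constant, all other rules are untouched.
#'
#' @slot node Node name.
#' @slot value Forced value, 0 or 1.
#'
#' @seealso [perturbation()], [applyPerturbations()]
#' @export
setClass("Perturbation",
  representation(node = "character", value = "integer"))

setValidity("Perturbation", function(object) {
  if (length(object@node) != 1L) return("node must be a single name")
  if (!object@value %in% c(0L, 1L)) return("value must be 0 or 1")
  TRUE
})

#' Simulation configuration for the stochastic engine
#'
#' @slot nTrajectories Number of Gillespie trajectories (default 10000).
#' @slot tMax Simulation horizon in model-time units (default 50).
#' @slot rateUp Named numeric of per-node activation rates; nodes absent
#'   from the vector use 1.
#' @slot rateDown Same for deactivation rates.
#' @slot seed Integer seed; expands to per-trajectory substreams.
#' @slot gridPoints Number of uniform time-grid points (default 100).
#' @slot convergenceWindow Fraction of `tMax` over which asymptotics are
#'   averaged (default 0.2, the last 20 percent).
#' @slot convergenceTol Total-variation tolerance between the two halves of
#'   the convergence window above which non-convergence is flagged.
#'
#' @seealso [simulationConfig()], [simulateEnsemble()]
#' @export
setClass("SimulationConfig",
  representation(nTrajectories = "integer", tMax = "numeric",
                 rateUp = "numeric", rateDown = "numeric", seed = "numeric",
                 gridPoints = "integer", convergenceWindow = "numeric",
                 convergenceTol = "numeric"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nTrajectories < 1L) msg <- c(msg, "nTrajectories must be >= 1")
  if (object@tMax <= 0) msg <- c(msg, "tMax must be positive")
  if (any(object@rateUp <= 0) || any(object@rateDown <= 0))
    msg <- c(msg, "rates must be strictly positive")
  if (object@convergenceWindow <= 0 || object@convergenceWindow >= 1)
    msg <- c(msg, "convergenceWindow must be in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' Trajectory ensemble: averaged stochastic time courses
#'
#' Extends [SummarizedExperiment::SummarizedExperiment]: the `"marginal"`
#' assay holds the per-node marginal probability on the uniform time grid
#' (nodes as rows, grid points as columns, times in `colData()$time`), the
#' node role in `rowData()$kind`. The joint distribution over the phenotype
#' nodes is kept in `phenotypeJoint` (categories as rows, grid as columns).
#'
#' @slot phenotypeJoint Matrix of joint phenotype-category probabilities.
#' @slot config The [SimulationConfig][SimulationConfig-class] used.
#' @slot absorbedFraction Fraction of trajectories absorbed in a stable
#'   state before the horizon.
#'
#' @seealso [simulateEnsemble()], [asymptoticPhenotypes()]
#' @export
#' @import SummarizedExperiment
setClass("TrajectoryEnsemble",
  contains = "SummarizedExperiment",
  representation(phenotypeJoint = "matrix", config = "SimulationConfig",
                 absorbedFraction = "numeric"))

#' Joint phenotype distribution at quasi-stationarity
#'
#' Probabilities over the joint states of the phenotype nodes, averaged over
#' the convergence window of an ensemble. Categories follow the convention
#' of naming a state by its ON set (e.g. `"Treg"` means Treg is ON while the
#' other phenotype nodes are OFF; `"Treg-Th1"` means both are ON); the
#' all-OFF category is `"None"`.
#'
#' @slot probs Named numeric of category probabilities (sums to 1).
#' @slot marginals Named numeric of per-phenotype marginal probabilities.
#' @slot se Named numeric of Monte-Carlo standard errors of `marginals`.
#' @slot nTrajectories Ensemble size behind the estimates.
#' @slot converged FALSE when the two halves of the convergence window
#'   differ by more than the tolerance (total variation).
#'
#' @seealso [asymptoticPhenotypes()], [inhibitionStrength()], [th1TregRatio()]
#' @export
setClass("PhenotypeDistribution",
  representation(probs = "numeric", marginals = "numeric", se = "numeric",
                 nTrajectories = "integer", converged = "logical"))

setValidity("PhenotypeDistribution", function(object) {
  if (abs(sum(object@probs) - 1) > 1e-9)
    return("category probabilities must sum to 1")
  TRUE
})

#' Attractor of the asynchronous dynamics
#'
#' Either a stable state (a single state whose successor is itself) or a
#' cyclic attractor (a terminal strongly connected component with two or
#' more states).
#'
#' @slot kind `"stable_state"` or `"cyclic"`.
#' @slot states 0/1 matrix, one row per member state, columns named by node.
#' @slot basinSize Number of reachable states from which the attractor is
#'   reachable, or `NA` when not computed.
#'
#' @seealso [attractors()]
#' @export
setClass("Attractor",
  representation(kind = "character", states = "matrix", basinSize = "integer"))

setValidity("Attractor", function(object) {
  msg <- character()
  if (!object@kind %in% c("stable_state", "cyclic"))
    msg <- c(msg, "kind must be stable_state or cyclic")
  if (object@kind == "stable_state" && nrow(object@states) != 1L)
    msg <- c(msg, "a stable state has exactly one member state")
  if (object@kind == "cyclic" && nrow(object@states) < 2L)
    msg <- c(msg, "a cyclic attractor has at least two member states")
  if (length(msg)) msg else TRUE
})

#' Result of an in-silico scenario protocol
#'
#' @slot scenario Scenario identifier.
#' @slot distributions Named list of
#'   [PhenotypeDistribution][PhenotypeDistribution-class] objects, one per
#'   simulated condition/treatment.
#' @slot stats Data frame of derived statistics (inhibition strengths,
#'   Th1/Treg ratios, per-stage probabilities).
#' @slot verdicts Data frame of directional comparisons (PASS/FAIL) against
#'   the published qualitative expectations; empty for panels without
#'   directional expectations.
#' @slot seedUsed Seed behind every simulation of the scenario.
#'
#' @seealso [singleCheckpointPanel()], [twoStepProtocol()], [cytokinePanel()]
#' @export
setClass("ScenarioResult",
  representation(scenario = "character", distributions = "list",
                 stats = "data.frame", verdicts = "data.frame",
                 seedUsed = "numeric"))
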