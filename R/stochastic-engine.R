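## Gillespie simulation of the continuous-time Markov process on the
## Boolean network: at each jump, among the nodes whose rule value disagrees
## with their current value, one is chosen with probability proportional to
## its rate (activation rate when flipping to 1, deactivation rate when
## flipping to 0, both defaulting to the standard value 1); the holding time
## is exponential with the summed rate. A single seed expands to one
## substream per trajectory, so ensembles are reproducible independently of
## execution order.

#' Simulation configuration
#'
#' @param nTrajectories Ensemble size (default 10000).
#' @param tMax Horizon in model-time units (default 50).
#' @param rateUp,rateDown Named numeric vectors of per-node rates; nodes not
#'   named use the standard value 1.
#' @param seed Integer seed.
#' @param gridPoints Time-grid resolution (default 100).
#' @param convergenceWindow Fraction of `tMax` over which asymptotics are
#'   averaged (default 0.2).
#' @param convergenceTol Total-variation threshold between the two window
#'   halves above which non-convergence is flagged (default 0.02).
#' @return A [SimulationConfig][SimulationConfig-class].
#' @export
simulationConfig <- function(nTrajectories = 10000L, tMax = 50,
                             rateUp = numeric(), rateDown = numeric(),
                             seed = 1L, gridPoints = 100L,
                             convergenceWindow = 0.2, convergenceTol = 0.02) {
  new("SimulationConfig", nTrajectories = as.integer(nTrajectories),
      tMax = as.numeric(tMax), rateUp = rateUp, rateDown = rateDown,
      seed = as.numeric(seed), gridPoints = as.integer(gridPoints),
      convergenceWindow = convergenceWindow, convergenceTol = convergenceTol)
}

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf("SimulationConfig: %d trajectories, tMax = %g, seed = %g\n",
              object@nTrajectories, object@tMax, object@seed))
})

#' Initial-condition specification
#'
#' Every node receives exactly one specification: clamped (held constant),
#' deterministic initial value (default 0), or randomized with a given
#' activation probability.
#'
#' @param net A [BooleanNetwork][BooleanNetwork-class].
#' @param clamp Named 0/1 vector of nodes held constant for the whole
#'   simulation (inputs, non-expressed receptors, forced nodes).
#' @param init Named 0/1 vector of deterministic initial values for free
#'   nodes (unnamed nodes start at 0).
#' @param randomProb Named numeric vector of activation probabilities for
#'   nodes randomized at t = 0.
#' @return List with entries `clamp`, `init`, `randomProb`, aligned to the
#'   node order of the network.
#' @export
initialConditionSpec <- function(net, clamp = NULL, init = NULL,
                                 randomProb = NULL) {
  nodes <- net@nodes
  bad <- setdiff(c(names(clamp), names(init), names(randomProb)), nodes)
  if (length(bad))
    stop(sprintf("unknown node(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  overlap <- intersect(names(init), names(randomProb))
  if (length(overlap))
    stop(sprintf("node(s) specified both deterministically and randomly: %s",
                 paste(overlap, collapse = ", ")), call. = FALSE)
  clampVec <- setNames(rep(-1L, length(nodes)), nodes)
  clampVec[names(clamp)] <- as.integer(clamp)
  initVec <- setNames(rep(0L, length(nodes)), nodes)
  initVec[names(init)] <- as.integer(init)
  randVec <- setNames(rep(-1, length(nodes)), nodes)
  randVec[names(randomProb)] <- as.numeric(randomProb)
  list(clamp = clampVec, init = initVec, randomProb = randVec)
}

rateVectors <- function(net, config) {
  nodes <- net@nodes
  up <- setNames(rep(1, length(nodes)), nodes)
  down <- up
  if (length(config@rateUp)) up[names(config@rateUp)] <- config@rateUp
  if (length(config@rateDown)) down[names(config@rateDown)] <- config@rateDown
  list(up = up, down = down)
}

phenotypeCategoryLabels <- function(phenNodes) {
  k <- length(phenNodes)
  labels <- character(2^k)
  for (cat in 0:(2^k - 1)) {
    on <- phenNodes[bitwAnd(cat, 2^(seq_len(k) - 1L)) > 0]
    labels[cat + 1L] <- if (length(on)) paste(on, collapse = "-") else "None"
  }
  labels
}

#' Simulate a stochastic trajectory ensemble
#'
#' Runs `nTrajectories` Gillespie paths and returns per-node marginal
#' probabilities and the joint distribution over the phenotype nodes on a
#' uniform time grid. Deterministic given the seed.
#'
#' @param net A [BooleanNetwork][BooleanNetwork-class].
#' @param initSpec An [initialConditionSpec()] (or a
#'   [CellCondition][CellCondition-class], which is converted with
#'   [conditionInitialSpec()]).
#' @param config A [simulationConfig()].
#' @return A [TrajectoryEnsemble][TrajectoryEnsemble-class].
#' @examples
#' toggle <- booleanNetwork(c(A = "!B", B = "!A"))
#' ens <- simulateEnsemble(toggle,
#'   initialConditionSpec(toggle, randomProb = c(A = 0.5, B = 0.5)),
#'   simulationConfig(nTrajectories = 500L, tMax = 10, seed = 7L))
#' marginals(ens)[, ncol(marginals(ens))]
#' @export
#' @importFrom S4Vectors DataFrame
simulateEnsemble <- function(net, initSpec, config = simulationConfig()) {
  if (is(initSpec, "CellCondition"))
    initSpec <- conditionInitialSpec(initSpec, net)
  nodes <- net@nodes
  phen <- nodes[net@kind == "phenotype"]
  phenIdx <- match(phen, nodes) - 1L
  grid <- seq(0, config@tMax, length.out = config@gridPoints)
  rates <- rateVectors(net, config)
  res <- cpp_simulate_ensemble(compileNetwork(net),
                               unname(initSpec$init), unname(initSpec$clamp),
                               unname(initSpec$randomProb),
                               unname(rates$up), unname(rates$down),
                               grid, config@nTrajectories, config@seed,
                               phenIdx)
  marg <- res$marginalCounts / config@nTrajectories
  dimnames(marg) <- list(nodes, NULL)
  joint <- res$jointCounts / config@nTrajectories
  rownames(joint) <- phenotypeCategoryLabels(phen)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(marginal = marg),
    rowData = S4Vectors::DataFrame(kind = net@kind),
    colData = S4Vectors::DataFrame(time = grid))
  new("TrajectoryEnsemble", se, phenotypeJoint = joint, config = config,
      absorbedFraction = res$absorbed / config@nTrajectories)
}

#' @rdname marginals
#' @export
setMethod("marginals", "TrajectoryEnsemble", function(x)
  SummarizedExperiment::assay(x, "marginal"))

#' @rdname phenotypeJoint
#' @export
setMethod("phenotypeJoint", "TrajectoryEnsemble", function(x) x@phenotypeJoint)

setMethod("show", "TrajectoryEnsemble", function(object) {
  cat(sprintf("TrajectoryEnsemble: %d nodes x %d grid points, %d trajectories (tMax = %g, seed = %g)\n",
              nrow(object), ncol(object), object@config@nTrajectories,
              object@config@tMax, object@config@seed))
  cat(sprintf("  absorbed before horizon: %.1f%%\n",
              100 * object@absorbedFraction))
})

#' Single Gillespie trajectory
#'
#' @param net A [BooleanNetwork][BooleanNetwork-class].
#' @param init Complete named 0/1 initial state.
#' @param config A [simulationConfig()]; `nTrajectories` is ignored.
#' @param clamped Named 0/1 vector of clamped nodes.
#' @param streamIndex Substream index (default 0), so that
#'   `gillespieTrajectory(..., streamIndex = i)` is the i-th trajectory of
#'   the corresponding ensemble stream layout.
#' @return List with `times` (jump times), `flips` (flipped node names),
#'   `finalState`, and `absorbed` (TRUE when a stable state was reached
#'   before `tMax`).
#' @export
gillespieTrajectory <- function(net, init, config = simulationConfig(),
                                clamped = NULL, streamIndex = 0) {
  init <- assertState(net, init)
  nodes <- net@nodes
  clampVec <- setNames(rep(-1L, length(nodes)), nodes)
  if (!is.null(clamped)) clampVec[names(clamped)] <- as.integer(clamped)
  rates <- rateVectors(net, config)
  res <- cpp_gillespie_path(compileNetwork(net), unname(init),
                            unname(clampVec), unname(rates$up),
                            unname(rates$down), config@tMax, config@seed,
                            streamIndex)
  list(times = res$times, flips = nodes[res$flips],
       finalState = setNames(as.integer(res$finalState), nodes),
       absorbed = res$absorbed)
}

#' Asymptotic phenotype distribution of an ensemble
#'
#' Averages the joint phenotype distribution over the convergence window
#' (by default the last 20 percent of the horizon) and flags
#' non-convergence when the two halves of the window differ by more than
#' the configured total-variation tolerance.
#'
#' @param ens A [TrajectoryEnsemble][TrajectoryEnsemble-class].
#' @return A [PhenotypeDistribution][PhenotypeDistribution-class].
#' @export
asymptoticPhenotypes <- function(ens) {
  cfg <- ens@config
  times <- SummarizedExperiment::colData(ens)$time
  window <- which(times >= (1 - cfg@convergenceWindow) * cfg@tMax)
  joint <- ens@phenotypeJoint
  half <- window[seq_len(floor(length(window) / 2))]
  rest <- setdiff(window, half)
  p1 <- rowMeans(joint[, half, drop = FALSE])
  p2 <- rowMeans(joint[, rest, drop = FALSE])
  tv <- 0.5 * sum(abs(p1 - p2))
  probs <- rowMeans(joint[, window, drop = FALSE])
  probs <- probs / sum(probs)

  phen <- rownames(ens)[SummarizedExperiment::rowData(ens)$kind == "phenotype"]
  marg <- vapply(seq_along(phen), function(p) {
    cats <- which(bitwAnd(seq_along(probs) - 1L, 2^(p - 1L)) > 0)
    sum(probs[cats])
  }, 0)
  names(marg) <- phen
  n <- cfg@nTrajectories
  ## Agresti-Coull adjusted standard errors: honest near 0 and 1, where the
  ## plain binomial formula collapses to zero
  pt <- (marg * n + 2) / (n + 4)
  se <- sqrt(pt * (1 - pt) / (n + 4))
  new("PhenotypeDistribution", probs = probs, marginals = marg, se = se,
      nTrajectories = n, converged = tv <= cfg@convergenceTol)
}

#' @rdname categoryProbs
#' @export
setMethod("categoryProbs", "PhenotypeDistribution", function(x) x@probs)

#' @rdname phenotypeMarginals
#' @export
setMethod("phenotypeMarginals", "PhenotypeDistribution", function(x)
  x@marginals)

#' @rdname isConverged
#' @export
setMethod("isConverged", "PhenotypeDistribution", function(x) x@converged)

setMethod("show", "PhenotypeDistribution", function(object) {
  cat("PhenotypeDistribution",
      if (!object@converged) "(non-convergence flagged)", "\n")
  p <- sort(object@probs[object@probs > 0.0005], decreasing = TRUE)
  for (nm in names(p)) cat(sprintf("  %-28s %6.3f\n", nm, p[[nm]]))
})

#' Inhibition strength of a condition relative to a baseline
#'
#' `100 * (1 - P_condition(phenotype) / P_baseline(phenotype))`, clipped to
#' `[0, 100]` in `$percent` for reporting; negative values (activation) are
#' kept unclipped in `$raw`.
#'
#' @param dist,baseline [PhenotypeDistribution][PhenotypeDistribution-class]
#'   objects for the condition and the reference.
#' @param phenotype Phenotype node name.
#' @param eps Baseline marginals below `eps` are an error (default 1e-6).
#' @return List with `percent` (clipped), `raw`, and `se` (Monte-Carlo
#'   standard error of the percentage).
#' @export
inhibitionStrength <- function(dist, baseline, phenotype, eps = 1e-6) {
  pb <- baseline@marginals[[phenotype]]
  pc <- dist@marginals[[phenotype]]
  if (is.null(pb) || pb < eps)
    stop(sprintf("zero baseline marginal for phenotype '%s'", phenotype),
         call. = FALSE)
  raw <- 100 * (1 - pc / pb)
  seb <- baseline@se[[phenotype]]
  sec <- dist@se[[phenotype]]
  ## delta method on the ratio pc/pb
  se <- 100 * sqrt((sec / pb)^2 + (pc * seb / pb^2)^2)
  list(percent = min(max(raw, 0), 100), raw = raw, se = se)
}
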