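## Synthetic-data generators: random Boolean networks with controlled size,
## in-degree and activator/inhibitor mix, plus hand-built fixtures with
## analytically known dynamics, so the engine is testable independently of
## the biological model. Seed expansion uses the same substream scheme as
## the stochastic engine (cpp_mix_seed), so results are reproducible across
## modules.

#' Generate a random Boolean network
#'
#' Two rule schemes: `"inhibitory-bias"` mirrors the convention of the
#' T-cell model, building each rule as (OR of activators) AND (AND of
#' negated inhibitors); `"random-truth-table"` draws a uniform random
#' Boolean function over the chosen regulators. Deterministic given the
#' seed.
#'
#' @param nNodes Number of nodes.
#' @param k In-degree: a single value or a range `c(kmin, kmax)` sampled
#'   per node; must be below `nNodes`.
#' @param inhibitorFraction Probability that a chosen regulator acts as an
#'   inhibitor (inhibitory-bias scheme only; default 0.3).
#' @param scheme `"inhibitory-bias"` or `"random-truth-table"`.
#' @param seed Integer seed.
#' @return A [BooleanNetwork][BooleanNetwork-class].
#' @examples
#' net <- randomNetwork(6, k = 2, seed = 7)
#' nodeNames(net)
#' @export
randomNetwork <- function(nNodes, k = 2L, inhibitorFraction = 0.3,
                          scheme = c("inhibitory-bias", "random-truth-table"),
                          seed = 1L) {
  scheme <- match.arg(scheme)
  if (nNodes < 1L) stop("nNodes must be >= 1", call. = FALSE)
  if (max(k) >= nNodes && nNodes > 1L)
    stop("in-degree k must be below nNodes", call. = FALSE)
  if (nNodes == 1L && max(k) > 0L)
    stop("a single-node network admits only k = 0", call. = FALSE)
  rng <- makeSubstream(seed, 0L)
  nodes <- sprintf("N%02d", seq_len(nNodes))
  rules <- character(nNodes)
  for (i in seq_len(nNodes)) {
    ki <- if (length(k) > 1L)
      k[1L] + rngInt(rng, k[2L] - k[1L] + 1L) - 1L else k
    regs <- nodes[-i][rngSample(rng, nNodes - 1L, ki)]
    if (ki == 0L) {
      rules[[i]] <- as.character(rngInt(rng, 2L) - 1L)
      next
    }
    if (scheme == "inhibitory-bias") {
      inhib <- vapply(seq_len(ki), function(j) rngUnif(rng) < inhibitorFraction,
                      NA)
      if (all(inhib)) inhib[[1L]] <- FALSE  # keep at least one activator
      act <- regs[!inhib]
      inh <- regs[inhib]
      rule <- paste0("(", paste(act, collapse = " | "), ")")
      if (length(inh))
        rule <- paste(rule, paste0("!", inh, collapse = " & "), sep = " & ")
      rules[[i]] <- rule
    } else {
      ## random truth table, rendered as a DNF over the regulators
      tt <- vapply(seq_len(2^ki), function(j) rngInt(rng, 2L) - 1L, 0L)
      ones <- which(tt == 1L) - 1L
      if (!length(ones)) { rules[[i]] <- "0"; next }
      if (length(ones) == 2^ki) { rules[[i]] <- "1"; next }
      terms <- vapply(ones, function(row) {
        bits <- bitwAnd(row, 2^(seq_len(ki) - 1L)) > 0
        paste(ifelse(bits, regs, paste0("!", regs)), collapse = " & ")
      }, "")
      rules[[i]] <- paste0("(", terms, ")", collapse = " | ")
    }
  }
  booleanNetwork(setNames(rules, nodes))
}

## Small deterministic RNG on top of the engine's substream scheme: each
## draw advances a counter and hashes (seed, counter), so generation is
## reproducible and independent of R's global RNG state.
makeSubstream <- function(seed, index) {
  base <- cpp_mix_seed(seed, index)
  env <- new.env(parent = emptyenv())
  env$counter <- 0L
  env$base <- base
  env
}

rngUnif <- function(rng) {
  rng$counter <- rng$counter + 1L
  cpp_mix_seed(rng$base, rng$counter) / 2147483647
}

rngInt <- function(rng, n) {
  1L + as.integer(floor(rngUnif(rng) * n)) %% n
}

rngSample <- function(rng, n, size) {
  pool <- seq_len(n)
  out <- integer(size)
  for (i in seq_len(size)) {
    j <- rngInt(rng, length(pool))
    out[[i]] <- pool[[j]]
    pool <- pool[-j]
  }
  sort(out)
}

#' Hand-built fixture networks with known dynamics
#'
#' * `toggle_switch`: `A = !B`, `B = !A`; fixed points (1,0) and (0,1).
#' * `self_activator`: `A = A`; fixed points (0) and (1).
#' * `oscillator_2`: `A = B`, `B = !A`; a single 4-state cyclic attractor,
#'   no fixed point.
#' * `chain_k`: `X1 = 1`, `Xi = X(i-1)`; relaxation cascade, the marginal
#'   of `Xk` at time t is the Erlang(k) distribution function.
#' * `relaxation_1`: `X = 1` started from 0; `P(X = 1 at t) = 1 - exp(-t)`.
#'
#' @param name Fixture name.
#' @param k Chain length for `chain_k` (default 3).
#' @return A [BooleanNetwork][BooleanNetwork-class].
#' @export
networkFixture <- function(name = c("toggle_switch", "self_activator",
                                    "oscillator_2", "chain_k",
                                    "relaxation_1"), k = 3L) {
  name <- match.arg(name)
  switch(name,
    toggle_switch = booleanNetwork(c(A = "!B", B = "!A")),
    self_activator = booleanNetwork(c(A = "A")),
    oscillator_2 = booleanNetwork(c(A = "B", B = "!A")),
    chain_k = {
      nodes <- paste0("X", seq_len(k))
      rules <- c("1", nodes[-k])
      booleanNetwork(setNames(rules, nodes))
    },
    relaxation_1 = booleanNetwork(c(X = "1")))
}
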