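## Exact analysis of the asynchronous dynamics. Asynchronous semantics
## throughout: a transition flips exactly one node, and a flip of node n is
## legal in state s iff the rule of n evaluates to a value different from
## s[n]. These are also the transitions of the continuous-time Markov chain
## simulated by the stochastic engine.

#' Asynchronous successor states
#'
#' One successor per node whose rule value differs from its current value;
#' the empty set exactly when `state` is a stable state.
#'
#' @param net A [BooleanNetwork][BooleanNetwork-class].
#' @param state Complete named 0/1 state.
#' @param clamped Optional named 0/1 vector of nodes held fixed
#'   (perturbations are usually applied with [applyPerturbations()] instead).
#' @return Named list: for each flippable node, the successor state.
#' @export
asyncSuccessors <- function(net, state, clamped = NULL) {
  state <- assertState(net, state)
  free <- setdiff(net@nodes, names(clamped))
  out <- list()
  for (nm in free) {
    v <- evaluateRule(net@rules[[nm]], state)
    if (v != state[[nm]]) {
      s2 <- state
      s2[[nm]] <- v
      out[[nm]] <- s2
    }
  }
  out
}

#' Is a state stable?
#'
#' @inheritParams asyncSuccessors
#' @return TRUE iff the state has no asynchronous successor.
#' @export
isStableState <- function(net, state, clamped = NULL) {
  length(asyncSuccessors(net, state, clamped)) == 0L
}

## ---- fixed points ----------------------------------------------------------

#' Enumerate the fixed points of a Boolean network
#'
#' A fixed point is a state `s` with `rule(s) = s` for every free node,
#' consistent with the clamps. The default method is constraint propagation
#' with branching (a DPLL-style search that propagates node values whose
#' regulators are fully assigned); `method = "exhaustive"` enumerates all
#' `2^n` states of the free nodes and is refused above `limit` free nodes.
#'
#' @param net A [BooleanNetwork][BooleanNetwork-class].
#' @param clamped Named 0/1 vector of clamped nodes (their rules are ignored).
#' @param method `"propagate"` (default) or `"exhaustive"`.
#' @param limit Maximum number of free nodes for the exhaustive method
#'   (default 22).
#' @return 0/1 matrix with one row per fixed point (possibly zero rows),
#'   columns named by node, rows ordered lexicographically in declared node
#'   order (0 before 1).
#' @examples
#' toggle <- booleanNetwork(c(A = "!B", B = "!A"))
#' fixedPoints(toggle)
#' @export
fixedPoints <- function(net, clamped = NULL,
                        method = c("propagate", "exhaustive"), limit = 22L) {
  method <- match.arg(method)
  nodes <- net@nodes
  if (!is.null(clamped)) {
    unknown <- setdiff(names(clamped), nodes)
    if (length(unknown))
      stop(sprintf("unknown clamped node(s): %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
  }
  free <- setdiff(nodes, names(clamped))

  if (method == "exhaustive") {
    if (length(free) > limit)
      stop(sprintf("exhaustive enumeration refused: %d free nodes exceeds limit %d",
                   length(free), limit), call. = FALSE)
    grid <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), length(free)),
                                  KEEP.OUT.ATTRS = FALSE))
    ## expand.grid varies the first column fastest; lexicographic order in
    ## declared node order needs the last to vary fastest
    grid <- grid[, rev(seq_len(ncol(grid))), drop = FALSE]
    colnames(grid) <- free
    ord <- do.call(order, as.data.frame(grid))
    grid <- grid[ord, , drop = FALSE]
    states <- matrix(FALSE, nrow(grid), length(nodes),
                     dimnames = list(NULL, nodes))
    states[, free] <- grid
    for (nm in names(clamped)) states[, nm] <- clamped[[nm]] == 1
    keep <- rep(TRUE, nrow(states))
    for (nm in free)
      keep <- keep & (evaluateRuleStates(net@rules[[nm]], states) == states[, nm])
    res <- states[keep, , drop = FALSE]
    out <- matrix(as.integer(res), nrow(res), ncol(res),
                  dimnames = list(NULL, nodes))
    rownames(out) <- apply(out, 1L, paste, collapse = "")
    return(out)
  }

  ## constraint propagation with branching
  rules <- net@rules
  regs <- lapply(rules, ruleRegulators)
  clampVal <- setNames(rep(NA_integer_, length(nodes)), nodes)
  for (nm in names(clamped)) clampVal[[nm]] <- as.integer(clamped[[nm]])
  solutions <- list()

  propagate <- function(assign) {
    repeat {
      changed <- FALSE
      for (nm in free) {
        r <- regs[[nm]]
        if (length(r) && anyNA(assign[r])) next
        val <- evaluateRule(rules[[nm]], assign)
        cur <- assign[[nm]]
        if (is.na(cur)) {
          assign[[nm]] <- val
          changed <- TRUE
        } else if (cur != val) {
          return(NULL)
        }
      }
      if (!changed) return(assign)
    }
  }

  search <- function(assign) {
    assign <- propagate(assign)
    if (is.null(assign)) return(invisible(NULL))
    open <- nodes[is.na(assign)]
    if (!length(open)) {
      solutions[[length(solutions) + 1L]] <<- assign
      return(invisible(NULL))
    }
    nm <- open[[1L]]
    for (v in c(0L, 1L)) {
      a2 <- assign
      a2[[nm]] <- v
      search(a2)
    }
    invisible(NULL)
  }

  search(clampVal)
  if (!length(solutions)) {
    out <- matrix(integer(), 0L, length(nodes), dimnames = list(NULL, nodes))
    return(out)
  }
  out <- do.call(rbind, solutions)
  colnames(out) <- nodes
  out <- out[do.call(order, as.data.frame(out)), , drop = FALSE]
  rownames(out) <- apply(out, 1L, paste, collapse = "")
  out
}

## ---- reachable transition system -------------------------------------------

## Encode states over free nodes as doubles (exact up to 2^53).
encodeStates <- function(states, weights) as.vector(states %*% weights)

## BFS over the reachable asynchronous transition system.
## Returns states matrix (0/1, all nodes), and an edge list of state indices
## labelled with the flipped node.
reachableSystem <- function(net, initialStates, clamped = NULL,
                            limit = 2^20) {
  nodes <- net@nodes
  free <- setdiff(nodes, names(clamped))
  weights <- setNames(2^(seq_along(free) - 1L), free)

  if (is.null(dim(initialStates)))
    initialStates <- matrix(initialStates, 1L,
                            dimnames = list(NULL, names(initialStates)))
  init <- matrix(0L, nrow(initialStates), length(nodes),
                 dimnames = list(NULL, nodes))
  init[, colnames(initialStates)] <- initialStates
  for (nm in names(clamped)) init[, nm] <- as.integer(clamped[[nm]])

  seen <- new.env(hash = TRUE, parent = emptyenv())
  states <- list()
  keyOf <- function(srow) as.character(sum(srow[free] * weights))
  pushState <- function(srow) {
    k <- keyOf(srow)
    idx <- seen[[k]]
    if (is.null(idx)) {
      idx <- length(states) + 1L
      if (idx > limit) stop("reachable state-space limit exceeded", call. = FALSE)
      states[[idx]] <<- srow
      seen[[k]] <<- idx
      attr(idx, "new") <- TRUE
    }
    idx
  }

  edges <- list()
  queue <- integer()
  for (i in seq_len(nrow(init))) {
    idx <- pushState(init[i, ])
    if (isTRUE(attr(idx, "new"))) queue <- c(queue, idx)
  }
  qpos <- 1L
  while (qpos <= length(queue)) {
    idx <- queue[[qpos]]; qpos <- qpos + 1L
    s <- states[[idx]]
    for (nm in free) {
      v <- evaluateRule(net@rules[[nm]], s)
      if (v != s[[nm]]) {
        s2 <- s
        s2[[nm]] <- v
        j <- pushState(s2)
        if (isTRUE(attr(j, "new"))) queue <- c(queue, as.integer(j))
        edges[[length(edges) + 1L]] <- c(idx, as.integer(j), match(nm, nodes))
      }
    }
  }
  stateMat <- do.call(rbind, states)
  colnames(stateMat) <- nodes
  edgeMat <- if (length(edges)) do.call(rbind, edges)
             else matrix(integer(), 0L, 3L)
  colnames(edgeMat) <- c("from", "to", "node")
  list(states = stateMat, edges = edgeMat, free = free)
}

#' Attractors of the reachable asynchronous dynamics
#'
#' Builds the transition system reachable from the initial state(s) and
#' returns its terminal strongly connected components: stable states
#' (single self-successor states) and cyclic attractors.
#'
#' @param net A [BooleanNetwork][BooleanNetwork-class].
#' @param initialStates A complete named 0/1 state, or a 0/1 matrix of
#'   states (columns named by node).
#' @param clamped Named 0/1 vector of clamped nodes.
#' @param limit Maximum reachable state-space size (default `2^20`).
#' @param basinSizes Compute, for each attractor, the number of reachable
#'   states from which it can be reached (default FALSE).
#' @return List of [Attractor][Attractor-class] objects, ordered by the
#'   lexicographically smallest member state.
#' @examples
#' osc <- booleanNetwork(c(A = "B", B = "!A"))
#' attractors(osc, networkState(osc))
#' @export
#' @importFrom igraph graph_from_data_frame components V subcomponent
attractors <- function(net, initialStates, clamped = NULL, limit = 2^20,
                       basinSizes = FALSE) {
  sys <- reachableSystem(net, initialStates, clamped, limit)
  n <- nrow(sys$states)
  if (nrow(sys$edges) == 0L) {
    ## every reachable state is stable
    comp <- list(membership = seq_len(n), no = n)
    g <- NULL
  } else {
    g <- igraph::graph_from_data_frame(
      data.frame(from = sys$edges[, "from"], to = sys$edges[, "to"]),
      directed = TRUE, vertices = data.frame(name = seq_len(n)))
    comp <- igraph::components(g, mode = "strong")
  }
  memb <- comp$membership
  ## terminal SCC: no edge leaves the component
  leaves <- rep(FALSE, comp$no)
  if (nrow(sys$edges)) {
    cross <- memb[sys$edges[, "from"]] != memb[sys$edges[, "to"]]
    leaves[unique(memb[sys$edges[cross, "from"]])] <- TRUE
  }
  out <- list()
  for (cid in seq_len(comp$no)) {
    if (leaves[[cid]]) next
    members <- which(memb == cid)
    st <- sys$states[members, , drop = FALSE]
    kind <- if (length(members) == 1L) {
      ## single state: terminal SCC with no outgoing edge is stable
      "stable_state"
    } else "cyclic"
    st <- st[do.call(order, as.data.frame(st)), , drop = FALSE]
    rownames(st) <- apply(st, 1L, paste, collapse = "")
    basin <- NA_integer_
    if (basinSizes && !is.null(g)) {
      basin <- length(igraph::subcomponent(g, v = as.character(members[[1L]]),
                                           mode = "in"))
    } else if (basinSizes) {
      basin <- 1L
    }
    out[[length(out) + 1L]] <-
      new("Attractor", kind = kind, states = st, basinSize = basin)
  }
  ord <- order(vapply(out, function(a) rownames(a@states)[1L], ""))
  out[ord]
}

#' Tabular attractor report
#'
#' @param atts List of [Attractor][Attractor-class] objects.
#' @return Data frame: attractor id, kind, size, member states (bitstrings
#'   in declared node order, separated by `;`). Write with
#'   [utils::write.table()] for the tab-separated form.
#' @export
attractorReport <- function(atts) {
  data.frame(
    id = seq_along(atts),
    kind = vapply(atts, function(a) a@kind, ""),
    size = vapply(atts, function(a) nrow(a@states), 0L),
    states = vapply(atts, function(a)
      paste(rownames(a@states), collapse = ";"), ""),
    stringsAsFactors = FALSE)
}

setMethod("show", "Attractor", function(object) {
  cat(sprintf("Attractor (%s) with %d state(s): %s\n", object@kind,
              nrow(object@states),
              paste(utils::head(rownames(object@states), 4L), collapse = ";")))
})

## ---- exact CTMC (oracle for small networks) --------------------------------

#' Transient distribution of the asynchronous Boolean CTMC
#'
#' Exact solver for small networks, used as the oracle against which the
#' Gillespie engine is checked. The generator has rate `rateUp[n]`
#' (`rateDown[n]`) for each legal flip of node `n` to 1 (to 0). Solved by
#' uniformization with truncation error below `tol` (default 1e-10).
#'
#' @param net A [BooleanNetwork][BooleanNetwork-class].
#' @param p0States Complete named 0/1 state or 0/1 matrix of initial states.
#' @param p0Probs Initial probabilities (recycled to one value per row of
#'   `p0States`; default uniform).
#' @param times Numeric vector of evaluation times.
#' @param rateUp,rateDown Named per-node rates; nodes absent default to 1.
#' @param clamped Named 0/1 vector of clamped nodes.
#' @param limit Maximum reachable state-space size (default 4096).
#' @param tol Uniformization truncation error bound.
#' @return List with `states` (reachable 0/1 matrix), `times`, `probs`
#'   (states x times matrix of probabilities), and `marginals`
#'   (nodes x times).
#' @examples
#' relax <- booleanNetwork(c(X = "1"))
#' sol <- ctmcDistribution(relax, c(X = 0L), times = 1)
#' sol$marginals["X", ]  # 1 - exp(-1)
#' @export
ctmcDistribution <- function(net, p0States, p0Probs = NULL, times,
                             rateUp = NULL, rateDown = NULL, clamped = NULL,
                             limit = 4096, tol = 1e-10) {
  sys <- reachableSystem(net, p0States, clamped, limit)
  n <- nrow(sys$states)
  nodes <- net@nodes
  up <- setNames(rep(1, length(nodes)), nodes)
  down <- up
  if (!is.null(rateUp)) up[names(rateUp)] <- rateUp
  if (!is.null(rateDown)) down[names(rateDown)] <- rateDown
  if (any(c(up, down) <= 0)) stop("rates must be strictly positive", call. = FALSE)

  ## initial distribution over reachable states
  if (is.null(dim(p0States)))
    p0States <- matrix(p0States, 1L, dimnames = list(NULL, names(p0States)))
  if (is.null(p0Probs)) p0Probs <- rep(1 / nrow(p0States), nrow(p0States))
  if (abs(sum(p0Probs) - 1) > 1e-9)
    stop("initial probabilities must sum to 1", call. = FALSE)
  free <- sys$free
  weights <- setNames(2^(seq_along(free) - 1L), free)
  keys <- encodeStates(sys$states[, free, drop = FALSE] == 1L, weights)
  init <- matrix(0L, nrow(p0States), length(nodes),
                 dimnames = list(NULL, nodes))
  init[, colnames(p0States)] <- p0States
  for (nm in names(clamped)) init[, nm] <- as.integer(clamped[[nm]])
  k0 <- encodeStates(init[, free, drop = FALSE] == 1L, weights)
  p0 <- numeric(n)
  idx <- match(k0, keys)
  for (i in seq_along(idx)) p0[idx[i]] <- p0[idx[i]] + p0Probs[i]

  ## sparse generator
  if (nrow(sys$edges)) {
    toVal <- sys$states[cbind(sys$edges[, "to"], sys$edges[, "node"])]
    rate <- ifelse(toVal == 1L, up[nodes[sys$edges[, "node"]]],
                   down[nodes[sys$edges[, "node"]]])
    Q <- Matrix::sparseMatrix(i = sys$edges[, "from"], j = sys$edges[, "to"],
                              x = rate, dims = c(n, n))
  } else {
    Q <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                              dims = c(n, n))
  }
  exitRate <- Matrix::rowSums(Q)
  Q <- Q - Matrix::Diagonal(n, exitRate)

  lambda <- max(exitRate, 1e-12)
  P <- Matrix::Diagonal(n) + Q / lambda

  times <- sort(times)
  probs <- matrix(0, n, length(times))
  for (ti in seq_along(times)) {
    t <- times[[ti]]
    lt <- lambda * t
    ## truncation point covering 1 - tol of the Poisson mass
    kmax <- max(10L, ceiling(lt + 12 * sqrt(lt + 1)))
    while (stats::ppois(kmax, lt, lower.tail = FALSE) > tol) kmax <- kmax * 2L
    w <- stats::dpois(0:kmax, lt)
    vec <- p0
    acc <- w[1L] * vec
    for (k in seq_len(kmax)) {
      vec <- as.vector(vec %*% P)
      acc <- acc + w[k + 1L] * vec
    }
    probs[, ti] <- acc / sum(acc)
  }
  marg <- t(sys$states) %*% probs
  dimnames(marg) <- list(nodes, NULL)
  rownames(probs) <- apply(sys$states, 1L, paste, collapse = "")
  list(states = sys$states, times = times, probs = probs, marginals = marg)
}
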