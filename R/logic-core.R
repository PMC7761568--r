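## Rule language: identifiers, constants 0/1, operators ! & | and
## parentheses, with precedence ! > & > |. AND and OR are n-ary in the
## parsed tree. Node names containing '/' in the literature (e.g. CD80/86)
## are written with underscores (CD80_86).

logicExpr <- function(type, ...) {
  structure(list(type = type, ...), class = "logicExpr")
}

tokenizeRule <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  tokens <- list()
  i <- 1L
  n <- nchar(text)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch %in% c("&", "|", "!", "(", ")")) {
      tokens[[length(tokens) + 1L]] <- list(type = ch, value = ch, pos = i)
      i <- i + 1L
      next
    }
    if (grepl("^[01]$", ch) &&
        !grepl("^[A-Za-z0-9_]$", substr(text, i + 1L, i + 1L))) {
      tokens[[length(tokens) + 1L]] <-
        list(type = "const", value = as.integer(ch), pos = i)
      i <- i + 1L
      next
    }
    if (grepl("^[A-Za-z_]$", ch)) {
      j <- i
      while (j <= n && grepl("^[A-Za-z0-9_]$", substr(text, j, j))) j <- j + 1L
      tokens[[length(tokens) + 1L]] <-
        list(type = "ident", value = substr(text, i, j - 1L), pos = i)
      i <- j
      next
    }
    stop(sprintf("unknown token '%s' at position %d in rule \"%s\"",
                 ch, i, text), call. = FALSE)
  }
  tokens
}

#' Parse a logical rule string
#'
#' Parses a rule written with identifiers, constants `0`/`1`, parentheses
#' and the operators `!` (NOT), `&` (AND) and `|` (OR), with the standard
#' precedence `!` > `&` > `|`. AND and OR are flattened to n-ary operators,
#' so `"Antigens & LCK_FYN & !SHP"` parses to a single AND over three
#' arguments.
#'
#' @param text A single rule string, e.g. `"Antigens & LCK_FYN & !SHP"`.
#' @return A parsed expression tree (class `logicExpr`).
#' @examples
#' e <- parseRule("Antigens & LCK_FYN & !SHP")
#' ruleRegulators(e)
#' evaluateRule(e, c(Antigens = 1, LCK_FYN = 1, SHP = 0))
#' @seealso [evaluateRule()], [renderRule()], [ruleRegulators()]
#' @export
parseRule <- function(text) {
  tokens <- tokenizeRule(text)
  if (length(tokens) == 0L)
    stop("empty rule", call. = FALSE)
  pos <- 1L

  peek <- function() if (pos <= length(tokens)) tokens[[pos]] else NULL
  advance <- function() { tok <- tokens[[pos]]; pos <<- pos + 1L; tok }
  expect <- function(type) {
    tok <- peek()
    if (is.null(tok))
      stop(sprintf("unexpected end of rule \"%s\" (expected '%s')",
                   text, type), call. = FALSE)
    if (tok$type != type)
      stop(sprintf("syntax error at position %d in rule \"%s\": expected '%s'",
                   tok$pos, text, type), call. = FALSE)
    advance()
  }

  parsePrimary <- function() {
    tok <- peek()
    if (is.null(tok))
      stop(sprintf("unexpected end of rule \"%s\"", text), call. = FALSE)
    if (tok$type == "!") {
      advance()
      return(logicExpr("not", arg = parsePrimary()))
    }
    if (tok$type == "(") {
      advance()
      e <- parseOr()
      expect(")")
      return(e)
    }
    if (tok$type == "ident") {
      advance()
      return(logicExpr("var", name = tok$value))
    }
    if (tok$type == "const") {
      advance()
      return(logicExpr("const", value = tok$value))
    }
    stop(sprintf("syntax error at position %d in rule \"%s\"",
                 tok$pos, text), call. = FALSE)
  }

  parseAnd <- function() {
    args <- list(parsePrimary())
    while (!is.null(peek()) && peek()$type == "&") {
      advance()
      args[[length(args) + 1L]] <- parsePrimary()
    }
    if (length(args) == 1L) args[[1L]] else logicExpr("and", args = args)
  }

  parseOr <- function() {
    args <- list(parseAnd())
    while (!is.null(peek()) && peek()$type == "|") {
      advance()
      args[[length(args) + 1L]] <- parseAnd()
    }
    if (length(args) == 1L) args[[1L]] else logicExpr("or", args = args)
  }

  e <- parseOr()
  tok <- peek()
  if (!is.null(tok))
    stop(sprintf("syntax error at position %d in rule \"%s\": trailing input",
                 tok$pos, text), call. = FALSE)
  e
}

#' Render a parsed rule back to its string form
#'
#' `parseRule(renderRule(e))` is logically equivalent to `e` (identical
#' truth table over its regulators).
#'
#' @param expr A parsed rule expression.
#' @return A single rule string.
#' @export
renderRule <- function(expr) {
  rec <- function(e, parentPrec) {
    switch(e$type,
      var = e$name,
      const = as.character(e$value),
      not = paste0("!", {
        s <- rec(e$arg, 3L)
        if (e$arg$type %in% c("and", "or")) paste0("(", s, ")") else s
      }),
      "and" = {
        s <- paste(vapply(e$args, rec, "", parentPrec = 2L), collapse = " & ")
        if (parentPrec > 2L) paste0("(", s, ")") else s
      },
      "or" = {
        s <- paste(vapply(e$args, rec, "", parentPrec = 1L), collapse = " | ")
        if (parentPrec > 1L) paste0("(", s, ")") else s
      },
      stop("unknown expression type"))
  }
  rec(expr, 0L)
}

#' @export
print.logicExpr <- function(x, ...) {
  cat(renderRule(x), "\n")
  invisible(x)
}

#' Evaluate a rule on a network state
#'
#' Standard Boolean semantics; every variable occurring in the expression
#' must be assigned in `state`.
#'
#' @param expr A parsed rule expression.
#' @param state Named numeric/logical vector of 0/1 values.
#' @return 0 or 1 (integer).
#' @export
evaluateRule <- function(expr, state) {
  rec <- function(e) {
    switch(e$type,
      var = {
        v <- state[[e$name]]
        if (is.null(v) || is.na(v))
          stop(sprintf("unassigned variable '%s'", e$name), call. = FALSE)
        as.logical(v)
      },
      const = e$value == 1L,
      not = !rec(e$arg),
      "and" = all(vapply(e$args, rec, NA)),
      "or" = any(vapply(e$args, rec, NA)),
      stop("unknown expression type"))
  }
  if (!is.null(names(state)) && anyNA(match(ruleRegulators(expr), names(state))))
    stop(sprintf("unassigned variable '%s'",
                 setdiff(ruleRegulators(expr), names(state))[1L]), call. = FALSE)
  as.integer(rec(expr))
}

## Vectorized evaluation of a rule over many states at once (logical matrix
## with one named column per node, one row per state).
evaluateRuleStates <- function(expr, states) {
  rec <- function(e) {
    switch(e$type,
      var = {
        if (!e$name %in% colnames(states))
          stop(sprintf("unassigned variable '%s'", e$name), call. = FALSE)
        states[, e$name]
      },
      const = rep(e$value == 1L, nrow(states)),
      not = !rec(e$arg),
      "and" = Reduce(`&`, lapply(e$args, rec)),
      "or" = Reduce(`|`, lapply(e$args, rec)),
      stop("unknown expression type"))
  }
  as.logical(rec(expr))
}

#' Regulators of a rule
#'
#' @param expr A parsed rule expression.
#' @return Character vector of the distinct variable names occurring in the
#'   expression (empty for constant rules).
#' @export
ruleRegulators <- function(expr) {
  rec <- function(e) {
    switch(e$type,
      var = e$name,
      const = character(),
      not = rec(e$arg),
      unlist(lapply(e$args, rec)))
  }
  unique(rec(expr))
}

## Signed regulators: tracks negation parity; a variable under an odd number
## of NOTs contributes a negative edge, even a positive one; both parities
## yield a dual edge.
signedRegulators <- function(expr) {
  out <- list()
  rec <- function(e, neg) {
    switch(e$type,
      var = out[[length(out) + 1L]] <<- c(e$name, if (neg) "-" else "+"),
      const = NULL,
      not = rec(e$arg, !neg),
      for (a in e$args) rec(a, neg))
    invisible(NULL)
  }
  rec(expr, FALSE)
  if (!length(out))
    return(data.frame(source = character(), sign = character(),
                      stringsAsFactors = FALSE))
  m <- do.call(rbind, out)
  df <- unique(data.frame(source = m[, 1L], sign = m[, 2L],
                          stringsAsFactors = FALSE))
  dual <- names(which(table(df$source) > 1L))
  if (length(dual)) {
    df <- df[!df$source %in% dual, , drop = FALSE]
    df <- rbind(df, data.frame(source = dual, sign = "+/-",
                               stringsAsFactors = FALSE))
  }
  df
}

## Compile a rule to the integer bytecode understood by the C++ engine.
compileRule <- function(expr, nodeIndex) {
  rec <- function(e) {
    switch(e$type,
      var = {
        idx <- nodeIndex[[e$name]]
        if (is.null(idx)) stop(sprintf("undeclared node '%s'", e$name))
        c(0L, idx - 1L)
      },
      const = c(1L, e$value),
      not = c(rec(e$arg), 2L),
      "and" = c(unlist(lapply(e$args, rec)), 3L, length(e$args)),
      "or" = c(unlist(lapply(e$args, rec)), 4L, length(e$args)))
  }
  rec(expr)
}

compileNetwork <- function(net) {
  idx <- setNames(seq_along(net@nodes), net@nodes)
  lapply(net@rules, compileRule, nodeIndex = idx)
}

#' Construct a Boolean network
#'
#' @param rules Named character vector (or named list of parsed expressions)
#'   of update rules, one per node; order defines the node order. A node
#'   whose rule is its own name is an input.
#' @param phenotypes Optional character vector of node names to annotate as
#'   phenotype (read-out) nodes.
#' @return A validated [BooleanNetwork][BooleanNetwork-class].
#' @examples
#' toggle <- booleanNetwork(c(A = "!B", B = "!A"))
#' nodeNames(toggle)
#' @export
booleanNetwork <- function(rules, phenotypes = character()) {
  if (is.null(names(rules)) || any(!nzchar(names(rules))))
    stop("rules must be a named vector/list", call. = FALSE)
  nodes <- names(rules)
  parsed <- lapply(seq_along(rules), function(i) {
    r <- rules[[i]]
    if (inherits(r, "logicExpr")) r else parseRule(r)
  })
  names(parsed) <- nodes
  kind <- vapply(nodes, function(nm) {
    e <- parsed[[nm]]
    if (nm %in% phenotypes) "phenotype"
    else if (e$type == "var" && e$name == nm) "input"
    else "internal"
  }, "")
  new("BooleanNetwork", nodes = nodes, rules = parsed, kind = kind)
}

#' @rdname nodeNames
#' @export
setMethod("nodeNames", "BooleanNetwork", function(x) x@nodes)

#' @rdname nodeKinds
#' @export
setMethod("nodeKinds", "BooleanNetwork", function(x) x@kind)

#' @rdname networkRules
#' @export
setMethod("networkRules", "BooleanNetwork", function(x) x@rules)

setMethod("show", "BooleanNetwork", function(object) {
  k <- table(factor(object@kind, c("input", "internal", "phenotype")))
  cat(sprintf("BooleanNetwork with %d nodes (%d inputs, %d internal, %d phenotypes)\n",
              length(object@nodes), k[["input"]], k[["internal"]],
              k[["phenotype"]]))
  shown <- utils::head(object@nodes, 5L)
  for (nm in shown)
    cat(sprintf("  %s <- %s\n", nm, renderRule(object@rules[[nm]])))
  if (length(object@nodes) > 5L)
    cat(sprintf("  ... and %d more rules\n", length(object@nodes) - 5L))
})

#' Derived influence graph of a network
#'
#' One edge per (regulator, target) pair occurring in the target's rule,
#' with the syntactically determined sign: `+` when the regulator appears
#' only under an even number of negations, `-` only under an odd number,
#' `+/-` when both occur.
#'
#' @param net A [BooleanNetwork][BooleanNetwork-class].
#' @param dropSelfInputs Drop the identity self-loop of input nodes
#'   (default TRUE).
#' @return Data frame with columns `source`, `target`, `sign`.
#' @export
influenceGraph <- function(net, dropSelfInputs = TRUE) {
  rows <- lapply(net@nodes, function(nm) {
    df <- signedRegulators(net@rules[[nm]])
    if (nrow(df) == 0L) return(NULL)
    df$target <- nm
    df
  })
  g <- do.call(rbind, rows)
  if (is.null(g))
    return(data.frame(source = character(), target = character(),
                      sign = character(), stringsAsFactors = FALSE))
  if (dropSelfInputs)
    g <- g[!(g$source == g$target & net@kind[g$target] == "input"), ,
           drop = FALSE]
  rownames(g) <- NULL
  g[, c("source", "target", "sign")]
}

#' Validate a Boolean network
#'
#' Produces a diagnostics report rather than raising errors: undeclared
#' regulators, duplicate node names, and phenotype nodes unreachable from
#' any input along the influence graph. An empty report (zero rows) means
#' the network is well-formed.
#'
#' @param net A [BooleanNetwork][BooleanNetwork-class] (validity of the S4
#'   object itself is not assumed).
#' @return Data frame with columns `finding`, `node`, `message`.
#' @export
#' @importFrom igraph graph_from_data_frame distances V
validateNetwork <- function(net) {
  findings <- list()
  add <- function(finding, node, message)
    findings[[length(findings) + 1L]] <<-
      data.frame(finding = finding, node = node, message = message,
                 stringsAsFactors = FALSE)

  dup <- unique(net@nodes[duplicated(net@nodes)])
  for (d in dup) add("duplicate_name", d, sprintf("node '%s' declared more than once", d))

  for (nm in unique(net@nodes)) {
    regs <- ruleRegulators(net@rules[[nm]])
    miss <- setdiff(regs, net@nodes)
    for (m in miss)
      add("undeclared_regulator", nm,
          sprintf("rule of '%s' references undeclared node '%s'", nm, m))
  }

  ## phenotype reachability from inputs (only meaningful if well-formed so far)
  if (length(findings) == 0L) {
    edges <- influenceGraph(net, dropSelfInputs = FALSE)
    inputs <- net@nodes[net@kind == "input"]
    phen <- net@nodes[net@kind == "phenotype"]
    if (length(inputs) && length(phen) && nrow(edges)) {
      g <- igraph::graph_from_data_frame(edges[, c("source", "target")],
                                         vertices = net@nodes)
      d <- igraph::distances(g, v = inputs, to = phen, mode = "out")
      unreachable <- phen[apply(d, 2L, function(col) all(!is.finite(col)))]
      for (u in unreachable)
        add("unreachable_phenotype", u,
            sprintf("phenotype node '%s' is not influenced by any input", u))
    }
  }

  if (length(findings) == 0L)
    return(data.frame(finding = character(), node = character(),
                      message = character(), stringsAsFactors = FALSE))
  do.call(rbind, findings)
}

#' Construct a complete network state
#'
#' @param net A [BooleanNetwork][BooleanNetwork-class].
#' @param active Character vector of nodes set to 1; all others are 0.
#' @return Named integer vector of 0/1 over all nodes.
#' @export
networkState <- function(net, active = character()) {
  unknown <- setdiff(active, net@nodes)
  if (length(unknown))
    stop(sprintf("unknown node(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  setNames(as.integer(net@nodes %in% active), net@nodes)
}

assertState <- function(net, state) {
  if (is.null(names(state)) || !setequal(names(state), net@nodes) ||
      length(state) != length(net@nodes))
    stop("state must assign every network node exactly once", call. = FALSE)
  if (!all(state %in% c(0L, 1L)))
    stop("state values must be 0 or 1", call. = FALSE)
  state[net@nodes]
}

## Truth table of one node's rule over its regulators; used by the
## equivalence checks in the I/O round-trip and the tests.
ruleTruthTable <- function(expr, regulators = NULL) {
  regs <- sort(ruleRegulators(expr))
  if (!is.null(regulators)) regs <- sort(unique(c(regs, regulators)))
  if (length(regs) == 0L)
    return(evaluateRule(expr, stats::setNames(integer(), character())))
  grid <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), length(regs)),
                                KEEP.OUT.ATTRS = FALSE))
  colnames(grid) <- regs
  as.integer(evaluateRuleStates(expr, grid))
}

#' Truth-table equivalence of two networks
#'
#' Networks are equivalent when they declare the same node set and each
#' node's rule has an identical truth table over the union of the two
#' regulator sets.
#'
#' @param a,b [BooleanNetwork][BooleanNetwork-class] objects.
#' @return TRUE or FALSE.
#' @export
equivalentNetworks <- function(a, b) {
  if (!setequal(a@nodes, b@nodes)) return(FALSE)
  for (nm in a@nodes) {
    regs <- union(ruleRegulators(a@rules[[nm]]), ruleRegulators(b@rules[[nm]]))
    if (!identical(ruleTruthTable(a@rules[[nm]], regs),
                   ruleTruthTable(b@rules[[nm]], regs)))
      return(FALSE)
  }
  TRUE
}
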