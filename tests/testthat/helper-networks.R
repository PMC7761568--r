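# Shared helpers: an independent rule-evaluation oracle (R's own parser and
# logical operators), a random expression generator for property tests, and
# small utilities used across the suite.

# Independent oracle: a rule string is valid R syntax (!, &, | are R
# operators), so R's parser/evaluator gives a second, independent route to
# the truth value.
oracleEvaluate <- function(ruleText, state) {
  env <- as.list(as.logical(state))
  names(env) <- names(state)
  env$`1` <- TRUE  # unused; constants handled below
  txt <- gsub("\\b1\\b", "TRUE", gsub("\\b0\\b", "FALSE", ruleText))
  as.integer(eval(parse(text = txt)[[1]], envir = env))
}

oracleTruthTable <- function(ruleText, vars) {
  if (length(vars) == 0) return(oracleEvaluate(ruleText, integer()))
  grid <- expand.grid(rep(list(0:1), length(vars)), KEEP.OUT.ATTRS = FALSE)
  names(grid) <- vars
  apply(grid, 1, function(row) oracleEvaluate(ruleText, row))
}

pkgTruthTable <- function(expr, vars) {
  if (length(vars) == 0)
    return(evaluateRule(expr, stats::setNames(integer(), character())))
  grid <- expand.grid(rep(list(0:1), length(vars)), KEEP.OUT.ATTRS = FALSE)
  names(grid) <- vars
  apply(grid, 1, function(row) evaluateRule(expr, row))
}

# Random rule string over a variable pool; depth-bounded.
randomRuleText <- function(vars, depth = 3) {
  pick <- function(d) {
    if (d <= 0 || runif(1) < 0.35) {
      if (runif(1) < 0.08) return(sample(c("0", "1"), 1))
      return(sample(vars, 1))
    }
    op <- sample(c("and", "or", "not"), 1)
    if (op == "not") return(paste0("!(", pick(d - 1), ")"))
    k <- sample(2:3, 1)
    args <- vapply(seq_len(k), function(i) pick(d - 1), "")
    paste0("(", paste(args, collapse = if (op == "and") " & " else " | "), ")")
  }
  pick(depth)
}

# Compare Monte-Carlo marginals p against exact values q: counts of
# comparisons outside the 3-SE and 5-SE bands (each with a 3-count Poisson
# slack for near-degenerate probabilities). With hundreds of comparisons a
# few 3-sigma exceedances are expected by chance; callers accumulate counts
# and require all within 5 SE and at least 99% within 3 SE.
marginalExceedances <- function(p, q, n) {
  se <- sqrt(pmax(q * (1 - q), 0) / n)  # q may carry ~1e-16 solver noise
  d <- abs(p - q)
  c(over3 = sum(d > 3 * se + 3 / n), over5 = sum(d > 5 * se + 5 / n),
    total = length(d))
}

expectDistributionsClose <- function(p, q, n) {
  ex <- marginalExceedances(p, q, n)
  expect_equal(unname(ex[["over3"]]), 0,
               label = sprintf("comparisons outside 3 SE (max |diff| %.4g)",
                               max(abs(p - q))))
}
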