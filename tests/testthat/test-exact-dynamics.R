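test_that("asynchronous successors flip exactly the disagreeing nodes", {
  tog <- networkFixture("toggle_switch")
  s00 <- networkState(tog)
  succ <- asyncSuccessors(tog, s00)
  expect_setequal(names(succ), c("A", "B"))
  expect_equal(succ$A, c(A = 1L, B = 0L))
  expect_equal(succ$B, c(A = 0L, B = 1L))
  expect_length(asyncSuccessors(tog, c(A = 1L, B = 0L)), 0)
  expect_true(isStableState(tog, c(A = 1L, B = 0L)))
})

test_that("successor sets equal per-node rule recomputation on random nets", {
  set.seed(5)
  for (seed in 1:6) {
    net <- randomNetwork(6, k = 2, scheme = "random-truth-table", seed = seed)
    for (rep in 1:5) {
      s <- setNames(sample(0:1, 6, replace = TRUE), nodeNames(net))
      succ <- asyncSuccessors(net, s)
      for (nm in nodeNames(net)) {
        v <- evaluateRule(networkRules(net)[[nm]], s)
        if (v != s[[nm]]) {
          expect_true(nm %in% names(succ))
          expect_equal(succ[[nm]][[nm]], v)
        } else {
          expect_false(nm %in% names(succ))
        }
      }
    }
  }
})

test_that("toggle switch and self-activator have the known fixed points", {
  expect_equal(rownames(fixedPoints(networkFixture("toggle_switch"))),
               c("01", "10"))
  expect_equal(rownames(fixedPoints(networkFixture("self_activator"))),
               c("0", "1"))
  expect_equal(nrow(fixedPoints(networkFixture("oscillator_2"))), 0)
})

test_that("constraint propagation equals exhaustive enumeration", {
  for (seed in 1:10) {
    scheme <- if (seed %% 2) "inhibitory-bias" else "random-truth-table"
    net <- randomNetwork(10, k = c(1, 3), scheme = scheme, seed = seed)
    expect_identical(fixedPoints(net),
                     fixedPoints(net, method = "exhaustive"),
                     label = sprintf("seed %d (%s)", seed, scheme))
  }
})

test_that("fixed points respect clamps and the exhaustive size limit", {
  tog <- networkFixture("toggle_switch")
  fp <- fixedPoints(tog, clamped = c(A = 1L))
  expect_equal(rownames(fp), "10")
  expect_error(fixedPoints(randomNetwork(30, k = 2, seed = 1),
                           method = "exhaustive", limit = 22),
               "exceeds limit")
})

test_that("attractors: stable states and the 4-state limit cycle", {
  tog <- networkFixture("toggle_switch")
  allStates <- as.matrix(expand.grid(A = 0:1, B = 0:1))
  at <- attractors(tog, allStates)
  expect_length(at, 2)
  expect_true(all(vapply(at, function(a) a@kind, "") == "stable_state"))

  osc <- networkFixture("oscillator_2")
  at2 <- attractors(osc, networkState(osc))
  expect_length(at2, 1)
  expect_equal(at2[[1]]@kind, "cyclic")
  expect_equal(nrow(at2[[1]]@states), 4)

  rep <- attractorReport(at2)
  expect_equal(rep$size, 4)
  expect_equal(rep$kind, "cyclic")
})

test_that("attractor states are closed under asynchronous successors", {
  for (seed in 1:5) {
    net <- randomNetwork(7, k = 2, scheme = "random-truth-table", seed = seed)
    init <- networkState(net, nodeNames(net)[c(1, 3)])
    atts <- attractors(net, init)
    expect_gte(length(atts), 1)
    for (a in atts) {
      keys <- rownames(a@states)
      for (i in seq_len(nrow(a@states))) {
        for (succ in asyncSuccessors(net, a@states[i, ])) {
          expect_true(paste(succ, collapse = "") %in% keys)
        }
      }
    }
  }
})

test_that("attractors are invariant to node declaration order", {
  rules <- c(A = "B", B = "!A", C = "A & B")
  net1 <- booleanNetwork(rules)
  net2 <- booleanNetwork(rules[c(3, 1, 2)])
  keyset <- function(net, init) {
    ats <- attractors(net, init)
    sort(vapply(ats, function(a)
      paste(sort(apply(a@states[, c("A", "B", "C"), drop = FALSE], 1, paste,
                       collapse = "")), collapse = ";"), ""))
  }
  expect_identical(keyset(net1, networkState(net1)),
                   keyset(net2, networkState(net2)))
})

test_that("single-node relaxation follows the closed-form exponential", {
  rel <- networkFixture("relaxation_1")
  sol <- ctmcDistribution(rel, c(X = 0L), times = c(0.5, 1, 2))
  expect_equal(unname(sol$marginals["X", ]), 1 - exp(-c(0.5, 1, 2)),
               tolerance = 1e-9)
  # at t = 1, to four decimals
  expect_equal(round(unname(sol$marginals["X", 2]), 4), 0.6321)
})

test_that("toggle switch from the uniform distribution splits evenly", {
  tog <- networkFixture("toggle_switch")
  st <- as.matrix(expand.grid(A = 0:1, B = 0:1))
  sol <- ctmcDistribution(tog, st, rep(0.25, 4), times = 50)
  expect_equal(unname(sol$probs["10", 1]), 0.5, tolerance = 1e-9)
  expect_equal(unname(sol$probs["01", 1]), 0.5, tolerance = 1e-9)
})

test_that("uniformization matches the matrix exponential to 1e-8", {
  for (seed in c(3, 42)) {
    net <- randomNetwork(5, k = 2, scheme = "random-truth-table", seed = seed)
    s0 <- networkState(net, nodeNames(net)[c(1, 3)])
    sol <- ctmcDistribution(net, s0, times = 2)
    sys <- icilogic:::reachableSystem(net, s0)
    n <- nrow(sys$states)
    Q <- matrix(0, n, n)
    for (r in seq_len(nrow(sys$edges)))
      Q[sys$edges[r, 1], sys$edges[r, 2]] <- Q[sys$edges[r, 1], sys$edges[r, 2]] + 1
    diag(Q) <- -rowSums(Q)
    p0 <- numeric(n); p0[1] <- 1
    pe <- as.vector(p0 %*% as.matrix(Matrix::expm(Matrix::Matrix(2 * Q))))
    expect_lt(max(abs(pe - sol$probs[, 1])), 1e-8)
  }
})

test_that("probability is conserved and stable states absorb monotonically", {
  net <- randomNetwork(6, k = 2, seed = 8)
  s0 <- networkState(net, nodeNames(net)[1:3])
  times <- c(0.1, 0.5, 1, 2, 5, 10)
  sol <- ctmcDistribution(net, s0, times = times)
  expect_true(all(abs(colSums(sol$probs) - 1) <= 1e-9))
  fp <- fixedPoints(net)
  stable <- intersect(rownames(fp), rownames(sol$probs))
  for (key in stable) {
    mass <- sol$probs[key, ]
    expect_true(all(diff(mass) >= -1e-9), label = sprintf("state %s", key))
  }
})

test_that("the reachable state-space limit is enforced", {
  net <- randomNetwork(12, k = 3, scheme = "random-truth-table", seed = 2)
  expect_error(
    ctmcDistribution(net, networkState(net), times = 1, limit = 16),
    "limit exceeded")
})
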