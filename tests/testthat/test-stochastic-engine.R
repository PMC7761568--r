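test_that("a constant activator jumps exactly once, at an Exp(1) time", {
  rel <- networkFixture("relaxation_1")
  cfg <- simulationConfig(tMax = 100, seed = 11L)
  times <- vapply(seq_len(20000), function(i) {
    p <- gillespieTrajectory(rel, c(X = 0L), cfg, streamIndex = i)
    expect_length(p$times, 1)
    p$times[[1]]
  }, 0)
  expect_equal(mean(times), 1.0, tolerance = 0.025)  # ~3 MC standard errors
})

test_that("a stable initial state yields zero jumps", {
  tog <- networkFixture("toggle_switch")
  p <- gillespieTrajectory(tog, c(A = 1L, B = 0L))
  expect_length(p$times, 0)
  expect_true(p$absorbed)
})

test_that("ensembles are bit-identical for a fixed seed", {
  tog <- networkFixture("toggle_switch")
  spec <- initialConditionSpec(tog, randomProb = c(A = 0.5, B = 0.5))
  cfg <- simulationConfig(nTrajectories = 400L, tMax = 10, seed = 99L)
  e1 <- simulateEnsemble(tog, spec, cfg)
  e2 <- simulateEnsemble(tog, spec, cfg)
  expect_identical(marginals(e1), marginals(e2))
  expect_identical(phenotypeJoint(e1), phenotypeJoint(e2))
  e3 <- simulateEnsemble(tog, spec,
                         simulationConfig(nTrajectories = 400L, tMax = 10,
                                          seed = 100L))
  expect_false(identical(marginals(e1), marginals(e3)))
})

test_that("the toggle switch relaxes to the symmetric split", {
  tog <- networkFixture("toggle_switch")
  spec <- initialConditionSpec(tog, randomProb = c(A = 0.5, B = 0.5))
  cfg <- simulationConfig(nTrajectories = 8000L, tMax = 30, seed = 2L)
  ens <- simulateEnsemble(tog, spec, cfg)
  final <- marginals(ens)[, ncol(marginals(ens))]
  se <- sqrt(0.25 / 8000)
  expect_true(all(abs(final - 0.5) <= 3 * se))
})

test_that("Gillespie ensembles match the exact CTMC oracle", {
  times <- c(0.5, 1, 2, 3.5, 5)
  n <- 10000L
  ex <- c(over3 = 0, over5 = 0, total = 0)
  for (seed in 1:6) {
    scheme <- if (seed %% 2) "random-truth-table" else "inhibitory-bias"
    net <- randomNetwork(6, k = 2, scheme = scheme, seed = seed)
    on <- nodeNames(net)[seq_len(3)]
    sol <- ctmcDistribution(net, networkState(net, on), times = times)
    cfg <- simulationConfig(nTrajectories = n, tMax = 5, seed = seed,
                            gridPoints = 11L)
    ens <- simulateEnsemble(net,
      initialConditionSpec(net, init = setNames(rep(1L, 3), on)), cfg)
    grid <- SummarizedExperiment::colData(ens)$time
    for (ti in seq_along(times)) {
      gi <- which.min(abs(grid - times[[ti]]))
      expect_equal(grid[[gi]], times[[ti]], tolerance = 1e-9)
      ex <- ex + marginalExceedances(marginals(ens)[, gi],
                                     sol$marginals[, ti], n)
    }
  }
  expect_equal(unname(ex[["over5"]]), 0)
  expect_lte(ex[["over3"]] / ex[["total"]], 0.01)
})

test_that("clamped inputs stay at their clamped value throughout", {
  net <- booleanNetwork(c(I = "I", A = "I & !B", B = "A"))
  spec <- initialConditionSpec(net, clamp = c(I = 1L))
  ens <- simulateEnsemble(net, spec,
                          simulationConfig(nTrajectories = 300L, tMax = 10,
                                           seed = 4L))
  expect_true(all(marginals(ens)["I", ] == 1))
  spec0 <- initialConditionSpec(net, clamp = c(I = 0L))
  ens0 <- simulateEnsemble(net, spec0,
                           simulationConfig(nTrajectories = 300L, tMax = 10,
                                            seed = 4L))
  expect_true(all(marginals(ens0)["I", ] == 0))
})

test_that("a forced node holds its forced value at every time point", {
  net <- buildTCellNetwork()
  cond <- tcellConditions()$PD1_L_only
  spec <- conditionInitialSpec(cond, net, list(perturbation("PD1", 0L)))
  ens <- simulateEnsemble(net, spec,
                          simulationConfig(nTrajectories = 500L, tMax = 20,
                                           seed = 6L))
  expect_true(all(marginals(ens)["PD1", ] == 0))
  specUp <- conditionInitialSpec(tcellConditions()$LAG3_L_only, net,
                                 list(perturbation("LAG3", 1L)))
  ensUp <- simulateEnsemble(net, specUp,
                            simulationConfig(nTrajectories = 500L, tMax = 20,
                                             seed = 6L))
  expect_true(all(marginals(ensUp)["LAG3", ] == 1))
})

test_that("doubling the ensemble size shrinks the standard error by ~sqrt(2)", {
  tog <- networkFixture("toggle_switch")
  spec <- initialConditionSpec(tog, randomProb = c(A = 0.5, B = 0.5))
  estimate <- function(n, seed) {
    cfg <- simulationConfig(nTrajectories = n, tMax = 15, seed = seed,
                            gridPoints = 10L)
    marginals(simulateEnsemble(tog, spec, cfg))["A", 10]
  }
  sdSmall <- sd(vapply(1:40, function(s) estimate(400L, 1000L + s), 0))
  sdBig <- sd(vapply(1:40, function(s) estimate(800L, 2000L + s), 0))
  expect_equal(sdSmall / sdBig, sqrt(2), tolerance = 0.2 * sqrt(2))
})

test_that("asymptotic phenotype distributions are normalized and labelled", {
  net <- booleanNetwork(c(I = "I", P = "I", Q = "I & P"),
                        phenotypes = c("P", "Q"))
  spec <- initialConditionSpec(net, clamp = c(I = 0L))
  ens <- simulateEnsemble(net, spec,
                          simulationConfig(nTrajectories = 200L, tMax = 10,
                                           seed = 3L))
  d <- asymptoticPhenotypes(ens)
  expect_equal(sum(categoryProbs(d)), 1, tolerance = 1e-12)
  # all trajectories end with every phenotype OFF
  expect_equal(unname(categoryProbs(d)[["None"]]), 1)
  expect_true(isConverged(d))

  specOn <- initialConditionSpec(net, clamp = c(I = 1L))
  ensOn <- simulateEnsemble(net, specOn,
                            simulationConfig(nTrajectories = 200L, tMax = 20,
                                             seed = 3L))
  dOn <- asymptoticPhenotypes(ensOn)
  expect_equal(unname(categoryProbs(dOn)[["P-Q"]]), 1)
})

test_that("non-convergence within the averaging window is flagged", {
  # a still-relaxing marginal: horizon comparable to the relaxation time
  net <- booleanNetwork(c(X = "1"), phenotypes = "X")
  ens <- simulateEnsemble(net, initialConditionSpec(net),
                          simulationConfig(nTrajectories = 4000L, tMax = 1,
                                           seed = 5L))
  expect_false(isConverged(asymptoticPhenotypes(ens)))
})

test_that("inhibition strength is the relative drop of the marginal", {
  mk <- function(p) {
    probs <- setNames(c(1 - p, p), c("None", "P"))
    new("PhenotypeDistribution", probs = probs,
        marginals = c(P = p), se = c(P = sqrt(p * (1 - p) / 10000)),
        nTrajectories = 10000L, converged = TRUE)
  }
  out <- inhibitionStrength(mk(0.30), mk(1.0), "P")
  expect_equal(out$percent, 70)
  expect_equal(inhibitionStrength(mk(0.4), mk(0.4), "P")$percent, 0)
  # activation is clipped in percent but kept raw
  act <- inhibitionStrength(mk(0.8), mk(0.4), "P")
  expect_equal(act$percent, 0)
  expect_lt(act$raw, 0)
  expect_error(inhibitionStrength(mk(0.5), mk(0), "P"), "zero baseline")
})
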