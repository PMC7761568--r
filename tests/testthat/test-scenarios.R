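test_that("the Th1/Treg ratio follows the guarded division", {
  mk <- function(th1, treg) {
    probs <- c(None = 1 - th1 - treg, Th1 = th1, Treg = treg)
    new("PhenotypeDistribution", probs = probs / sum(probs),
        marginals = c(Th1_CTL = th1, Treg = treg),
        se = c(Th1_CTL = 0.01, Treg = 0.01), nTrajectories = 1000L,
        converged = TRUE)
  }
  expect_equal(th1TregRatio(mk(0.6, 0.3)), 2.0)
  expect_equal(th1TregRatio(mk(0.25, 0.25)), 1.0)
  und <- th1TregRatio(mk(0.5, 0))
  expect_true(is.na(und))
  expect_true(attr(und, "undefined"))
})

test_that("compareDirections classifies changes against the SE band", {
  stats <- data.frame(
    treatment = c("none", "none", "trt", "trt"),
    statistic = c("x", "y", "x", "y"),
    value = c(0.2, 0.5, 0.5, 0.505),
    se = c(0.01, 0.01, 0.01, 0.01))
  exp <- data.frame(
    treatment = c("trt", "trt"),
    statistic = c("x", "y"),
    direction = c("up", "no_effect"))
  v <- compareDirections(stats, exp)
  expect_equal(v$verdict, c("PASS", "PASS"))
  # a clear change fails a no-effect expectation, and vice versa
  exp2 <- data.frame(treatment = "trt", statistic = "x",
                     direction = "no_effect")
  expect_equal(compareDirections(stats, exp2)$verdict, "FAIL")
  exp3 <- data.frame(treatment = "trt", statistic = "y", direction = "up")
  expect_equal(compareDirections(stats, exp3)$verdict, "FAIL")
})

test_that("intensity grades are checked as orderings, not magnitudes", {
  stats <- data.frame(
    treatment = c("none", "a", "b", "combo"),
    statistic = "x",
    value = c(0.1, 0.3, 0.25, 0.6),
    se = 0.005)
  exp <- data.frame(
    treatment = c("a", "b", "combo"),
    statistic = "x",
    direction = "up",
    grade = c(1L, 1L, 2L))
  v <- compareDirections(stats, exp)
  expect_equal(v$verdict, rep("PASS", 3))
  # the combination must beat both monotherapies
  stats$value[stats$treatment == "combo"] <- 0.28
  v2 <- compareDirections(stats, exp)
  expect_equal(v2$verdict[v2$treatment == "combo"], "FAIL")
})

test_that("sameAs expectations require equality within the band", {
  stats <- data.frame(
    treatment = c("none", "a", "combo"),
    statistic = "x",
    value = c(0.1, 0.4, 0.41),
    se = 0.01)
  exp <- data.frame(treatment = "combo", statistic = "x", direction = "up",
                    sameAs = "a")
  expect_equal(compareDirections(stats, exp)$verdict, "PASS")
  stats$value[3] <- 0.8
  expect_equal(compareDirections(stats, exp)$verdict, "FAIL")
})

cfgSmall <- simulationConfig(nTrajectories = 600L, seed = 42L)

test_that("scenario results are reproducible bit-for-bit for a fixed seed", {
  r1 <- singleCheckpointPanel(config = cfgSmall)
  r2 <- singleCheckpointPanel(config = cfgSmall)
  expect_identical(scenarioStats(r1), scenarioStats(r2))
  expect_identical(verdicts(r1), verdicts(r2))
})

test_that("the single-checkpoint panel reproduces the qualitative pattern", {
  r <- singleCheckpointPanel(config = cfgSmall)
  s <- scenarioStats(r)
  rowOf <- function(nm) s[s$condition == nm, ]
  # CTLA4 arrests proliferation and Th1 completely, Treg is retained
  expect_equal(rowOf("CTLA4")$prolif, 0)
  expect_equal(rowOf("CTLA4")$th1, 0)
  expect_gt(rowOf("CTLA4")$treg, 0.9)
  # partial checkpoints sit strictly between baseline and full arrest
  expect_true(rowOf("PD1")$prolifInhibitionPct > 0 &&
              rowOf("PD1")$prolifInhibitionPct < 100)
  expect_lt(rowOf("PD1")$prolifInhibitionPct,
            rowOf("CTLA4")$prolifInhibitionPct)
  # LAG3 ligand alone is inert; forcing the receptor inhibits
  expect_lt(abs(rowOf("LAG3_ligand")$prolifInhibitionRaw), 5)
  expect_gt(rowOf("LAG3_forced")$prolifInhibitionPct, 50)
  expect_true(all(verdicts(r)$verdict == "PASS"))
})

test_that("relieving the checkpoints never lowers the proliferation odds", {
  net <- buildTCellNetwork()
  conds <- tcellConditions()
  inhibitoryLigands <- c("CD80_86", "PD1_L", "TIGIT_L", "TIM3_L")
  for (nm in names(conds)) {
    cond <- conds[[nm]]
    relieved <- cond
    relieved@activeInputs <- setdiff(cond@activeInputs, inhibitoryLigands)
    relieved@initialActive <- setdiff(cond@initialActive, "LAG3_L")
    cfg <- simulationConfig(nTrajectories = 500L, seed = 7L)
    d <- asymptoticPhenotypes(simulateEnsemble(net,
      conditionInitialSpec(cond, net), cfg))
    d0 <- asymptoticPhenotypes(simulateEnsemble(net,
      conditionInitialSpec(relieved, net), cfg))
    p <- phenotypeMarginals(d)[["Proliferation_Survival"]]
    p0 <- phenotypeMarginals(d0)[["Proliferation_Survival"]]
    band <- 3 * sqrt(2 * 0.25 / 500)
    expect_gte(p0, p - band)
  }
})

test_that("the two-step protocol exposes the stage-specific treatment effects", {
  r <- twoStepProtocol(config = simulationConfig(nTrajectories = 4000L,
                                                 seed = 5L))
  v <- verdicts(r)
  expect_equal(nrow(v), 12)
  expect_true(all(v$verdict == "PASS"))
  s <- scenarioStats(r)
  val <- function(trt, stat) s$value[s$treatment == trt & s$statistic == stat]
  # untreated lymph node: arrested and Treg-dominated
  expect_equal(val("none", "prolif_LN"), 0)
  expect_gt(val("none", "treg_LN"), 0.9)
  # anti-CTLA4 restores clonal expansion in the LN only
  expect_gt(val("anti-CTLA4", "prolif_LN"), 0.9)
})

test_that("the cytokine panel reproduces the published modulation pattern", {
  r <- cytokinePanel(config = simulationConfig(nTrajectories = 1500L,
                                               seed = 6L))
  expect_true(all(verdicts(r)$verdict == "PASS"))
  s <- scenarioStats(r)
  val <- function(trt, stat) s$value[s$treatment == trt & s$statistic == stat]
  expect_gt(val("IFNG", "ratio"), val("none", "ratio"))
  expect_gt(val("IFNG", "mixed_treg_th1"), 0.1)
  expect_lt(val("IL27", "th1"), 0.02)
  expect_lt(val("IL27", "treg"), 0.02)
})

test_that("runScenario dispatches by name and rejects unknown names", {
  expect_error(runScenario("nope"), "unknown scenario")
  r <- runScenario("fig3_panel", config = cfgSmall)
  expect_s4_class(r, "ScenarioResult")
  expect_equal(r@scenario, "single_checkpoint_panel")
})
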