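net <- buildTCellNetwork()

test_that("the built network is well-formed with the expected catalogue", {
  expect_equal(nrow(validateNetwork(net)), 0)
  expect_length(nodeNames(net), 49)
  kinds <- nodeKinds(net)
  expect_equal(sum(kinds == "input"), 13)
  expect_setequal(names(kinds)[kinds == "phenotype"],
                  c("Proliferation_Survival", "Th1_CTL", "Treg"))
  expect_true(all(c("TCR", "CD28", "CTLA4", "PD1", "TIGIT", "CD226", "LAG3",
                    "TIM3", "ICOS", "TNFRs", "LCK_FYN", "SHP", "SHIP1",
                    "LAT", "Ca_NFAT", "MAPK", "NFkB", "PI3K", "AKT", "GSK3",
                    "FOXO1", "FOXP3", "Tbet", "STAT1", "STAT3", "STAT4",
                    "SMAD", "NFIL3", "MAF_PRDM1", "IL2") %in% nodeNames(net)))
})

test_that("the TCR rule is the canonical antigen/LCK_FYN/SHP conjunction", {
  expect_equal(renderRule(networkRules(net)$TCR), "Antigens & LCK_FYN & !SHP")
  expect_setequal(ruleRegulators(networkRules(net)$TCR),
                  c("Antigens", "LCK_FYN", "SHP"))
})

test_that("key influence edges carry the documented signs", {
  g <- influenceGraph(net)
  sgn <- function(src, tgt) g$sign[g$source == src & g$target == tgt]
  expect_equal(sgn("TIGIT", "SHIP1"), "+")
  expect_equal(sgn("SHIP1", "PI3K"), "-")
  # CTLA4 and FOXP3 form a positive feedback loop
  expect_equal(sgn("CTLA4", "FOXP3"), "+")
  expect_equal(sgn("FOXP3", "CTLA4"), "+")
  # CTLA4 outcompetes CD28 for CD80/86
  expect_equal(sgn("CTLA4", "CD28"), "-")
  # Tbet destabilises the LAG3 ligand and represses PD1
  expect_equal(sgn("Tbet", "LAG3_L"), "-")
  expect_equal(sgn("Tbet", "PD1"), "-")
  # TIM3 acts on TCR signalling through LCK_FYN
  expect_equal(sgn("TIM3", "LCK_FYN"), "-")
})

test_that("phenotype nodes have no outgoing influence", {
  g <- influenceGraph(net)
  phen <- names(nodeKinds(net))[nodeKinds(net) == "phenotype"]
  expect_length(intersect(g$source, phen), 0)
})

test_that("input nodes are constant along any trajectory", {
  cond <- tcellConditions()$TME
  spec <- conditionInitialSpec(cond, net)
  ens <- simulateEnsemble(net, spec,
                          simulationConfig(nTrajectories = 300L, tMax = 20,
                                           seed = 8L))
  inputs <- names(nodeKinds(net))[nodeKinds(net) == "input"]
  m <- marginals(ens)[inputs, ]
  expect_true(all(m == m[, 1]))
  expect_true(all(m[, 1] %in% c(0, 1)))
})

test_that("the condition catalogue encodes the documented contexts", {
  conds <- tcellConditions()
  pd1 <- conditionInitialSpec(conds$PD1_L_only, net)
  expect_equal(unname(pd1$clamp[["PD1_L"]]), 1L)
  expect_equal(unname(pd1$clamp[c("CD80_86", "TIGIT_L", "TIM3_L")]),
               c(0L, 0L, 0L))
  expect_equal(unname(pd1$clamp[["Antigens"]]), 1L)

  cd8 <- conditionInitialSpec(conds$CD8, net)
  expect_equal(unname(cd8$clamp[c("MHCI", "MHCII")]), c(1L, 0L))
  cd4 <- conditionInitialSpec(conds$CD4, net)
  expect_equal(unname(cd4$clamp[c("MHCI", "MHCII")]), c(0L, 1L))

  # CD28 axis engaged in the CD4+ TME; CTLA4 outside the TME repertoire
  tme4 <- conditionInitialSpec(conds$TME_CD4, net)
  expect_equal(unname(tme4$clamp[["CD80_86"]]), 1L)
  expect_equal(unname(tme4$clamp[["CTLA4"]]), 0L)
  # the CD8+ TME lacks CD80/86
  tme8 <- conditionInitialSpec(conds$TME_CD8, net)
  expect_equal(unname(tme8$clamp[["CD80_86"]]), 0L)
  # LN repertoire: CTLA4 axis present, effector checkpoints absent
  ln <- conditionInitialSpec(conds$LN, net)
  expect_equal(unname(ln$clamp[["CD80_86"]]), 1L)
  expect_equal(unname(ln$clamp[c("PD1", "TIGIT", "LAG3", "TIM3")]),
               rep(0L, 4))
  # the LAG3 ligand starts active but is free to decay
  lag <- conditionInitialSpec(conds$LAG3_L_only, net)
  expect_equal(unname(lag$init[["LAG3_L"]]), 1L)
  expect_equal(unname(lag$clamp[["LAG3_L"]]), -1L)
})

test_that("perturbations replace rules by constants on a copy", {
  p <- applyPerturbations(net, list(perturbation("PD1", 0L)))
  expect_equal(renderRule(networkRules(p)$PD1), "0")
  expect_equal(renderRule(networkRules(net)$PD1), "PD1_L & FOXO1 & !Tbet")

  up <- applyPerturbations(net, list(perturbation("LAG3", 1L)))
  expect_equal(renderRule(networkRules(up)$LAG3), "1")

  same <- applyPerturbations(net, list())
  expect_true(equivalentNetworks(same, net))

  expect_error(applyPerturbations(net, list(perturbation("NOPE", 0L))),
               "unknown node")
  expect_error(applyPerturbations(net, list(perturbation("PD1", 0L),
                                            perturbation("PD1", 1L))),
               "conflicting")
})

test_that("fixed points per condition reflect the commitment structure", {
  conds <- tcellConditions()
  clampOf <- function(cond) {
    s <- conditionInitialSpec(cond, net)$clamp
    s[s >= 0]
  }
  # without checkpoints the only stable state is full activation
  fp0 <- fixedPoints(net, clamped = clampOf(conds$no_checkpoint))
  expect_equal(nrow(fp0), 1)
  expect_equal(unname(fp0[1, "Proliferation_Survival"]), 1L)
  expect_equal(unname(fp0[1, "Treg"]), 0L)
  # with CD80/86 present every stable state is arrested and Treg-committed
  fpC <- fixedPoints(net, clamped = clampOf(conds$CD80_86_only))
  expect_gte(nrow(fpC), 1)
  expect_true(all(fpC[, "Proliferation_Survival"] == 0))
  expect_true(all(fpC[, "Th1_CTL"] == 0))
  expect_true(all(fpC[, "Treg"] == 1))
  # PD1 ligation makes the system bistable: arrest and escape coexist
  fpP <- fixedPoints(net, clamped = clampOf(conds$PD1_L_only))
  expect_true(any(fpP[, "Proliferation_Survival"] == 1))
  expect_true(any(fpP[, "Treg"] == 1))
})
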