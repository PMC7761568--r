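## In-silico experiments as reproducible protocols. Every scenario derives
## one deterministic substream seed per simulated condition from the config
## seed, runs the stochastic engine, reads out asymptotic phenotype
## distributions, and compares derived statistics against the published
## qualitative expectations ("up", "down", "no effect", with intensity
## grades treated as orderings within a table).

scenarioRun <- function(net, cond, perturbations, config, runIndex) {
  spec <- conditionInitialSpec(cond, net, perturbations)
  cfg <- config
  cfg@seed <- as.numeric(cpp_mix_seed(config@seed, runIndex))
  asymptoticPhenotypes(simulateEnsemble(net, spec, cfg))
}

distRow <- function(dist) {
  m <- dist@marginals
  s <- dist@se
  c(prolif = m[["Proliferation_Survival"]], th1 = m[["Th1_CTL"]],
    treg = m[["Treg"]], prolif_se = s[["Proliferation_Survival"]],
    th1_se = s[["Th1_CTL"]], treg_se = s[["Treg"]])
}

## ratio with explicit +Inf when the denominator vanishes but the numerator
## does not; NA when both vanish
ratioStat <- function(a, b, sea, seb, eps = 1e-6) {
  if (b < eps) {
    if (a < eps) return(c(value = NA_real_, se = 0))
    return(c(value = Inf, se = 0))
  }
  r <- a / b
  se <- r * sqrt((sea / max(a, eps))^2 + (seb / b)^2)
  c(value = r, se = se)
}

#' Th1/Treg balance of a phenotype distribution
#'
#' The balance between anti-tumour and pro-tumour response, as the ratio of
#' the Th1_CTL and Treg marginal probabilities. When the Treg marginal is
#' below `eps` the ratio is reported as undefined (`NA` with attribute
#' `undefined = TRUE`) rather than a number.
#'
#' @param dist A [PhenotypeDistribution][PhenotypeDistribution-class], or a
#'   named numeric vector with entries `Th1_CTL` and `Treg`.
#' @param eps Degeneracy threshold for the Treg marginal (default 1e-6).
#' @return Numeric ratio, or `NA` flagged with `attr(, "undefined")`.
#' @export
th1TregRatio <- function(dist, eps = 1e-6) {
  m <- if (is(dist, "PhenotypeDistribution")) dist@marginals else dist
  treg <- m[["Treg"]]
  if (treg < eps) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    attr(out, "reason") <- "undefined (Treg ~ 0)"
    return(out)
  }
  m[["Th1_CTL"]] / treg
}

#' Compare simulated changes against directional expectations
#'
#' For every expectation the change of a statistic between a treatment and
#' its baseline is classified: `up` passes when the change exceeds
#' `seFactor` combined Monte-Carlo standard errors, `down` symmetrically,
#' and `no_effect` passes when the absolute change stays within that bound.
#' A `sameAs` reference passes when the statistic is within the bound of the
#' referenced treatment. Intensity grades are treated as orderings only:
#' a grade-2 expectation additionally requires its change to exceed the
#' change of every lower-grade expectation on the same statistic.
#'
#' @param stats Data frame with columns `treatment`, `statistic`, `value`,
#'   `se`.
#' @param expectations Data frame with columns `treatment`, `statistic`,
#'   `direction` (`up`/`down`/`no_effect`), and optionally `grade`
#'   (default 1), `baseline` (default `"none"`) and `sameAs`.
#' @param seFactor Width of the no-effect band in combined standard errors
#'   (default 3).
#' @return The expectations with columns `observedChange` and `verdict`
#'   (`"PASS"`/`"FAIL"`) appended.
#' @export
compareDirections <- function(stats, expectations, seFactor = 3) {
  if (is.null(expectations$grade)) expectations$grade <- 1L
  if (is.null(expectations$baseline)) expectations$baseline <- "none"
  if (is.null(expectations$sameAs)) expectations$sameAs <- NA_character_
  key <- function(trt, stat) paste(trt, stat, sep = "\r")
  lut <- setNames(seq_len(nrow(stats)), key(stats$treatment, stats$statistic))
  getVal <- function(trt, stat) {
    i <- lut[[key(trt, stat)]]
    if (is.null(i)) stop(sprintf("no statistic '%s' for treatment '%s'",
                                 stat, trt), call. = FALSE)
    c(stats$value[[i]], stats$se[[i]])
  }
  delta <- function(trt, stat, base) {
    v <- getVal(trt, stat); v0 <- getVal(base, stat)
    d <- v[1L] - v0[1L]
    if (is.infinite(v[1L]) && is.infinite(v0[1L])) d <- 0
    c(d, sqrt(v[2L]^2 + v0[2L]^2))
  }
  changes <- numeric(nrow(expectations))
  verdict <- character(nrow(expectations))
  for (i in seq_len(nrow(expectations))) {
    e <- expectations[i, ]
    d <- delta(e$treatment, e$statistic, e$baseline)
    changes[[i]] <- d[1L]
    band <- seFactor * d[2L]
    ok <- switch(e$direction,
      up = isTRUE(d[1L] > band),
      down = isTRUE(d[1L] < -band),
      no_effect = isTRUE(abs(d[1L]) <= band) || is.na(d[1L]),
      stop(sprintf("unknown direction '%s'", e$direction), call. = FALSE))
    if (ok && !is.na(e$sameAs)) {
      v <- getVal(e$treatment, e$statistic)
      vr <- getVal(e$sameAs, e$statistic)
      ok <- abs(v[1L] - vr[1L]) <= seFactor * sqrt(v[2L]^2 + vr[2L]^2)
    }
    verdict[[i]] <- if (ok) "PASS" else "FAIL"
  }
  ## intensity orderings within a statistic
  for (i in seq_len(nrow(expectations))) {
    e <- expectations[i, ]
    if (e$grade <= 1L || verdict[[i]] == "FAIL") next
    lower <- which(expectations$statistic == e$statistic &
                   expectations$grade < e$grade)
    if (length(lower) && !all(changes[[i]] > changes[lower] |
                              is.na(changes[lower])))
      verdict[[i]] <- "FAIL"
  }
  expectations$observedChange <- changes
  expectations$verdict <- verdict
  expectations
}

setMethod("show", "ScenarioResult", function(object) {
  cat(sprintf("ScenarioResult '%s' (%d conditions, seed %g)\n",
              object@scenario, length(object@distributions), object@seedUsed))
  if (nrow(object@verdicts)) {
    pass <- sum(object@verdicts$verdict == "PASS")
    cat(sprintf("  verdicts: %d/%d PASS\n", pass, nrow(object@verdicts)))
  }
})

#' @rdname verdicts
#' @export
setMethod("verdicts", "ScenarioResult", function(x) x@verdicts)

#' @rdname scenarioStats
#' @export
setMethod("scenarioStats", "ScenarioResult", function(x) x@stats)

## ---- single-checkpoint panel ------------------------------------------------

#' Single-checkpoint inhibition panel
#'
#' Simulates a generic T cell with each inhibitory-checkpoint ligand
#' activated one by one (plus the no-checkpoint baseline and the
#' LAG3-overexpression control) and reports the asymptotic phenotype
#' distributions and inhibition strengths relative to the baseline. Treg
#' retention is additionally reported relative to the full checkpoint
#' arrest of the CTLA4 (CD80_86-only) condition, in which the Treg
#' phenotype is fully retained.
#'
#' @param net The network (default: built-in T-cell model).
#' @param config A [simulationConfig()].
#' @return A [ScenarioResult][ScenarioResult-class]; `scenarioStats()` has
#'   one row per condition with phenotype probabilities and inhibition
#'   strengths, `verdicts()` checks the qualitative claims (complete CTLA4
#'   arrest, inactive LAG3 ligand, active forced LAG3).
#' @export
singleCheckpointPanel <- function(net = buildTCellNetwork(),
                                  config = simulationConfig()) {
  conds <- tcellConditions()
  runs <- list(
    baseline = list(conds$no_checkpoint, list()),
    CTLA4 = list(conds$CD80_86_only, list()),
    PD1 = list(conds$PD1_L_only, list()),
    TIGIT = list(conds$TIGIT_L_only, list()),
    TIM3 = list(conds$TIM3_L_only, list()),
    LAG3_ligand = list(conds$LAG3_L_only, list()),
    LAG3_forced = list(conds$LAG3_L_only, list(perturbation("LAG3", 1L))))
  dists <- list()
  for (i in seq_along(runs))
    dists[[names(runs)[[i]]]] <-
      scenarioRun(net, runs[[i]][[1L]], runs[[i]][[2L]], config, i)

  base <- dists$baseline
  rows <- lapply(names(dists), function(nm) {
    d <- dists[[nm]]
    r <- distRow(d)
    inh <- if (nm == "baseline") list(percent = 0, raw = 0, se = 0)
           else inhibitionStrength(d, base, "Proliferation_Survival")
    data.frame(condition = nm, prolif = r[["prolif"]], th1 = r[["th1"]],
               treg = r[["treg"]], prolifInhibitionPct = inh$percent,
               prolifInhibitionRaw = inh$raw, prolifInhibitionSE = inh$se,
               converged = d@converged, stringsAsFactors = FALSE)
  })
  stats <- do.call(rbind, rows)
  ## Treg retention relative to the fully arrested CTLA4 condition
  tregFull <- stats$treg[stats$condition == "CTLA4"]
  stats$tregRetentionPct <- 100 * stats$treg / tregFull
  stats$tregReductionPct <- 100 - stats$tregRetentionPct

  long <- data.frame(
    treatment = rep(stats$condition, 2L),
    statistic = rep(c("prolif", "th1"), each = nrow(stats)),
    value = c(stats$prolif, stats$th1),
    se = c(vapply(dists, function(d) d@se[["Proliferation_Survival"]], 0),
           vapply(dists, function(d) d@se[["Th1_CTL"]], 0)),
    stringsAsFactors = FALSE)
  exp <- data.frame(
    treatment = c("CTLA4", "CTLA4", "PD1", "TIGIT", "TIM3",
                  "LAG3_ligand", "LAG3_forced"),
    statistic = c("prolif", "th1", "prolif", "prolif", "prolif",
                  "prolif", "prolif"),
    direction = c("down", "down", "down", "down", "down",
                  "no_effect", "down"),
    baseline = "baseline",
    stringsAsFactors = FALSE)
  v <- compareDirections(long, exp)
  ## complete arrest under CTLA4: the phenotype probabilities are exactly 0
  v$verdict[v$treatment == "CTLA4" & v$statistic == "prolif"] <-
    if (stats$prolif[stats$condition == "CTLA4"] == 0) "PASS" else "FAIL"
  v$verdict[v$treatment == "CTLA4" & v$statistic == "th1"] <-
    if (stats$th1[stats$condition == "CTLA4"] == 0) "PASS" else "FAIL"

  new("ScenarioResult", scenario = "single_checkpoint_panel",
      distributions = dists, stats = stats, verdicts = v,
      seedUsed = config@seed)
}

## ---- two-step LN -> TME protocol --------------------------------------------

twoStepStats <- function(net, lnCond, tmeCond, treatments, config,
                         runOffset = 0L, label = identity) {
  rows <- list()
  dists <- list()
  i <- runOffset
  for (trtName in names(treatments)) {
    perts <- treatments[[trtName]]
    dLN <- scenarioRun(net, lnCond, perts, config, i <- i + 1L)
    dTME <- scenarioRun(net, tmeCond, perts, config, i <- i + 1L)
    dists[[label(paste0(trtName, "/LN"))]] <- dLN
    dists[[label(paste0(trtName, "/TME"))]] <- dTME
    ln <- distRow(dLN); tme <- distRow(dTME)
    rLN <- ratioStat(ln[["th1"]], ln[["treg"]], ln[["th1_se"]], ln[["treg_se"]])
    rTME <- ratioStat(tme[["th1"]], tme[["treg"]], tme[["th1_se"]],
                      tme[["treg_se"]])
    ## combined two-step read-out: expansion in the LN gates the TME response
    comb <- function(p, pse) {
      v <- ln[["prolif"]] * p
      se <- sqrt((ln[["prolif_se"]] * p)^2 + (ln[["prolif"]] * pse)^2)
      c(v, se)
    }
    cp <- comb(tme[["prolif"]], tme[["prolif_se"]])
    cth <- comb(tme[["th1"]], tme[["th1_se"]])
    ctr <- comb(tme[["treg"]], tme[["treg_se"]])
    add <- function(stat, value, se)
      rows[[length(rows) + 1L]] <<-
        data.frame(treatment = label(trtName), statistic = stat,
                   value = value, se = se, stringsAsFactors = FALSE)
    add("prolif_LN", ln[["prolif"]], ln[["prolif_se"]])
    add("th1_LN", ln[["th1"]], ln[["th1_se"]])
    add("treg_LN", ln[["treg"]], ln[["treg_se"]])
    add("ratio_LN", rLN[["value"]], rLN[["se"]])
    add("prolif_TME", tme[["prolif"]], tme[["prolif_se"]])
    add("th1_TME", tme[["th1"]], tme[["th1_se"]])
    add("treg_TME", tme[["treg"]], tme[["treg_se"]])
    add("ratio_TME", rTME[["value"]], rTME[["se"]])
    add("prolif_combined", cp[1L], cp[2L])
    add("th1_combined", cth[1L], cth[2L])
    add("treg_combined", ctr[1L], ctr[2L])
  }
  list(stats = do.call(rbind, rows), dists = dists, nextRun = i)
}

defaultTherapies <- function() {
  list(none = list(),
       `anti-CTLA4` = treatmentPerturbations("anti-CTLA4"),
       `anti-PD1` = treatmentPerturbations("anti-PD1"),
       `anti-PD1+anti-CTLA4` =
         treatmentPerturbations("anti-PD1+anti-CTLA4"))
}

#' Directional expectations for the two-step therapy comparison
#'
#' Three therapies by four read-outs (LN proliferation, LN Th1/Treg ratio,
#' TME proliferation, TME Th1/Treg ratio): anti-CTLA4 acts in the lymph
#' node only, anti-PD1 in the tumour microenvironment only, and the
#' combination in both.
#'
#' @return Expectations data frame for [compareDirections()].
#' @export
table3Expectations <- function() {
  data.frame(
    treatment = rep(c("anti-CTLA4", "anti-PD1", "anti-PD1+anti-CTLA4"),
                    each = 4L),
    statistic = rep(c("prolif_LN", "ratio_LN", "prolif_TME", "ratio_TME"), 3L),
    direction = c("up", "up", "no_effect", "no_effect",
                  "no_effect", "no_effect", "up", "up",
                  "up", "up", "up", "up"),
    baseline = "none",
    stringsAsFactors = FALSE)
}

#' Two-step lymph-node/tumour activation protocol
#'
#' T-cell response simulated as two independent stages with their own
#' checkpoint repertoires: priming and clonal expansion in the lymph node
#' (CTLA4, ICOS, TNFRs active) and effector response in the tumour
#' microenvironment (ICOS, TNFRs, PD1, TIGIT, LAG3, TIM3 active). Each
#' treatment forces its target checkpoints to 0 in both stages (a no-op in
#' the stage where the target is not expressed). The combined read-out of a
#' phenotype is `P_LN(Proliferation_Survival) * P_TME(phenotype)`:
#' inefficient priming gates the response in the tumour bed.
#'
#' @param net The network.
#' @param treatments Named list of perturbation lists; default: untreated,
#'   anti-CTLA4, anti-PD1, and the combination.
#' @param lnCond,tmeCond Stage conditions (catalogue names or
#'   [CellCondition][CellCondition-class] objects).
#' @param config A [simulationConfig()].
#' @param expectations Directional expectations (default
#'   [table3Expectations()]).
#' @return A [ScenarioResult][ScenarioResult-class] with per-stage
#'   distributions, per-stage and combined statistics, and the verdict
#'   table.
#' @export
twoStepProtocol <- function(net = buildTCellNetwork(),
                            treatments = defaultTherapies(),
                            lnCond = "LN", tmeCond = "TME",
                            config = simulationConfig(),
                            expectations = table3Expectations()) {
  conds <- tcellConditions()
  if (is.character(lnCond)) lnCond <- conds[[lnCond]]
  if (is.character(tmeCond)) tmeCond <- conds[[tmeCond]]
  res <- twoStepStats(net, lnCond, tmeCond, treatments, config)
  v <- compareDirections(res$stats, expectations)
  new("ScenarioResult", scenario = "two_step_protocol",
      distributions = res$dists, stats = res$stats, verdicts = v,
      seedUsed = config@seed)
}

#' Expected treatment responses of CD8+ cells and PD1/CTLA4 subpopulations
#'
#' Monotherapies are judged in the stage where their target is engaged
#' (anti-CTLA4 in the LN, anti-PD1 in the TME); combination rows carry
#' grade 2 and are judged as orderings on the combined two-step read-out.
#' The PD1+CTLA4- subpopulation has CTLA4 forced to 0 in both stages; in
#' the PD1+CTLA4+ subpopulation CTLA4 is expressed and engaged in the LN
#' (its ligand is absent from the CD8+ TME).
#'
#' @return Expectations data frame for [compareDirections()].
#' @export
table2Expectations <- function() {
  rows <- function(subpop, treatment, statistic, direction, grade = 1L,
                   sameAs = NA_character_)
    data.frame(treatment = paste0(subpop, "/", treatment),
               statistic = paste0(subpop, "/", statistic),
               direction = direction, grade = grade,
               baseline = paste0(subpop, "/none"),
               sameAs = if (is.na(sameAs)) NA_character_
                        else paste0(subpop, "/", sameAs),
               stringsAsFactors = FALSE)
  rbind(
    rows("total", "anti-CTLA4", "prolif_LN", "up"),
    rows("total", "anti-CTLA4", "th1_LN", "up"),
    rows("total", "anti-PD1", "prolif_TME", "up"),
    rows("total", "anti-PD1", "th1_TME", "up"),
    rows("total", "anti-PD1+anti-CTLA4", "prolif_combined", "up", grade = 2L),
    rows("total", "anti-PD1+anti-CTLA4", "th1_combined", "up", grade = 2L),
    rows("PD1+CTLA4-", "anti-CTLA4", "prolif_LN", "no_effect"),
    rows("PD1+CTLA4-", "anti-PD1", "prolif_TME", "up"),
    rows("PD1+CTLA4-", "anti-PD1+anti-CTLA4", "prolif_combined", "up",
         sameAs = "anti-PD1"),
    rows("PD1+CTLA4+", "anti-CTLA4", "prolif_LN", "up"),
    rows("PD1+CTLA4+", "anti-PD1", "prolif_TME", "up"),
    rows("PD1+CTLA4+", "anti-PD1+anti-CTLA4", "prolif_combined", "up",
         grade = 2L))
}

## grade-2 orderings must compare changes of the same statistic within one
## subpopulation and against grade-1 rows of other statistics of the same
## phenotype; the statistics are therefore prefixed per subpopulation and
## the combined rows compare against the monotherapies' combined change,
## which compareDirections resolves through the shared statistic name. To
## make the ordering comparison meaningful the monotherapies' combined
## read-outs are included as hidden grade-1 expectations.
table2HiddenOrderingRows <- function() {
  rows <- function(subpop, treatment, statistic)
    data.frame(treatment = paste0(subpop, "/", treatment),
               statistic = paste0(subpop, "/", statistic),
               direction = "up", grade = 1L,
               baseline = paste0(subpop, "/none"), sameAs = NA_character_,
               hidden = TRUE, stringsAsFactors = FALSE)
  rbind(
    rows("total", "anti-CTLA4", "prolif_combined"),
    rows("total", "anti-PD1", "prolif_combined"),
    rows("total", "anti-CTLA4", "th1_combined"),
    rows("total", "anti-PD1", "th1_combined"),
    rows("PD1+CTLA4+", "anti-CTLA4", "prolif_combined"),
    rows("PD1+CTLA4+", "anti-PD1", "prolif_combined"))
}

#' CD8+ treatment-response scenario with PD1/CTLA4 subpopulations
#'
#' Runs the two-step protocol for CD8+ cells for the total population and
#' the PD1+CTLA4- and PD1+CTLA4+ subpopulations under anti-CTLA4, anti-PD1
#' and the combination, and compares the responses against the expected
#' directions (see [table2Expectations()]).
#'
#' @param net The network.
#' @param config A [simulationConfig()].
#' @return A [ScenarioResult][ScenarioResult-class].
#' @export
cd8TreatmentScenario <- function(net = buildTCellNetwork(),
                                 config = simulationConfig()) {
  conds <- tcellConditions()
  subpops <- list(
    "total" = list(),
    "PD1+CTLA4-" = list(perturbation("CTLA4", 0L)),
    "PD1+CTLA4+" = list())
  allStats <- list(); allDists <- list(); off <- 0L
  for (sp in names(subpops)) {
    treatments <- lapply(defaultTherapies(), function(p)
      c(p, subpops[[sp]]))
    res <- twoStepStats(net, conds$LN_CD8, conds$TME_CD8, treatments, config,
                        runOffset = off,
                        label = function(x) paste0(sp, "/", x))
    res$stats$statistic <- paste0(sp, "/", res$stats$statistic)
    allStats[[sp]] <- res$stats
    allDists <- c(allDists, res$dists)
    off <- res$nextRun
  }
  stats <- do.call(rbind, allStats)
  exp <- table2Expectations()
  exp$hidden <- FALSE
  v <- compareDirections(stats, rbind(exp, table2HiddenOrderingRows()))
  v <- v[!v$hidden, setdiff(names(v), "hidden")]
  new("ScenarioResult", scenario = "cd8_treatment_response",
      distributions = allDists, stats = stats, verdicts = v,
      seedUsed = config@seed)
}

## ---- cytokine panel ----------------------------------------------------------

#' Cytokine modulation panel on CD4+ effector cells
#'
#' Simulates the CD4+ tumour-microenvironment condition without cytokines
#' and with each of IFNG, IL12, IL27 and TGFb individually, and reports the
#' phenotype distributions, Th1/Treg ratios and the probability of the
#' mixed Treg-Th1 category. Expected behaviour: IFNG and IL12 raise the
#' Th1/Treg ratio and produce the mixed Treg-Th1 phenotype, TGFb changes
#' nothing, and IL27 alone blocks both the Th1 and the Treg phenotype.
#'
#' @param net The network.
#' @param cond CD4+ condition (catalogue name or
#'   [CellCondition][CellCondition-class]; default `"TME_CD4"`).
#' @param cytokines Cytokines to test one by one.
#' @param config A [simulationConfig()].
#' @return A [ScenarioResult][ScenarioResult-class].
#' @export
cytokinePanel <- function(net = buildTCellNetwork(), cond = "TME_CD4",
                          cytokines = c("IFNG", "IL12", "IL27", "TGFb"),
                          config = simulationConfig()) {
  conds <- tcellConditions()
  if (is.character(cond)) cond <- conds[[cond]]
  bad <- setdiff(cytokines, c("IFNG", "IL12", "IL27", "TGFb"))
  if (length(bad))
    stop(sprintf("unknown cytokine(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  settings <- c(list(none = character()),
                setNames(as.list(cytokines), cytokines))
  dists <- list()
  rows <- list()
  mixedLabel <- "Th1_CTL-Treg"
  for (i in seq_along(settings)) {
    nm <- names(settings)[[i]]
    c2 <- cond
    c2@activeInputs <- unique(c(cond@activeInputs, settings[[i]]))
    c2@name <- paste0(cond@name, if (nzchar(nm) && nm != "none")
      paste0("+", nm) else "")
    d <- scenarioRun(net, c2, list(), config, i)
    dists[[nm]] <- d
    r <- distRow(d)
    rr <- ratioStat(r[["th1"]], r[["treg"]], r[["th1_se"]], r[["treg_se"]])
    mixed <- if (mixedLabel %in% names(d@probs)) d@probs[[mixedLabel]] else 0
    n <- d@nTrajectories
    add <- function(stat, value, se)
      rows[[length(rows) + 1L]] <<-
        data.frame(treatment = nm, statistic = stat, value = value, se = se,
                   stringsAsFactors = FALSE)
    add("prolif", r[["prolif"]], r[["prolif_se"]])
    add("th1", r[["th1"]], r[["th1_se"]])
    add("treg", r[["treg"]], r[["treg_se"]])
    add("ratio", rr[["value"]], rr[["se"]])
    add("mixed_treg_th1", mixed, sqrt(max(mixed * (1 - mixed), 0) / n))
  }
  stats <- do.call(rbind, rows)
  exp <- data.frame(
    treatment = c("IFNG", "IFNG", "IL12", "IL12",
                  "TGFb", "TGFb", "TGFb",
                  "IL27", "IL27"),
    statistic = c("ratio", "mixed_treg_th1", "ratio", "mixed_treg_th1",
                  "prolif", "th1", "treg",
                  "th1", "treg"),
    direction = c("up", "up", "up", "up",
                  "no_effect", "no_effect", "no_effect",
                  "down", "down"),
    baseline = "none",
    stringsAsFactors = FALSE)
  v <- compareDirections(stats, exp)
  ## IL27 blocks both differentiation phenotypes outright
  for (stat in c("th1", "treg")) {
    i <- which(v$treatment == "IL27" & v$statistic == stat)
    val <- stats$value[stats$treatment == "IL27" & stats$statistic == stat]
    if (v$verdict[[i]] == "PASS" && val > 0.02) v$verdict[[i]] <- "FAIL"
  }
  new("ScenarioResult", scenario = "cytokine_panel", distributions = dists,
      stats = stats, verdicts = v, seedUsed = config@seed)
}

#' Run a named scenario
#'
#' @param name One of `"fig3_panel"` (single-checkpoint panel),
#'   `"table3_two_step"`, `"table2_cd8"`, `"fig4_cytokines"`, or `"all"`.
#' @param net The network.
#' @param config A [simulationConfig()].
#' @return A [ScenarioResult][ScenarioResult-class], or a named list of
#'   them for `"all"`.
#' @export
runScenario <- function(name, net = buildTCellNetwork(),
                        config = simulationConfig()) {
  known <- c("fig3_panel", "table3_two_step", "table2_cd8", "fig4_cytokines",
             "all")
  if (!name %in% known)
    stop(sprintf("unknown scenario '%s'; known: %s", name,
                 paste(known, collapse = ", ")), call. = FALSE)
  if (name == "all") {
    out <- lapply(setdiff(known, "all"), runScenario, net = net,
                  config = config)
    names(out) <- setdiff(known, "all")
    return(out)
  }
  switch(name,
    fig3_panel = singleCheckpointPanel(net, config),
    table3_two_step = twoStepProtocol(net, config = config),
    table2_cd8 = cd8TreatmentScenario(net, config),
    fig4_cytokines = cytokinePanel(net, config = config))
}
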