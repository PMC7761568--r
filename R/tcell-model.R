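## The T-cell activation network: TCR signalling modulated by inhibitory
## (PD1, CTLA4, TIGIT, LAG3, TIM3) and activating (CD226, ICOS, TNFRs)
## immune checkpoints and by cytokines (IFNG, IL12, IL27, TGFb), read out on
## three phenotypes (Proliferation_Survival, Th1_CTL, Treg). Rules follow
## the inhibitory bias: any active inhibitor vetoes activation (inhibitors
## enter as AND NOT), alternative activators combine with OR, obligatory
## partners with AND.

tcellRuleTable <- function() {
  c(
    ## ligand and cytokine inputs (identity rules; clamped per condition)
    Antigens = "Antigens",
    MHCI     = "MHCI",
    MHCII    = "MHCII",
    CD80_86  = "CD80_86",
    PD1_L    = "PD1_L",
    TIGIT_L  = "TIGIT_L",
    TIM3_L   = "TIM3_L",
    ICOS_L   = "ICOS_L",
    TNFRs_L  = "TNFRs_L",
    IFNG     = "IFNG",
    IL12     = "IL12",
    IL27     = "IL27",
    TGFb     = "TGFb",
    ## LAG3 ligand expression is unstable: lost, irreversibly, once the Tbet
    ## effector program is engaged; set active by the relevant conditions
    LAG3_L   = "LAG3_L & !Tbet",
    ## receptors and co-receptors
    CD4      = "MHCII",
    CD8      = "MHCI",
    LCK_FYN  = "(CD4 | CD8) & !TIM3",
    TCR      = "Antigens & LCK_FYN & !SHP",
    CD28     = "CD80_86 & !CTLA4",
    CTLA4    = "CD80_86 & (TCR | FOXP3 | CTLA4)",
    PD1      = "PD1_L & FOXO1 & !Tbet",
    TIGIT    = "TIGIT_L & FOXO1 & !CD226",
    CD226    = "TIGIT_L & !TIGIT & TCR",
    LAG3     = "LAG3_L & LAT & FOXO1",
    TIM3     = "TIM3_L & ((FOXP3 & FOXO1 & !Tbet) | MAF_PRDM1)",
    ICOS     = "ICOS_L & LAT",
    TNFRs    = "TNFRs_L",
    ## proximal signalling
    SHP      = "PD1 | LAG3 | CTLA4",
    SHIP1    = "TIGIT",
    LAT      = "TCR",
    Ca_NFAT  = "LAT",
    MAPK     = "LAT",
    NFkB     = "LAT | TNFRs",
    PI3K     = "(LAT | CD28 | ICOS | CD226) & !SHIP1",
    AKT      = "PI3K",
    GSK3     = "!PI3K",
    ## cytokine signal transducers
    STAT1    = "IFNG | IL27",
    STAT3    = "IL27",
    STAT4    = "IL12",
    SMAD     = "TGFb",
    NFIL3    = "STAT3",
    MAF_PRDM1 = "IL27",
    ## transcription-factor hubs
    FOXO1    = "!AKT",
    Tbet     = "Tbet | (LAT & !GSK3) | STAT1 | STAT4",
    FOXP3    = "(FOXO1 | CTLA4 | SMAD | STAT1) & !PI3K & !STAT3 & !NFIL3",
    IL2      = "Ca_NFAT & MAPK & NFkB",
    ## phenotype read-outs
    Proliferation_Survival = "IL2 & AKT",
    Th1_CTL  = "Tbet & Ca_NFAT",
    Treg     = "FOXP3 & FOXO1"
  )
}

#' Build the T-cell checkpoint network
#'
#' Returns the curated logical model of T-cell activation under
#' immune-checkpoint control: 49 nodes covering antigen recognition
#' (Antigens, MHCI/MHCII, CD4/CD8, LCK_FYN, TCR), the LAT signalosome and
#' its downstream pathways (Ca/NFAT, MAPK, NFkB, PI3K/AKT), five inhibitory
#' checkpoints (PD1, CTLA4, TIGIT, LAG3, TIM3) and three activating ones
#' (CD226, ICOS, TNFRs), cytokine axes (IFNG/STAT1, IL12/STAT4,
#' IL27/STAT1+STAT3+MAF_PRDM1, TGFb/SMAD) and the transcription-factor hubs
#' (Tbet, FOXP3, FOXO1) driving the three phenotype read-outs.
#'
#' @return A validated [BooleanNetwork][BooleanNetwork-class].
#' @examples
#' net <- buildTCellNetwork()
#' renderRule(networkRules(net)$TCR)
#' @seealso [tcellConditions()], [applyPerturbations()], the methods
#'   vignette for the rule-reconstruction rationale.
#' @export
buildTCellNetwork <- function() {
  booleanNetwork(tcellRuleTable(),
                 phenotypes = c("Proliferation_Survival", "Th1_CTL", "Treg"))
}

#' Construct a cell condition
#'
#' @param name Condition label.
#' @param activeInputs Input nodes clamped to 1.
#' @param initialActive Free nodes whose initial value is 1 (e.g. `LAG3_L`).
#' @param notExpressed Nodes clamped to 0 (receptors absent from the
#'   repertoire of this context).
#' @param cellType `"CD4"`, `"CD8"` or `"generic"`.
#' @param localization `"LN"`, `"TME"` or `"none"`.
#' @return A [CellCondition][CellCondition-class].
#' @export
cellCondition <- function(name, activeInputs = character(),
                          initialActive = character(),
                          notExpressed = character(),
                          cellType = "generic", localization = "none") {
  new("CellCondition", name = name, activeInputs = activeInputs,
      initialActive = initialActive, notExpressed = notExpressed,
      cellType = cellType, localization = localization)
}

setMethod("show", "CellCondition", function(object) {
  cat(sprintf("CellCondition '%s' (%s, %s)\n", object@name, object@cellType,
              object@localization))
  cat("  active inputs:", paste(object@activeInputs, collapse = ", "), "\n")
  if (length(object@initialActive))
    cat("  initially active:", paste(object@initialActive, collapse = ", "), "\n")
  if (length(object@notExpressed))
    cat("  not expressed:", paste(object@notExpressed, collapse = ", "), "\n")
})

## MHC engagement for a cell type: CD4 cells recognise antigen on MHCII,
## CD8 cells on MHCI; the generic T cell carries both co-receptor routes.
mhcFor <- function(cellType) {
  switch(cellType,
         CD4 = "MHCII",
         CD8 = "MHCI",
         generic = c("MHCI", "MHCII"))
}

#' Catalogue of cell conditions
#'
#' The built-in contexts: the single-ligand panel on a generic T cell
#' (each inhibitory checkpoint ligand activated one by one, plus the
#' no-checkpoint baseline), lymph-node (LN) priming and tumour
#' microenvironment (TME) effector conditions with their respective
#' checkpoint repertoires (LN: CTLA4, ICOS, TNFRs; TME: ICOS, TNFRs, PD1,
#' TIGIT, LAG3, TIM3), and CD4+/CD8+ variants. TCR activation of effector
#' CD4+ cells is CD28-dependent, so the CD4+ TME context includes CD80_86;
#' CD8+ cytotoxic activation does not, as non-immune cells do not normally
#' express CD80/CD86.
#'
#' @return Named list of [CellCondition][CellCondition-class] objects.
#' @export
tcellConditions <- function() {
  base <- c("Antigens", "MHCI", "MHCII")
  tmeCheckpointLigands <- c("ICOS_L", "TNFRs_L", "PD1_L", "TIGIT_L", "TIM3_L")
  lnNotExpressed <- c("PD1", "TIGIT", "CD226", "LAG3", "TIM3")
  conds <- list(
    cellCondition("no_checkpoint", base),
    cellCondition("CD80_86_only", c(base, "CD80_86")),
    cellCondition("PD1_L_only", c(base, "PD1_L")),
    cellCondition("LAG3_L_only", base, initialActive = "LAG3_L"),
    cellCondition("TIM3_L_only", c(base, "TIM3_L")),
    cellCondition("TIGIT_L_only", c(base, "TIGIT_L")),
    cellCondition("LN", c(base, "CD80_86", "ICOS_L", "TNFRs_L"),
                  notExpressed = lnNotExpressed, localization = "LN"),
    cellCondition("TME", c(base, tmeCheckpointLigands),
                  initialActive = "LAG3_L", notExpressed = "CTLA4",
                  localization = "TME"),
    cellCondition("CD8", c("Antigens", "MHCI"), cellType = "CD8"),
    cellCondition("CD4", c("Antigens", "MHCII", "CD80_86"), cellType = "CD4"),
    cellCondition("LN_CD8", c("Antigens", "MHCI", "CD80_86", "ICOS_L",
                              "TNFRs_L"),
                  notExpressed = lnNotExpressed, cellType = "CD8",
                  localization = "LN"),
    cellCondition("LN_CD4", c("Antigens", "MHCII", "CD80_86", "ICOS_L",
                              "TNFRs_L"),
                  notExpressed = lnNotExpressed, cellType = "CD4",
                  localization = "LN"),
    cellCondition("TME_CD8", c("Antigens", "MHCI", tmeCheckpointLigands),
                  initialActive = "LAG3_L", notExpressed = "CTLA4",
                  cellType = "CD8", localization = "TME"),
    cellCondition("TME_CD4", c("Antigens", "MHCII", "CD80_86",
                               tmeCheckpointLigands),
                  initialActive = "LAG3_L", notExpressed = "CTLA4",
                  cellType = "CD4", localization = "TME"))
  setNames(conds, vapply(conds, function(c) c@name, ""))
}

#' Initial-condition specification for a cell condition
#'
#' Active inputs are clamped to 1 and all other inputs to 0; nodes outside
#' the condition's receptor repertoire are clamped to 0; internal nodes
#' start at 0 except those named `initialActive`; perturbations clamp their
#' node to the forced value.
#'
#' @param cond A [CellCondition][CellCondition-class].
#' @param net The network (default: the built-in T-cell model).
#' @param perturbations List of [Perturbation][Perturbation-class] objects.
#' @return An [initialConditionSpec()] list.
#' @export
conditionInitialSpec <- function(cond, net = buildTCellNetwork(),
                                 perturbations = list()) {
  inputs <- net@nodes[net@kind == "input"]
  unknown <- setdiff(c(cond@activeInputs, cond@initialActive,
                       cond@notExpressed), net@nodes)
  if (length(unknown))
    stop(sprintf("unknown node(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  clamp <- setNames(as.integer(inputs %in% cond@activeInputs), inputs)
  for (nm in cond@notExpressed) clamp[[nm]] <- 0L
  pn <- vapply(perturbations, function(p) p@node, "")
  pv <- vapply(perturbations, function(p) p@value, 0L)
  if (anyDuplicated(pn)) {
    for (nm in unique(pn[duplicated(pn)]))
      if (length(unique(pv[pn == nm])) > 1L)
        stop(sprintf("conflicting perturbations on node '%s'", nm),
             call. = FALSE)
  }
  for (i in seq_along(pn)) clamp[[pn[[i]]]] <- pv[[i]]
  init <- setNames(rep(1L, length(cond@initialActive)), cond@initialActive)
  initialConditionSpec(net, clamp = clamp, init = init)
}

#' Construct a perturbation
#'
#' @param node Node name.
#' @param value Forced value: 0 models a blocking treatment (checkpoint
#'   inhibitor), 1 an overexpression.
#' @return A [Perturbation][Perturbation-class].
#' @export
perturbation <- function(node, value) {
  new("Perturbation", node = node, value = as.integer(value))
}

setMethod("show", "Perturbation", function(object) {
  cat(sprintf("Perturbation: %s := %d\n", object@node, object@value))
})

#' Perturbations for named checkpoint-inhibitor treatments
#'
#' `"anti-X"` forces node `X` to 0 (the receptor activity is blocked
#' wherever it would otherwise be expressed).
#'
#' @param treatments Character vector such as `c("anti-PD1", "anti-CTLA4")`.
#' @return List of [Perturbation][Perturbation-class] objects.
#' @export
treatmentPerturbations <- function(treatments) {
  out <- list()
  for (trt in treatments) {
    for (piece in strsplit(trt, "+", fixed = TRUE)[[1L]]) {
      piece <- trimws(piece)
      if (!grepl("^anti-", piece))
        stop(sprintf("unknown treatment '%s' (expected 'anti-<node>')", piece),
             call. = FALSE)
      out[[length(out) + 1L]] <- perturbation(sub("^anti-", "", piece), 0L)
    }
  }
  out
}

#' Apply perturbations to a network
#'
#' Returns a perturbed copy in which each forced node's rule is replaced by
#' the constant; all other rules are untouched and the original network is
#' unmodified. Forced nodes are constant in all downstream dynamics
#' (when simulating, the forced value is also used as the node's initial
#' value, which [conditionInitialSpec()] arranges by clamping).
#'
#' @param net A [BooleanNetwork][BooleanNetwork-class].
#' @param perturbations List of [Perturbation][Perturbation-class] objects.
#' @return A new [BooleanNetwork][BooleanNetwork-class].
#' @export
applyPerturbations <- function(net, perturbations) {
  pn <- vapply(perturbations, function(p) p@node, "")
  pv <- vapply(perturbations, function(p) p@value, 0L)
  unknown <- setdiff(pn, net@nodes)
  if (length(unknown))
    stop(sprintf("unknown node(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  for (nm in unique(pn[duplicated(pn)]))
    if (length(unique(pv[pn == nm])) > 1L)
      stop(sprintf("conflicting perturbations on node '%s'", nm),
           call. = FALSE)
  for (i in seq_along(pn))
    net@rules[[pn[[i]]]] <- logicExpr("const", value = pv[[i]])
  net
}

#' Path to the shipped T-cell model file
#'
#' The built-in model in the native targets/factors dialect, with per-rule
#' annotations. [buildTCellNetwork()] is the authoritative definition; the
#' shipped file is its serialization.
#'
#' @return File path.
#' @export
tcellModelPath <- function() {
  system.file("extdata", "tcell_checkpoint_model.bnet", package = "icilogic",
              mustWork = TRUE)
}
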