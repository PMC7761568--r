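---
title: "Methods: a logical model of T-cell activation under checkpoint control"
author: "icilogic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a logical model of T-cell activation under checkpoint control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The formalism

`icilogic` models a signalling network as a Boolean network: every species
(ligand, receptor, kinase, transcription factor, phenotype read-out) is a
binary variable with a logical update rule over its regulators. The rule
language admits identifiers, the constants `0`/`1`, parentheses and the
operators `!`, `&`, `|` with precedence `!` > `&` > `|`; AND and OR are
n-ary after parsing. Names that contain `/` in the literature are written
with underscores (`CD80_86`, `MAF_PRDM1`).

Dynamics are **asynchronous**: exactly one node changes per transition, and
a flip of node $i$ is enabled in state $s$ iff $f_i(s) \neq s_i$. Giving
each enabled flip a positive rate (activation rate when flipping to 1,
deactivation rate when flipping to 0) turns the transition system into a
continuous-time Markov chain (CTMC). All rates default to the standard
value 1; per-node overrides are accepted by `simulationConfig()` but unused
by the shipped scenarios. Synchronous updating is deliberately out of
scope: the stochastic interpretation is the object of study, and exact and
stochastic analyses must share one semantics.

Two complementary solvers operate on this chain:

* **Exact.** `fixedPoints()` enumerates all states with $f(s) = s$ either
  by a DPLL-style constraint propagation (propagate every node whose
  regulators are fully assigned, branch on the first open node, 0 before 1)
  or by exhaustive enumeration of the free nodes (refused above 22 free
  nodes). `attractors()` builds the reachable transition system (bounded at
  $2^{20}$ states) and reports its terminal strongly connected components —
  stable states and limit cycles. `ctmcDistribution()` solves the transient
  distribution by uniformization, $P(t) = \sum_k \mathrm{Pois}_k(\lambda t)
  \, P(0) \tilde P^k$, truncating the Poisson series at a tail mass below
  $10^{-10}$; it is intended as an oracle for state spaces up to a few
  thousand states.
* **Stochastic.** `simulateEnsemble()` runs Gillespie trajectories in
  compiled code: holding times are exponential in the summed enabled rate
  and the flipped node is chosen proportionally to its rate. Ensembles
  report per-node marginals and the joint distribution over the phenotype
  nodes on a uniform time grid (100 points by default).

The test suite cross-validates the two routes: Gillespie marginals against
uniformization (itself checked against a dense matrix exponential), and
constraint-propagation fixed points against $2^n$ enumeration, on random
networks from the synthetic generator.

# Random numbers and reproducibility

A single integer seed expands into one substream per trajectory through a
SplitMix64 hash of (seed, trajectory index), so ensembles are reproducible
bit-for-bit and independent of execution order. The synthetic-network
generator draws from the same substream scheme (`(seed, 0)` hashed and then
counted), so generated networks are reproducible across modules without
touching R's global random-number state.

# Asymptotic read-outs

The published summary of a stochastic logical model is the asymptotic
("pie-chart") distribution over phenotype states. `asymptoticPhenotypes()`
averages the joint phenotype distribution over the last 20% of the horizon
and flags non-convergence when the two halves of that window differ by more
than 0.02 in total variation. The horizon defaults to 50 time units —
roughly 50 expected single-node flips, an order of magnitude beyond the
commitment time of every shipped condition; the convergence flag, not the
horizon, is the contract. Phenotype categories are named by their ON set
(`"Treg"` means Treg ON with the other read-outs OFF; `"Th1_CTL-Treg"` is
the mixed state; all-OFF is `"None"`).

Marginal standard errors use the Agresti–Coull adjustment,
$\tilde p = (k+2)/(n+4)$, rather than the plain binomial formula: the
shipped scenarios routinely produce marginals at or near 0 and 1, where the
unadjusted estimator collapses to zero width and overstates certainty.

# The T-cell network

`buildTCellNetwork()` returns the 49-node model: 13 ligand/cytokine inputs,
33 internal nodes, 3 phenotype read-outs. The topology — which species
regulates which, and with which sign — follows the published influence
network of TCR signalling under checkpoint control; the logical rules are
this package's reconstruction, pinned by the following conventions and
validated against the published qualitative behaviour by the scenario
suite.

**Inhibitory bias.** Every negative regulator enters its target's rule as
`AND NOT`; alternative activators combine with `OR`; obligatory partners
with `AND`. One active inhibitor therefore vetoes activation — the
"extreme" reading of mixed regulation, consistent with the observation
that a single inhibitory signal can block activation that requires several
synergistic positive signals.

**TCR core.** `TCR = Antigens & LCK_FYN & !SHP` (the canonical rule);
`LCK_FYN = (CD4 | CD8) & !TIM3` with `CD4 = MHCII`, `CD8 = MHCI`;
`LAT = TCR` stands for the LAT/VAV/PLCG signalosome feeding `Ca_NFAT`,
`MAPK`, `NFkB` (the latter also reachable through `TNFRs`), and
`PI3K = (LAT | CD28 | ICOS | CD226) & !SHIP1`, `AKT = PI3K`.
`IL2 = Ca_NFAT & MAPK & NFkB` and the read-outs are
`Proliferation_Survival = IL2 & AKT`, `Th1_CTL = Tbet & Ca_NFAT`,
`Treg = FOXP3 & FOXO1`.

**CTLA4 dominance.** `CTLA4 = CD80_86 & (TCR | FOXP3 | CTLA4)`:
expression is induced by TCR engagement or by FOXP3 (closing the documented
CTLA4–FOXP3 positive feedback loop) and then self-maintains;
`CD28 = CD80_86 & !CTLA4` encodes the competition for the shared ligand,
and CTLA4 recruits the SHP phosphatase (`SHP = PD1 | LAG3 | CTLA4`) that
vetoes TCR. Because any signalling state keeps CTLA4 enabled, no
proliferating stable state exists when CD80/86 is present — CTLA4
inhibition is complete by construction, which the fixed-point analysis
confirms exactly.

**Commitment races.** The partial checkpoints act through a shared
bistability. At stimulation onset AKT is off, so FOXO1 switches on and
licenses checkpoint expression (`PD1 = PD1_L & FOXO1 & !Tbet`,
`TIGIT = TIGIT_L & FOXO1 & !CD226`, `LAG3 = LAG3_L & LAT & FOXO1`,
`TIM3 = TIM3_L & ((FOXP3 & FOXO1 & !Tbet) | MAF_PRDM1)`). If the TCR
cascade reaches AKT first, FOXO1 shuts down, the checkpoints lose their
licence and the cell locks into the activated attractor; if a checkpoint
engages its effector first (SHP onto TCR, SHIP1 onto PI3K, TIM3 onto
LCK_FYN), signalling collapses, FOXO1 stays on, FOXP3 follows
(`FOXP3 = (FOXO1 | CTLA4 | SMAD | STAT1) & !PI3K & !STAT3 & !NFIL3`), and
the cell locks into an arrested, Treg-committed attractor. The asymptotic
inhibition percentages are the probabilities of losing this race, and they
order the checkpoints by the depth and speed of their strike: including
FOXO1 among the FOXP3 activators is required for any Treg commitment in
cytokine-free conditions and reflects FOXO1's documented, essential role in
inducible-Treg differentiation.

**TIGIT/CD226.** The two receptors compete for the same ligands:
`CD226 = TIGIT_L & !TIGIT & TCR` (activation-dependent costimulation,
displaced by TIGIT) feeds PI3K, while TIGIT recruits SHIP1
(`SHIP1 = TIGIT`), which blocks PI3K directly — the mechanistic reason
TIGIT emerges as a strong checkpoint despite acting below the TCR.

**Tbet axis.** `GSK3 = !PI3K` (PI3K signalling inactivates GSK3) and
`Tbet = Tbet | (LAT & !GSK3) | STAT1 | STAT4`: the effector program is
self-maintaining once engaged, as Tbet autoregulation warrants, and it
represses checkpoint expression — `!Tbet` in the PD1 and TIM3 rules and
decay of the LAG3 ligand (`LAG3_L = LAG3_L & !Tbet`, an internal node
initialised by the conditions). This is why LAG3 ligation alone is inert:
its block is not self-sustaining (LAG3 needs LAT), every recovery gives the
Tbet program another chance, and the first transient Tbet pulse removes the
ligand permanently. Forcing `LAG3 = 1` bypasses the unstable expression and
restores full inhibition.

**Cytokines.** `IFNG → STAT1`, `IL12 → STAT4` (both feeding Tbet),
`TGFb → SMAD` (a FOXP3 activator), and `IL27 → STAT1 & STAT3 & MAF_PRDM1`
with `NFIL3 = STAT3`: STAT3/NFIL3 veto FOXP3 while MAF/PRDM1 induces
checkpoint expression unconditionally (the `MAF_PRDM1` arm of the TIM3
rule), which is how IL27 alone extinguishes both differentiation
phenotypes. TGFb's SMAD input is redundant wherever FOXO1 already licenses
FOXP3 and vetoed wherever PI3K is on — hence no change from TGFb alone, as
the cytokine panel verifies.

Where these reconstruction choices go beyond the published topology (the
TCR-induced arm of CTLA4 expression, FOXO1 as a FOXP3 activator, the
Tbet-destabilised TIM3 expression generalising the documented Tbet
repression of PD1 and of the LAG3 ligand, the activation-gated CD226, and
confining SHP's veto to TCR), they are the package's own modelling
decisions, each selected so that the qualitative invariants of the
published system hold and each annotated in the shipped model file
(`tcellModelPath()`).

# Conditions, treatments and scenarios

A `CellCondition` clamps the active inputs to 1 and all other inputs to 0,
clamps receptors outside the context's repertoire to 0, and starts internal
nodes at 0 (except nodes like `LAG3_L` that a condition sets active but
free to decay). The catalogue follows the published contexts: single-ligand
panels on a generic T cell (both MHC routes available); the lymph node (LN)
with CTLA4, ICOS and TNFRs; the tumour microenvironment (TME) with ICOS,
TNFRs, PD1, TIGIT, LAG3 and TIM3 but no CTLA4; and CD4+/CD8+ variants —
the CD4+ TME includes CD80/86 because effector CD4+ activation is
CD28-dependent, whereas the CD8+ TME lacks it.

Treatments force checkpoint nodes to 0 (`anti-X`), overexpression forces a
node to 1; forced nodes are clamped for the whole simulation, so they hold
their value at every time point. In the two-step protocol the two stages
are simulated independently with their own repertoires and a treatment is
applied in both stages (a no-op where its target is not expressed). The
combined read-out of a phenotype is
$P_{LN}(\text{Proliferation}) \times P_{TME}(\text{phenotype})$ —
inefficient priming gates the effector response. The anti-tumour balance is
summarised by the Th1/Treg ratio, reported as undefined when the Treg
marginal is below $10^{-6}$.

`compareDirections()` turns qualitative expectations into verdicts: a
change counts as "up"/"down" only beyond 3 combined Monte-Carlo standard
errors, "no effect" must stay within that band, and intensity grades are
orderings only — a grade-2 (double-arrow) expectation must additionally
exceed the change of every lower-grade expectation on the same statistic.
Monotherapy rows are judged in the stage where the target is engaged
(anti-CTLA4 in the LN, anti-PD1 in the TME); combination rows are judged on
the combined read-out. In the CD8+ subpopulation scenario, PD1+CTLA4−
clamps CTLA4 to 0 in both stages, while PD1+CTLA4+ leaves CTLA4 expressed —
engaged in the LN only, since the CD8+ TME lacks its ligand.

One read-out deserves a note: the ~50% "Treg reduction" under TIM3. The
no-checkpoint baseline of this model has an asymptotic Treg probability of
0 (every trajectory commits to proliferation), so a reduction relative to
baseline is undefined; the panel therefore reports Treg retention relative
to the fully arrested CTLA4 condition, where the Treg phenotype is retained
in full. Under TIM3 roughly half of the trajectories arrest into the Treg
state — a ~50% reduction of the Treg slice relative to full retention, and
simultaneously a ~50% proliferation inhibition.

# The synthetic generator

`randomNetwork()` produces networks with controlled size, in-degree (fixed
or ranged) and activator/inhibitor mix under two rule schemes: the
inhibitory bias of the biological model, and uniform random truth tables as
an adversarial contrast. `networkFixture()` supplies analytic fixtures
(toggle switch, self-activator, two-node oscillator, activation chain with
Erlang marginals, single-node relaxation with $1-e^{-t}$). These exercise
every engine path — races, cycles, absorption, degenerate constants — but
they do not emulate two features of the biological model: its strong
input-driven clamping structure and its long feedback loops through
transcription factors. Engine tests passing on random networks therefore
validate the simulator and the exact solvers, not the biology; the
scenario suite validates the biology separately against the published
qualitative pattern.

# Numerical choices and degenerate inputs

* Uniformization truncates the Poisson series at a $10^{-10}$ tail and
  renormalizes, keeping probability conservation at $10^{-9}$ or better;
  stable states are verified to absorb monotonically.
* Fixed points and attractor member states are ordered lexicographically in
  declared node order (0 before 1), so reports are stable across runs and
  node orderings.
* Statistical verdicts use 3 standard errors; engine-versus-oracle
  comparisons in the tests allow the chance-expected share of 3-sigma
  exceedances across hundreds of marginals (none beyond 5 SE plus a
  3-count Poisson slack) rather than pretending a hard per-comparison
  bound.
* Degenerate inputs are guarded: empty or malformed rules and unknown
  tokens fail with positions, conflicting forcings on one node are
  rejected, zero-baseline inhibition strengths raise an error, and the
  Th1/Treg ratio returns a flagged undefined value instead of dividing by
  zero. Inhibition percentages are clipped to $[0, 100]$ for reporting with
  the raw (possibly negative) value preserved.

# Simulation sizes

Shipped defaults: 10,000 trajectories, horizon 50, 100 grid points — the
sizes at which all scenario statistics have standard errors well below the
effects they are asked to resolve. The test suite uses smaller ensembles
(400–10,000) chosen per test so that the tested effect exceeds its
3-standard-error band by a comfortable margin.

# Known limitations

The formalism is coarse: two-valued nodes, unit rates, no partial
inhibition, no dose — intensity comparisons are orderings, never
magnitudes. The model ignores natural Tregs, Th2/Th17 subsets, innate
immunity and the cytokine-production feedback from the effector phenotypes,
and treats the LN and TME stages as independent except through the
multiplicative combined read-out. The exact percentages reported by the
panel depend on the reconstructed rules; they land near the published
values under the conventions above, but alternative rule readings
consistent with the same topology shift them by several points, which is
why the package treats them as tolerance-banded rather than exact
quantities.
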