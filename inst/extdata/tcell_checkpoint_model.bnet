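targets, factors
Antigens, Antigens # kind: input # tumour antigen presented by the APC/target cell
MHCI, MHCI # kind: input
MHCII, MHCII # kind: input
CD80_86, CD80_86 # kind: input
PD1_L, PD1_L # kind: input
TIGIT_L, TIGIT_L # kind: input
TIM3_L, TIM3_L # kind: input
ICOS_L, ICOS_L # kind: input
TNFRs_L, TNFRs_L # kind: input
IFNG, IFNG # kind: input
IL12, IL12 # kind: input
IL27, IL27 # kind: input
TGFb, TGFb # kind: input
LAG3_L, LAG3_L & !Tbet # kind: internal # ligand expression unstable once Tbet is active
CD4, MHCII # kind: internal
CD8, MHCI # kind: internal
LCK_FYN, (CD4 | CD8) & !TIM3 # kind: internal
TCR, Antigens & LCK_FYN & !SHP # kind: internal # activation requires antigen and LCK/FYN, vetoed by SHP
CD28, CD80_86 & !CTLA4 # kind: internal # CTLA4 outcompetes CD28 for CD80/86
CTLA4, CD80_86 & (TCR | FOXP3 | CTLA4) # kind: internal # activation-induced and FOXP3-driven expression, self-sustaining
PD1, PD1_L & FOXO1 & !Tbet # kind: internal # FOXO1 promotes PD1 expression; Tbet represses it
TIGIT, TIGIT_L & FOXO1 & !CD226 # kind: internal # competes with CD226 for CD155/CD112
CD226, TIGIT_L & !TIGIT & TCR # kind: internal # costimulation upon TCR engagement; displaced by TIGIT
LAG3, LAG3_L & LAT & FOXO1 # kind: internal # activation-induced; signals to SHP
TIM3, TIM3_L & (FOXP3 & FOXO1 & !Tbet | MAF_PRDM1) # kind: internal # FOXP3/FOXO1-driven, Tbet-destabilised, induced by IL27 via MAF/PRDM1
ICOS, ICOS_L & LAT # kind: internal
TNFRs, TNFRs_L # kind: internal
SHP, PD1 | LAG3 | CTLA4 # kind: internal # phosphatase recruited by PD1, LAG3 and CTLA4; dephosphorylates TCR
SHIP1, TIGIT # kind: internal # recruited by TIGIT; blocks PI3K signalling
LAT, TCR # kind: internal
Ca_NFAT, LAT # kind: internal
MAPK, LAT # kind: internal
NFkB, LAT | TNFRs # kind: internal
PI3K, (LAT | CD28 | ICOS | CD226) & !SHIP1 # kind: internal # survival arm; blocked by SHIP1
AKT, PI3K # kind: internal
GSK3, !PI3K # kind: internal # constitutively active unless PI3K/AKT signalling is on
STAT1, IFNG | IL27 # kind: internal
STAT3, IL27 # kind: internal
STAT4, IL12 # kind: internal
SMAD, TGFb # kind: internal
NFIL3, STAT3 # kind: internal
MAF_PRDM1, IL27 # kind: internal
FOXO1, !AKT # kind: internal # excluded from the nucleus by AKT phosphorylation
Tbet, Tbet | LAT & !GSK3 | STAT1 | STAT4 # kind: internal # effector master regulator; self-maintaining
FOXP3, (FOXO1 | CTLA4 | SMAD | STAT1) & !PI3K & !STAT3 & !NFIL3 # kind: internal # iTreg master regulator, vetoed by PI3K and STAT3/NFIL3
IL2, Ca_NFAT & MAPK & NFkB # kind: internal
Proliferation_Survival, IL2 & AKT # kind: phenotype # IL2-driven proliferation with PI3K/AKT survival
Th1_CTL, Tbet & Ca_NFAT # kind: phenotype # Tbet-driven Th1/cytotoxic differentiation
Treg, FOXP3 & FOXO1 # kind: phenotype # FOXP3- and FOXO1-dependent regulatory fate
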