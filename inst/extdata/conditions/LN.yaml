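condition:
  name: LN
  active_inputs:
  - Antigens
  - MHCI
  - MHCII
  - CD80_86
  - ICOS_L
  - TNFRs_L
  initial_active: []
  not_expressed:
  - PD1
  - TIGIT
  - CD226
  - LAG3
  - TIM3
  cell_type: generic
  localization: LN
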