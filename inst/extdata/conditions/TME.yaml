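condition:
  name: TME
  active_inputs:
  - Antigens
  - MHCI
  - MHCII
  - ICOS_L
  - TNFRs_L
  - PD1_L
  - TIGIT_L
  - TIM3_L
  initial_active:
  - LAG3_L
  not_expressed:
  - CTLA4
  cell_type: generic
  localization: TME
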