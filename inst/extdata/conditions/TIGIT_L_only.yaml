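condition:
  name: TIGIT_L_only
  active_inputs:
  - Antigens
  - MHCI
  - MHCII
  - TIGIT_L
  initial_active: []
  not_expressed: []
  cell_type: generic
  localization: none
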