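condition:
  name: CD8
  active_inputs:
  - Antigens
  - MHCI
  initial_active: []
  not_expressed: []
  cell_type: CD8
  localization: none
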