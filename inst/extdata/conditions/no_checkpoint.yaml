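condition:
  name: no_checkpoint
  active_inputs:
  - Antigens
  - MHCI
  - MHCII
  initial_active: []
  not_expressed: []
  cell_type: generic
  localization: none
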