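study: sensitivity
scanner: wt_pet
seed: 20260902
params:
  lineLengthCm: 106
  nDecays: 1.0e6
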