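# Total sensitivity of the flat-panel scanner, 70 cm sleeved line source
# at the isocenter.
study: sensitivity
scanner: wt_pet
seed: 20260901
params:
  lineLengthCm: 70
  nDecays: 1.0e6
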