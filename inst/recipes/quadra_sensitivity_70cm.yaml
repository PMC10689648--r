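# Cylindrical comparator, no maximum-ring-difference cut.
study: sensitivity
scanner: quadra_like
seed: 20260903
params:
  lineLengthCm: 70
  nDecays: 1.0e6
  mrd: .na
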