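# Image-quality phantom with the two extra surface lesions (desk-scale
# statistics).
study: iq
scanner: wt_pet
seed: 20260907
params:
  extraLesions: true
  nDecays: 2.0e6
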