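# Reconstructed point-source resolution at the first NEMA position
# (warm background, three replicate acquisitions averaged).
study: resolution
scanner: wt_pet
seed: 20260905
params:
  positionCm: [1, 0, 0]
  nDecays: 4.0e6
  warmBackground: true
  replicates: 3
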