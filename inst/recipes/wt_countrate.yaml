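# Count-rate ladder for the flat-panel scanner (desk-scale statistics).
study: countrate
scanner: wt_pet
seed: 20260906
params:
  activitiesKBqMl: [0.045, 1, 5, 10, 20, 30, 41]
  decaysPerPoint: 2.0e5
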