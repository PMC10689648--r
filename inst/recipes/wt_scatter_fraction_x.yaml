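# Scatter fraction of the flat-panel scanner, line source offset 4.5 cm
# along X (parallel to the panels), low activity.
study: scatter
scanner: wt_pet
seed: 20260904
params:
  offsetAxis: X
  activityKBqMl: 0.045
  nDecays: 2.0e6
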