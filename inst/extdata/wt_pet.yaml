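# Walk-through flat-panel total-body PET: two vertical panels of
# monolithic BGO blocks, 50 cm apart, 106 cm axial FOV.
type: flatpanel
panel_separation_cm: 50
panel_width_cm: 70
panel_axial_cm: 106
blocks_x: 14
blocks_z: 20
block_mm: [50, 50, 16]
crystal_material: BGO
energy_resolution: 0.15
energy_window_kev: [434, 645]
ctw_ns: 5
ctr_ps: 327
dead_time_ns: 370
smear_sigma_xy_mm: 0.55
smear_sigma_doi_mm: 0.85
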