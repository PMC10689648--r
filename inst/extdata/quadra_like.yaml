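# Cylindrical total-body comparator: pixelated LSO, 82 cm ring
# diameter, 106 cm axial FOV, 322 crystal rings.
type: cylindrical
ring_diameter_cm: 82
crystal_mm: [3.2, 3.2, 20]
n_rings: 322
axial_cm: 106
crystal_material: LSO
energy_resolution: 0.11
energy_window_kev: [455, 645]
ctw_ns: 4.7
ctr_ps: 228
dead_time_ns: 320
mrd: 85
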