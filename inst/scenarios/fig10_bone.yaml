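name: fig10_bone
description: Same beam as fig6_merge but 700-um pitch, with a 5-mm cortical-bone
  slab (density 1.85) covering x > 0 at the phantom surface.
headline: merge depth ~4 cm; bone-vs-open half-profile deviation < 10%
spectrum: {kvp: 320, hvl_mm: 3.8, hvl_material: copper}
source: {spot_mm: 6.8, shape: disk}
scd_mm: 295
gap_mm: 0
collimator: {aperture_mm: 0.3, pitch_mm: 0.7, n_apertures: 23, focusing: parallel}
phantom:
  material: water
  lateral_mm: 50
  depth_mm: 100
  dx_mm: 0.05
  dz_mm: 1.0
  inserts:
    - {material: bone_cortical, x_mm: [0.0, .inf], z_mm: [0.0, 5.0]}
transport: {n_histories: 6000000, seed: 1}
analyses: [pvr, merge, half_profile]
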