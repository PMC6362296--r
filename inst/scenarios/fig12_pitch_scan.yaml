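name: fig12_pitch_scan
description: Merge-depth adjustment by beam spacing; three pitches with the
  same source and source-to-collimator distance.
headline: strictly increasing merge depth with pitch
spectrum: {kvp: 320, hvl_mm: 3.8, hvl_material: copper}
source: {spot_mm: 6.8, shape: disk}
scd_mm: 295
gap_mm: 0
collimator: {aperture_mm: 0.3, pitch_mm: 0.7, n_apertures: 23, focusing: parallel}
phantom: {material: water, lateral_mm: 60, depth_mm: 100, dx_mm: 0.05, dz_mm: 1.0}
transport: {n_histories: 1000000, seed: 1}
pitches_mm: [0.7, 1.0, 1.3]
analyses: [pitch_scan]
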