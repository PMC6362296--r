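name: fig6_merge
description: 320-kVp (3.8-mm Cu HVL) array of 0.3-mm minibeams at 1.0-mm pitch
  from a 6.8-mm disk source 295 mm upstream, water phantom at the collimator exit.
headline: PVR-1.2 merge depth in water (reference ~55 mm)
spectrum: {kvp: 320, hvl_mm: 3.8, hvl_material: copper}
source: {spot_mm: 6.8, shape: disk}
scd_mm: 295
gap_mm: 0
collimator: {aperture_mm: 0.3, pitch_mm: 1.0, n_apertures: 23, focusing: parallel}
phantom: {material: water, lateral_mm: 60, depth_mm: 100, dx_mm: 0.05, dz_mm: 1.0}
transport: {n_histories: 2000000, seed: 1}
analyses: [pvr, merge, valley_curve, biologic]
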