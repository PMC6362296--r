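name: fig2_compare
description: Depth-dose comparison of the 6-MV fixture curve, the 320-kVp open
  beam, and the minibeam valley-dose curve (0.3-mm beams, 0.7-mm pitch),
  normalized to coincide at 50-mm depth (center of a 2-cm target at 5 cm).
headline: three normalized depth-dose curves coinciding at 50 mm
spectrum: {kvp: 320, hvl_mm: 3.8, hvl_material: copper}
source: {spot_mm: 6.8, shape: disk}
scd_mm: 295
gap_mm: 0
collimator: {aperture_mm: 0.3, pitch_mm: 0.7, n_apertures: 23, focusing: parallel}
phantom: {material: water, lateral_mm: 50, depth_mm: 140, dx_mm: 0.05, dz_mm: 1.0}
transport: {n_histories: 2000000, seed: 1}
normalize_depth_mm: 50
analyses: [valley_curve, fig2_compare]
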