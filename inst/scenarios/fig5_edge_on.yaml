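name: fig5_edge_on
description: XRAD-320 film geometry; 6.0-mm source, parallel collimator at
  315 mm, 0.3-mm beams at 1.0-mm pitch, film-equivalent medium at the exit.
headline: merging point from the collimator (film measurement 3.1 cm)
spectrum: {kvp: 320, hvl_mm: 3.8, hvl_material: copper}
source: {spot_mm: 6.0, shape: disk}
scd_mm: 315
gap_mm: 0
collimator: {aperture_mm: 0.3, pitch_mm: 1.0, n_apertures: 9, focusing: parallel}
phantom: {material: film_plastic, lateral_mm: 40, depth_mm: 90, dx_mm: 0.05, dz_mm: 1.0}
transport: {n_histories: 2000000, seed: 1}
analyses: [pvr, merge]
film: {mode: edge_on, od_max: 2, d0_gy: 5, entrance_peak_gy: 5.0, noise_sd: 0.005}
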