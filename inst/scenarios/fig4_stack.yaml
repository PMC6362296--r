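name: fig4_stack
description: Cross-sectional film stack through a humanoid head phantom
  stand-in (homogeneous slab, density calibrated to a 1.55-cm depth-dose HVL);
  250-kVp beam with the Al/Cu/Sn F2 filter, diverging 0.34-mm / 1.12-mm
  collimator 295 mm from the source, phantom surface 25 mm below it.
headline: film stack at 0/2.5/5 cm depth; peak-dose HVL fit ~1.55 cm
spectrum:
  kvp: 250
  filtration:
    - {material: aluminium, thickness_mm: 1.5}
    - {material: copper, thickness_mm: 0.25}
    - {material: tin, thickness_mm: 0.75}
source: {spot_mm: 6.0, shape: disk}
scd_mm: 295
gap_mm: 25
collimator: {aperture_mm: 0.34, pitch_mm: 1.12, n_apertures: 19, focusing: diverging}
phantom:
  material: water
  density: hvl_calibrated
  target_hvl_cm: 1.55
  lateral_mm: 50
  depth_mm: 60
  dx_mm: 0.05
  dz_mm: 1.0
transport: {n_histories: 2000000, seed: 1}
analyses: [hvl_fit]
film:
  mode: cross_section_stack
  depths_mm: [25.0, 50.0, 75.0]
  entrance_peak_gy: 5.4
  noise_sd: 0.005
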