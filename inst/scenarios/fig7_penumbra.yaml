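name: fig7_penumbra
description: Solid-beam 220-kVp cone (15-mm field) lateral falloff at 40-mm
  depth, compared against the packaged film-measured falloff fixtures
  (0.40 mm at 220 kVp vs 2.2 mm at 6 MV).
headline: simulated orthovoltage 80-20 falloff sharper than the 6-MV fixture
spectrum: {kvp: 220, hvl_mm: 2.0, hvl_material: copper}
source: {spot_mm: 6.0, shape: disk}
scd_mm: 500
gap_mm: 0
field_mm: 15
phantom: {material: water, lateral_mm: 60, depth_mm: 80, dx_mm: 0.05, dz_mm: 1.0}
transport: {n_histories: 2000000, seed: 1}
penumbra_depth_mm: 40
analyses: [penumbra]
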