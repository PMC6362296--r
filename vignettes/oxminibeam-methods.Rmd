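---
title: "Merging orthovoltage minibeam arrays: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Merging orthovoltage minibeam arrays: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem this package models

Spatially fractionated kilovoltage radiotherapy segments a broad orthovoltage
x-ray beam into an array of thin planar *minibeams* (~0.3 mm wide, ~1 mm
apart on-center) with a multislit tungsten collimator placed near the skin.
Tissue tolerates such arrays at in-beam doses far beyond solid-beam
tolerance, as long as the *valley dose* — the dose midway between beams —
stays low. Because the x-ray tube's focal spot is large (3–9 mm) and the
source-to-collimator distance short (10–30 cm), each minibeam widens with
depth and the array deliberately *merges* into a solid beam at a chosen
depth, where the target sits. Proximal tissue sees separated minibeams
(spared); the target sees a solid therapeutic beam.

Two ratios organize the analysis, both functions of depth $z$:

* **PVR** (peak-to-valley dose ratio) $= D_\mathrm{peak}(z) / D_\mathrm{valley}(z)$.
* The array is *merged* where $\mathrm{PVR} \le 1.2$, and *tissue-sparing*
  where $\mathrm{PVR} \ge 3$.

The package implements the full chain — spectrum, collimator optics, photon
transport, dose metrics, biologic (valley-minimum) dose, and synthetic film
dosimetry — at desk scale, with every stage testable in seconds.

## Beam model

The tube spectrum is a Kramers-type bremsstrahlung fluence,
$\phi(E) \propto (E_\mathrm{max}-E)/E$ on 1-keV bins above the 10-keV
transport cutoff, filtered through exponential attenuation per layer.
Characteristic tungsten lines are omitted. Orthovoltage beams are specified
clinically by tube potential plus half-value layer (HVL), so
`tune_filtration_to_hvl()` solves (monotone bisection) for the copper
thickness whose filtered spectrum reproduces the stated HVL — e.g. 320 kVp
with a 3.8-mm Cu HVL, the configuration used throughout, needs ≈6.7 mm of
copper from the unfiltered Kramers shape and has a mean energy of ≈178 keV.
Downstream observables (merge depths, attenuation rates) depend on beam
*hardness*, which the HVL pins down, far more than on fine spectral shape;
this is why an analytic spectrum suffices in place of the unpublished
machine spectra. The HVL here is defined on transmitted fluence
(narrow-beam), the natural quantity for an attenuation model.

Photon interaction data (10–1000 keV) are embedded as per-material CSV
tables split into photoelectric, Compton and Rayleigh channels whose sum is
the total by construction. Totals for water, air, cortical bone, aluminium
and copper are anchored at standard published benchmark values; the Compton
channel is the analytic Klein–Nishina cross-section (free-electron
approximation) times electron density; Rayleigh is a calibrated power law;
photoelectric is the anchored remainder (for Sn, W and iodine, a piecewise
power law with a K-edge jump anchored at published values — iodine at
3.5 cm²/g @ 80 keV and 0.058 @ 1 MeV). Interpolation is log-log linear,
standard for photon cross sections. The free-electron Compton approximation
overstates incoherent scatter by a few percent below ~50 keV; for a beam
hardened to 3.8-mm Cu HVL the affected bins carry little weight.

## Collimator optics

For aperture width $a$, pitch $p$, source spot $s$ and source-to-collimator
distance $L$, similar triangles give at depth $z$ beyond the collimator
exit:

$$ w_\mathrm{full}(z) = a\frac{L+z}{L} + s\frac{z}{L}, \qquad
   w_\mathrm{umbra}(z) = \max\!\Big(0,\; a\frac{L+z}{L} - s\frac{z}{L}\Big), \qquad
   p(z) = p\frac{L+z}{L}. $$

Adjacent penumbrae touch at
$z^\* = (p-a)\,L \,/\, \big(s-(p-a)\big)$ (the *geometric merge onset*),
provided $s > p-a$; otherwise the array never merges. The onset is a strict
lower bound on the PVR-based merge depth: scatter and penumbral overlap only
*add* valley dose beyond it. Solvers invert the formula for $L$ (moving the
source, the dynamically adjustable knob) and for $p$ (swapping collimators).
Diverging (focused-at-the-source) collimators are treated as parallel: with
focal distance equal to $L$ the slit axes point at the source and the
first-order projections coincide; blade-edge vignetting is neglected.

## Photon transport

`run_transport()` is a compact voxelized Monte Carlo written in C++:

* **Dimensionality.** Planar minibeams are uniform along the slit length
  (2-cm apertures), so the problem is translation invariant in $y$ and is
  collapsed to $(x, z)$: positions are 2-D, directions full 3-D. A
  consequence is that the source acts as a *line* source — fluence falls as
  $L/(L+z)$, not $1/r^2$. Per-depth ratios (PVR, merge depths, penumbra)
  are unaffected to first order; absolute depth-dose curves are slightly
  shallower than a 3-D point-source geometry, which is accepted and shared
  by the analytic oracle so the two stay comparable.
* **Sampling.** Source positions are drawn from the collapsed focal-spot
  profile (semicircular for a disk spot), aim points uniformly within the
  apertures (blades are opaque by default — transmission through 5 mm of
  tungsten at ≤320 keV is below 10⁻⁶; an `attenuated` mode carries
  exponentially weighted blade rays). Energies come from the spectrum's
  inverse CDF. Free paths use Woodcock (delta) tracking against a
  per-energy majorant, so heterogeneous phantoms (a cortical-bone slab in
  water) need no boundary ray-tracing.
* **Interactions.** Photoelectric absorbs locally. Compton samples the
  Klein–Nishina distribution by rejection and deposits the electron energy
  locally. Rayleigh deflects without energy loss through a forward-peaked
  angle (Rayleigh-distributed polar angle with width
  $\propto Z_\mathrm{eff}^{1/3}\,m_ec^2/E$ — a form-factor-free
  approximation; the lateral tail *shape* far outside the field should not
  be over-interpreted). Photons below 10 keV deposit locally.
* **Electrons.** Secondary electron ranges at orthovoltage energies
  (CSDA ≈ 0.14 mm at 100 keV) are near the 50-µm voxel scale, so electron
  dose spread is modeled as a lateral Gaussian of width
  $\sigma = 0.3\,R_\mathrm{CSDA}(\bar T)$, with $\bar T$ the
  interaction-rate-weighted mean secondary energy (≈0.05 mm here; well
  under the 0.3-mm beam width, so the minibeam pattern survives, which the
  tests assert). The 0.3 factor reflects that a CSDA range is a hard upper
  bound on net displacement.
* **Reproducibility.** The generator is R's (`set.seed(seed)` before the
  C++ kernel): identical seeds give bit-identical grids; seeds are recorded
  in the grid metadata and every exported sidecar.

`analytic_primary_dose()` is the deterministic oracle: quadrature rays from
the source through each aperture, exponentially attenuated per energy group
along the voxelized path, depositing the full photon energy at the collision
site — exactly the expectation of the Monte Carlo's `primary_only` mode,
which the tests verify voxel-by-voxel at 3σ.

## Dose metrics

* **Peak/valley windows** are geometry-anchored (robust to MC noise):
  windows of one third of the projected beam width centered on the
  projected beam centers (peaks) and midway between them (valleys), capped
  at one third of the projected pitch so the families never overlap; the
  outermost two beams on each side are excluded. Beyond the merge depth the
  "peak"/"valley" labels are only geometric: the projected pattern inverts
  and the ratio may dip a few percent below 1.
* **Merge depth**: the PVR ≤ 1.2 crossing, interpolated linearly on the
  *inverse* ratio valley/peak — the bounded quantity that grows linearly as
  valleys fill, and well behaved when shallow valleys are empty.
* **Sparing range**: the contiguous interval from the surface with PVR ≥ 3.
* **Biologic dose** (`biologic_dose_map()`): per voxel, the minimum
  physical dose within a 350-µm radius — the dose in the nearest valley
  from which surviving cells can repopulate (the radius comes from the
  tolerance of 700-µm beams: no point is farther than ~350 µm from a
  valley). It is a morphological minimum filter; with 1-mm depth voxels the
  350-µm disk reduces to a ±350-µm lateral window. Tests check it against a
  brute-force disk scan.
* **Penumbra** (`penumbra_80_20()`): lateral distance between the 80% and
  20% of-plateau crossings, plateau taken over the central half of the
  field, averaged over both edges. For *simulated* solid beams the metric
  is evaluated on the primary component: the collapsed strip geometry
  produces an out-of-field scatter floor (~18% of plateau) appropriate to
  an infinite strip, not to the finite cone fields of the reference
  measurements, and a 20% threshold would land on that floor. The
  film-measured falloffs (0.40 mm at 220 kVp, 2.2 mm at 6 MV) are packaged
  as parametric error-function fixtures, clearly labeled fixtures.
* **Depth-dose HVL** (`hvl_from_depth_doses()`): log-linear least squares
  over all points (the printed 5.4/1.7/0.5 Gy at 0/2.5/5 cm give 1.46 cm);
  per-interval HVLs are attached since sparse three-point data make the
  estimator choice visible.
* **The 6-MV comparison curve** is a parametric percentage-depth-dose
  fixture (quadratic build-up to 15 mm, then 4.7%/cm), used only for
  normalized comparison plots — megavoltage transport is out of scope.

## Synthetic film module

The film stage emulates what the physical experiments measured: periodic
peak/valley patterns with geometric divergence, depth attenuation,
scatter-filled valleys, scanner response and pixel noise. The scanner
response is a saturating exponential in net optical density,
$OD(D) = OD_\mathrm{max}\,(1-e^{-D/D_0})$ (defaults $OD_\mathrm{max}=2$,
$D_0=5$ Gy, 16-bit, 3200 dpi), with multiplicative Gaussian OD noise and
quantization; `film_to_dose()` inverts it and flags saturation. The forward
model is information-preserving below saturation (round-trip tests at
quantization + 3σ noise). Films are infinitesimally thin scoring planes (no
self-attenuation). Energy-dependent film sensitivity is deliberately not
modeled. The head-phantom stand-in for the cross-section stack is a
homogeneous slab whose density is calibrated (`tune_phantom_density_to_hvl()`)
so narrow-beam attenuation reproduces the measured 1.55-cm depth-dose HVL —
its composition is unpublished; note that with scatter build-up the full
simulation then shows a slightly longer film-stack HVL (~1.66 cm), a real
build-up effect, not a calibration error.

What passing film tests do **not** show about real films: lot-to-lot
calibration drift, energy response, scanner lateral nonuniformity, and
development-time kinetics are all outside the forward model.

## Scenarios, problem sizes, determinism

Seven bundled scenarios (`list_scenarios()`) reproduce the package's
reference analyses end-to-end from YAML configs; `run_scenario()` validates
configs (reporting *all* offending keys), runs the chain, and writes CSV
curves, JSON reports with seed/history-count/config-hash, and film TIFFs.

Default problem sizes were chosen so each scenario is a seconds-scale run
while keeping the threshold-crossing estimates stable to a few percent
across seeds: 2×10⁶ histories for homogeneous merge scenarios, 6×10⁶ for
the bone half-slab (whose half-profile comparison needs the best
statistics), 50-µm lateral × 1-mm depth scoring voxels. The bone-vs-open
half-profile deviation is computed after re-binning profiles at one
projected pitch: at the merge depth, sub-pitch structure is the residual
minibeam pattern itself, not the slab effect being measured.

## Known limitations

* The collapsed 2-D geometry yields $L/(L+z)$ fluence decay and
  strip-field scatter; absolute depth doses and far-tail shapes differ from
  3-D cone/rectangular fields.
* Free-electron Compton and form-factor-free Rayleigh; no fluorescence, no
  bound-Compton corrections, no bremsstrahlung of secondaries.
* Electron transport is a Gaussian kernel, not condensed-history transport.
* The spectrum is analytic; only its HVL is matched to hardware.
* One reference quantity resists reproduction: the film-measured merging
  point of the fine-tuning geometry (3.1 cm from the collimator). That
  geometry's penumbra-touching onset is already 4.2 cm, and the same
  transport that reproduces the ~55-mm merge of the simulation geometry
  puts this one near 7 cm. The two reference values are mutually
  inconsistent under any monotone optics model; the package reports the
  simulated value rather than tuning toward the measurement (an effective
  source spot near 12 mm, or a by-eye reading of "merged", would explain
  the 3.1 cm).
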