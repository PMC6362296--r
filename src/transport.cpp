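// Voxelized 2-D (x-z) photon Monte Carlo for planar minibeam arrays.
//
// The slit-length direction is translation invariant and is collapsed:
// positions are tracked in (x, z) while directions are full 3-D unit
// vectors (scattering is sampled in 3-D; the y excursion is irrelevant to
// scoring). Free paths are sampled by Woodcock (delta) tracking against a
// per-energy majorant so heterogeneous phantoms (e.g. a cortical-bone slab)
// need no boundary ray-tracing. Interactions: photoelectric absorption
// (local deposit), Compton scattering with the Klein-Nishina differential
// cross-section sampled by rejection (local deposit of the electron
// energy), and Rayleigh scattering as an energy-conserving forward-peaked
// deflection. Uses R's RNG, so set.seed() makes runs bit-identical.

#include <Rcpp.h>
using namespace Rcpp;

static inline void rotate_direction(double &ux, double &uy, double &uz,
                                    double ct, double phi) {
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double cphi = std::cos(phi), sphi = std::sin(phi);
  double temp = std::sqrt(std::max(0.0, 1.0 - uz * uz));
  if (temp > 1e-10) {
    double nx = ux * ct + st * (ux * uz * cphi - uy * sphi) / temp;
    double ny = uy * ct + st * (uy * uz * cphi + ux * sphi) / temp;
    double nz = uz * ct - st * cphi * temp;
    ux = nx; uy = ny; uz = nz;
  } else {
    ux = st * cphi;
    uy = st * sphi;
    uz = (uz >= 0 ? ct : -ct);
  }
  double norm = std::sqrt(ux * ux + uy * uy + uz * uz);
  ux /= norm; uy /= norm; uz /= norm;
}

// Sample eps = E'/E from the Klein-Nishina distribution, k = E/m_e c^2.
// dsigma/deps is proportional to eps + 1/eps - sin^2(theta).
static inline double sample_kn_eps(double k) {
  double emin = 1.0 / (1.0 + 2.0 * k);
  double fmax = emin + 1.0 / emin;
  for (int it = 0; it < 1000; ++it) {
    double eps = emin + (1.0 - emin) * unif_rand();
    double ct = 1.0 - (1.0 - eps) / (k * eps);
    double s2 = 1.0 - ct * ct;
    double f = eps + 1.0 / eps - s2;
    if (unif_rand() * fmax <= f) return eps;
  }
  return 1.0; // unreachable in practice
}

// [[Rcpp::export]]
NumericMatrix mc_transport_cpp(
    int n_hist,
    NumericVector spec_E,       // bin energies (keV)
    NumericVector spec_cdf,     // cumulative weights (last = 1)
    double src_half_mm,         // source half-extent (mm)
    int src_disk,               // 1 = disk focal spot, 0 = uniform strip
    double L_mm,                // source-to-collimator distance
    double gap_mm,              // collimator exit to phantom surface
    NumericVector ap_centers,   // aperture centers (mm); empty = open field
    double ap_half_mm,          // aperture half-width
    double open_half_mm,        // open-field half-width (if no apertures)
    double x0_mm, double dx_mm, int nx,
    double z0_mm, double dz_mm, int nz,   // z0 = phantom surface depth
    IntegerVector mat_map,      // nx*nz material ids (0-based), x fastest
    NumericMatrix mu_tot,       // nE x nmat linear attenuation (1/mm)
    NumericMatrix p_pe,         // nE x nmat photoelectric probability
    NumericMatrix p_ray,        // nE x nmat rayleigh probability
    NumericVector mu_max,       // nE majorant (1/mm)
    NumericVector ray_coef,     // per-material Rayleigh width coefficient
    double e_min_keV,           // first row of the mu tables
    double cutoff_keV,
    int primary_only,           // 1: deposit all energy at first collision
    double blade_mu_mm,         // >0: attenuated-blade mode, mu*t of blades
    double blade_frac           // fraction of rays aimed at blades (attn mode)
) {
  NumericMatrix edep(nx, nz);   // keV deposited per voxel
  const int nE = mu_tot.nrow();
  const int n_ap = ap_centers.size();
  const double x_max = x0_mm + nx * dx_mm;
  const double z_max = z0_mm + nz * dz_mm;

  for (int h = 0; h < n_hist; ++h) {
    // --- source position (collapsed lateral coordinate) ---
    double xs;
    if (src_disk) {
      double a, b;
      do { a = 2.0 * unif_rand() - 1.0; b = 2.0 * unif_rand() - 1.0; }
      while (a * a + b * b > 1.0);
      xs = a * src_half_mm;
    } else {
      xs = (2.0 * unif_rand() - 1.0) * src_half_mm;
    }

    // --- aim point in the collimator exit plane ---
    double xa, w = 1.0;
    if (n_ap == 0) {
      xa = (2.0 * unif_rand() - 1.0) * open_half_mm;
    } else if (blade_mu_mm > 0.0 && unif_rand() < blade_frac) {
      // attenuated-blade mode: ray through a blade, exponential weight
      double span = ap_centers[n_ap - 1] - ap_centers[0] + 2.0 * ap_half_mm;
      double lo = ap_centers[0] - ap_half_mm;
      do {
        xa = lo + span * unif_rand();
        bool in_ap = false;
        for (int j = 0; j < n_ap; ++j)
          if (std::fabs(xa - ap_centers[j]) <= ap_half_mm) { in_ap = true; break; }
        if (!in_ap) break;
      } while (true);
      w = std::exp(-blade_mu_mm);
    } else {
      int j = (int)(unif_rand() * n_ap);
      if (j >= n_ap) j = n_ap - 1;
      xa = ap_centers[j] + (2.0 * unif_rand() - 1.0) * ap_half_mm;
    }

    // --- direction and entry at the phantom surface ---
    double dxr = xa - xs, dzr = L_mm;
    double nrm = std::sqrt(dxr * dxr + dzr * dzr);
    double ux = dxr / nrm, uy = 0.0, uz = dzr / nrm;
    double x = xa + (dxr / dzr) * z0_mm;      // x where z = z0 (surface)
    double z = z0_mm;

    // --- energy ---
    double u = unif_rand();
    int bi = (int)(std::lower_bound(spec_cdf.begin(), spec_cdf.end(), u) -
                   spec_cdf.begin());
    if (bi >= spec_E.size()) bi = spec_E.size() - 1;
    double E = spec_E[bi];

    int ie = (int)(E - e_min_keV);
    if (ie < 0) ie = 0; if (ie >= nE) ie = nE - 1;

    // --- Woodcock tracking ---
    for (int step = 0; step < 100000; ++step) {
      double mm = mu_max[ie];
      double s = -std::log(unif_rand()) / mm;
      x += ux * s;
      z += uz * s;
      if (x < x0_mm || x >= x_max || z < z0_mm || z >= z_max) break;
      int ix = (int)((x - x0_mm) / dx_mm);
      int iz = (int)((z - z0_mm) / dz_mm);
      int m = mat_map[ix + nx * iz];
      double mloc = mu_tot(ie, m);
      if (unif_rand() > mloc / mm) continue;          // virtual collision

      if (primary_only) { edep(ix, iz) += w * E; break; }

      double uch = unif_rand();
      if (uch < p_pe(ie, m)) {                        // photoelectric
        edep(ix, iz) += w * E;
        break;
      } else if (uch < p_pe(ie, m) + p_ray(ie, m)) {  // rayleigh
        double sig = ray_coef[m] * 510.99895 / E;
        if (sig > 0.6) sig = 0.6;
        double th = sig * std::sqrt(-std::log(unif_rand()));
        if (th > 1.5) th = 1.5;
        rotate_direction(ux, uy, uz, std::cos(th), 2.0 * M_PI * unif_rand());
      } else {                                        // compton
        double k = E / 510.99895;
        double eps = sample_kn_eps(k);
        double ct = 1.0 - (1.0 - eps) / (k * eps);
        if (ct < -1.0) ct = -1.0; if (ct > 1.0) ct = 1.0;
        double Enew = E * eps;
        edep(ix, iz) += w * (E - Enew);
        if (Enew < cutoff_keV) { edep(ix, iz) += w * Enew; break; }
        rotate_direction(ux, uy, uz, ct, 2.0 * M_PI * unif_rand());
        E = Enew;
        ie = (int)(E - e_min_keV);
        if (ie < 0) ie = 0; if (ie >= nE) ie = nE - 1;
      }
    }
  }
  return edep;
}
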