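# Build the embedded photon mass-attenuation tables under inst/extdata/materials/.
#
# Construction (per material, 10--1000 keV):
#   * compton   : analytic Klein-Nishina total cross-section per electron times
#                 N_A * (Z/A)  [free-electron approximation, no binding/Doppler]
#   * rayleigh  : calibrated power law  b * (100/E)^1.9  (coherent scatter is a
#                 few percent of the total in this band; the exponent matches the
#                 slope of tabulated coherent cross-sections)
#   * photoelectric:
#       - anchored materials (water, air, cortical bone, Al, Cu): remainder
#         total_anchor - compton - rayleigh at NIST XCOM benchmark totals,
#         clipped at >= 0, log-log interpolated between anchors
#       - heavy elements (Sn, W, I): piecewise power law in E with a K-edge
#         jump, anchored to published values (iodine: 3.5 cm2/g at 80 keV and
#         0.058 cm2/g at 1 MeV)
#   * total     : exact sum of the three channels (closure by construction)
#
# Run from the package root:  Rscript data-raw/make_materials.R

kn_sigma <- function(E_keV) {
  # Klein-Nishina total cross-section per electron [cm^2]
  r_e <- 2.8179403262e-13            # classical electron radius [cm]
  k <- E_keV / 510.99895
  t1 <- (1 + k) / k^2 * (2 * (1 + k) / (1 + 2 * k) - log(1 + 2 * k) / k)
  t2 <- log(1 + 2 * k) / (2 * k)
  t3 <- (1 + 3 * k) / (1 + 2 * k)^2
  2 * pi * r_e^2 * (t1 + t2 - t3)
}

NA_AVOG <- 6.02214076e23

loglog_interp <- function(x, y, xout) {
  exp(approx(log(x), log(pmax(y, 1e-12)), xout = log(xout), rule = 2)$y)
}

anchor_E <- c(10, 15, 20, 30, 40, 50, 60, 80, 100, 150, 200, 300, 400, 500,
              600, 800, 1000)

# NIST XCOM mass attenuation coefficients (with coherent), cm^2/g
anchors <- list(
  water = c(5.329, 1.673, 0.8096, 0.3756, 0.2683, 0.2269, 0.2059, 0.1837,
            0.1707, 0.1505, 0.1370, 0.1186, 0.1061, 0.09687, 0.08956,
            0.07865, 0.07072),
  air = c(5.120, 1.614, 0.7779, 0.3538, 0.2485, 0.2080, 0.1875, 0.1662,
          0.1541, 0.1356, 0.1233, 0.1067, 0.09549, 0.08712, 0.08055,
          0.07074, 0.06358),
  bone_cortical = c(28.51, 9.032, 4.001, 1.331, 0.6655, 0.4242, 0.3148,
                    0.2229, 0.1855, 0.1480, 0.1309, 0.1113, 0.09908,
                    0.09022, 0.08332, 0.07308, 0.06566),
  aluminium = c(26.23, 7.955, 3.441, 1.128, 0.5685, 0.3681, 0.2778, 0.2018,
                0.1704, 0.1378, 0.1223, 0.1042, 0.09276, 0.08445, 0.07802,
                0.06841, 0.06146),
  copper = c(215.9, 74.05, 33.79, 10.92, 4.862, 2.613, 1.593, 0.7630,
             0.4584, 0.2217, 0.1559, 0.1119, 0.09413, 0.08362, 0.07625,
             0.06605, 0.05901)
)

props <- list(
  # name = list(Z/A effective, density g/cm3, rayleigh b at 100 keV,
  #             effective atomic number)
  water         = list(zoa = 0.5551, rho = 1.000,  b = 0.0055, zeff = 7.42),
  air           = list(zoa = 0.4992, rho = 0.001205, b = 0.0051, zeff = 7.64),
  bone_cortical = list(zoa = 0.5148, rho = 1.850,  b = 0.0090, zeff = 13.8),
  aluminium     = list(zoa = 0.4818, rho = 2.699,  b = 0.0080, zeff = 13.0),
  copper        = list(zoa = 0.4564, rho = 8.960,  b = 0.0190, zeff = 29.0),
  film_plastic  = list(zoa = 0.5390, rho = 1.200,  b = 0.0055, zeff = 7.0),
  tin           = list(zoa = 50 / 118.71, rho = 7.310, b = 0.050, zeff = 50),
  tungsten      = list(zoa = 74 / 183.84, rho = 19.30, b = 0.100, zeff = 74),
  iodine        = list(zoa = 53 / 126.90, rho = 4.930, b = 0.055, zeff = 53)
)

rayleigh_mu <- function(b, E) b * (100 / E)^1.9
compton_mu <- function(zoa, E) zoa * NA_AVOG * kn_sigma(E)

grid_E <- round(exp(seq(log(10), log(1000), length.out = 34)), 2)

make_anchored <- function(name, totals, extra_pe_scale = 1) {
  p <- props[[name]]
  comp_a <- compton_mu(p$zoa, anchor_E)
  ray_a <- rayleigh_mu(p$b, anchor_E)
  pe_a <- pmax(totals - comp_a - ray_a, 1e-6) * extra_pe_scale
  pe <- loglog_interp(anchor_E, pe_a, grid_E)
  comp <- compton_mu(p$zoa, grid_E)
  ray <- rayleigh_mu(p$b, grid_E)
  data.frame(energy_keV = grid_E, pe = pe, compton = comp, rayleigh = ray,
             total = pe + comp + ray)
}

make_heavy <- function(name, k_edge, pe_ref_E, pe_ref, expo, jump) {
  # photoelectric: pe_ref * (pe_ref_E/E)^expo above the K edge, continuous
  # power law (slope 3) below it after dividing by the edge jump
  p <- props[[name]]
  E <- sort(unique(c(grid_E, k_edge - 0.01, k_edge + 0.01)))
  pe_above <- pe_ref * (pe_ref_E / E)^expo
  pe_edge_above <- pe_ref * (pe_ref_E / k_edge)^expo
  pe_below <- (pe_edge_above / jump) * (k_edge / E)^3
  pe <- ifelse(E >= k_edge, pe_above, pe_below)
  comp <- compton_mu(p$zoa, E)
  ray <- rayleigh_mu(p$b, E)
  data.frame(energy_keV = E, pe = pe, compton = comp, rayleigh = ray,
             total = pe + comp + ray)
}

out <- list(
  water = make_anchored("water", anchors$water),
  air = make_anchored("air", anchors$air),
  bone_cortical = make_anchored("bone_cortical", anchors$bone_cortical),
  aluminium = make_anchored("aluminium", anchors$aluminium),
  copper = make_anchored("copper", anchors$copper),
  # film-equivalent plastic: near water-equivalent; photoelectric slightly
  # lower (lower effective Z of the polyester/active-layer mix)
  film_plastic = make_anchored("film_plastic", anchors$water,
                               extra_pe_scale = 0.90),
  # iodine anchored to 3.5 cm2/g at 80 keV (PE remainder there) and sloped so
  # the total at 1 MeV is 0.058 cm2/g; K edge 33.17 keV
  iodine = make_heavy("iodine", 33.17, 80,
                      pe_ref = 3.5 - compton_mu(props$iodine$zoa, 80) -
                        rayleigh_mu(props$iodine$b, 80),
                      expo = 2.64, jump = 5.8),
  # tin scaled from the iodine anchor by (Z_Sn/Z_I)^4.5 * (A_I/A_Sn)
  tin = make_heavy("tin", 29.20, 80,
                   pe_ref = (3.5 - compton_mu(props$iodine$zoa, 80) -
                               rayleigh_mu(props$iodine$b, 80)) *
                     (50 / 53)^4.5 * (126.9 / 118.71),
                   expo = 2.70, jump = 5.4),
  # tungsten anchored at the 100-keV total 4.438 cm2/g; K edge 69.53 keV
  tungsten = make_heavy("tungsten", 69.53, 100,
                        pe_ref = 4.438 - compton_mu(props$tungsten$zoa, 100) -
                          rayleigh_mu(props$tungsten$b, 100),
                        expo = 2.70, jump = 4.5)
)

dir.create("inst/extdata/materials", recursive = TRUE, showWarnings = FALSE)
dens <- data.frame(material = names(props),
                   density_g_cm3 = vapply(props, `[[`, 0, "rho"),
                   z_eff = vapply(props, `[[`, 0, "zeff"))
write.csv(dens, "inst/extdata/materials/densities.csv", row.names = FALSE)
for (nm in names(out)) {
  df <- out[[nm]]
  df[, -1] <- signif(df[, -1], 6)
  write.csv(df, sprintf("inst/extdata/materials/%s.csv", nm),
            row.names = FALSE)
}
# CSDA range of electrons in liquid water (ESTAR), g/cm2
estar <- data.frame(
  energy_keV = c(10, 20, 30, 40, 50, 60, 80, 100, 150, 200, 300, 400, 500),
  csda_g_cm2 = c(2.515e-4, 8.566e-4, 1.756e-3, 2.919e-3, 4.320e-3, 5.938e-3,
                 9.773e-3, 1.431e-2, 2.817e-2, 4.488e-2, 8.421e-2, 1.280e-1,
                 1.766e-1)
)
write.csv(estar, "inst/extdata/materials/electron_range_water.csv",
          row.names = FALSE)
cat("wrote", length(out), "material tables\n")
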