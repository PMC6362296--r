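Package: oxminibeam
Title: Orthovoltage X-Ray Minibeam Dosimetry and Merging-Depth Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale dosimetry toolkit for merging orthovoltage x-ray
    minibeam arrays: filtered bremsstrahlung spectrum models with half-value
    layer tuning, embedded photon mass-attenuation tables, closed-form
    finite-source multislit collimator optics (beam widening, merge-onset
    prediction and solvers), a compact voxelized 2-D photon Monte Carlo with
    an analytic primary-dose oracle, peak-to-valley dose-ratio and
    merging-depth analysis, a 350-micron valley-minimum biologic dose model,
    penumbra and depth-dose metrics, and a synthetic radiochromic-film
    forward/inverse model for film-based array dosimetry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tiff,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
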