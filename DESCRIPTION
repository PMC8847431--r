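Package: hccimager
Title: Multi-Modal 3D Radionuclide Imaging with Hybrid Compton Cameras
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and reconstruction toolkit for a ring of two-plane
    hybrid Compton cameras that image gamma-emitting radionuclides in three
    modalities at once: Compton imaging of high-energy photons scattered in
    the front detector plane, pinhole imaging of low-energy photons passing
    the central aperture of the front plane, and PET imaging of coincident
    511 keV annihilation pairs detected by two different cameras. Includes a
    list-mode Monte Carlo event generator with embedded nuclide emission and
    photon attenuation tables, coincidence grouping and hit-pattern event
    selection with per-nuclide energy windows, list-mode MLEM reconstruction
    with a Gaussian-broadened cone system matrix, hist-mode pinhole MLEM,
    exact ray-traced back projection of PET lines of response, and a
    photopeak-ratio spectral analysis that estimates the thickness of water
    between source and camera.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    data.table,
    stats,
    utils,
    jsonlite,
    yaml,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    RNifti,
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
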