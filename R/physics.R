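# Embedded photon-interaction and nuclide data.
#
# Mass attenuation coefficients (cm^2/g) are digitized from standard photon
# cross-section compilations on a coarse energy grid and interpolated
# log-log.  For water the "total" column includes coherent scattering (the
# narrow-beam Beer-Lambert coefficient); for GAGG coherent scattering is
# ignored and interactions are partitioned into photoelectric absorption and
# incoherent (Compton) scattering only.

.water_table <- data.frame(
  energy = c(30, 40, 50, 60, 80, 100, 150, 200, 300, 400,
             500, 600, 800, 1000, 1250, 1500),
  total  = c(0.3756, 0.2683, 0.2269, 0.2059, 0.1837, 0.1707, 0.1505, 0.1370,
             0.1186, 0.1061, 0.09687, 0.08956, 0.07865, 0.07072, 0.06323,
             0.05754),
  pe     = c(0.1500, 0.0633, 0.0320, 0.0187, 0.0079, 0.0040, 0.0012, 5.0e-4,
             1.5e-4, 6.0e-5, 3.0e-5, 1.8e-5, 8.0e-6, 4.5e-6, 2.5e-6, 1.6e-6),
  incoh  = c(0.1770, 0.1805, 0.1800, 0.1770, 0.1700, 0.1630, 0.1460, 0.1330,
             0.1155, 0.1040, 0.0950, 0.0880, 0.0770, 0.0700, 0.0625, 0.0570)
)

# GAGG (Gd3Al2Ga3O12, density 6.63 g/cm^3).  Photoelectric column is an
# element-weighted digitization dominated by Gd (K edge at 50.2 keV; the
# edge is represented by two adjacent grid points).  Incoherent column is
# the electron-density scaling of the water incoherent cross section
# (Z/A = 0.439 vs 0.555).
.gagg_table <- data.frame(
  energy = c(30, 40, 50, 50.3, 60, 80, 93, 100, 150, 200, 245, 300, 356,
             400, 511, 600, 662, 800, 1000, 1275, 1500),
  total  = NA_real_,
  pe     = c(5.8, 2.65, 1.44, 8.5, 5.29, 2.45, 1.62, 1.34, 0.45, 0.205,
             0.118, 0.069, 0.043, 0.0315, 0.0167, 0.011, 0.0086, 0.0052,
             0.0031, 0.0019, 0.0014),
  incoh  = c(0.140, 0.143, 0.142, 0.142, 0.140, 0.134, 0.131, 0.129, 0.115,
             0.105, 0.0975, 0.0914, 0.0880, 0.0823, 0.0756, 0.0696, 0.0668,
             0.0609, 0.0554, 0.0491, 0.0451)
)
.gagg_table$total <- .gagg_table$pe + .gagg_table$incoh

.material_density <- c(water = 1.0, gagg = 6.63)

.material_table <- function(material) {
  switch(material,
         water = .water_table,
         gagg  = .gagg_table,
         stop("unknown material: ", material))
}

#' Linear attenuation coefficient of a material
#'
#' Interpolates the embedded mass-attenuation tables log-log in energy and
#' multiplies by the material density.  For water the coefficient is the
#' narrow-beam total (including coherent scattering); for GAGG it is the sum
#' of the photoelectric and incoherent components.
#'
#' @param energy_kev photon energies in keV (vectorized).
#' @param material `"water"` or `"gagg"`.
#' @param component `"total"`, `"pe"` (photoelectric) or `"incoh"`
#'   (incoherent/Compton).
#' @return linear attenuation coefficients in cm^-1.
#' @export
#' @examples
#' exp(-attenuation_mu(356, "water") * 5)  # transmission of 5 cm water
attenuation_mu <- function(energy_kev, material = "water", component = "total") {
  tab <- .material_table(material)
  if (!component %in% c("total", "pe", "incoh"))
    stop("unknown component: ", component)
  if (any(energy_kev <= 0)) stop("energy must be positive")
  e <- pmin(pmax(energy_kev, min(tab$energy)), max(tab$energy))
  mu_rho <- exp(stats::approx(log(tab$energy), log(tab[[component]]),
                              xout = log(e), rule = 2)$y)
  mu_rho * .material_density[[material]]
}

#' Photoelectric fraction of the interaction cross section
#'
#' @inheritParams attenuation_mu
#' @return fraction of interactions that are photoelectric (vectorized).
#' @export
photoelectric_fraction <- function(energy_kev, material = "gagg") {
  pe <- attenuation_mu(energy_kev, material, "pe")
  inc <- attenuation_mu(energy_kev, material, "incoh")
  pe / (pe + inc)
}

# --- nuclide emission tables ------------------------------------------------

# intensity: photons (or annihilation pairs) per decay; kind "gamma" or
# "pair" (back-to-back 511 keV annihilation photons).
.nuclide_lines <- list(
  cs137 = data.frame(energy = 661.66, intensity = 0.851, kind = "gamma"),
  am241 = data.frame(energy = 59.54, intensity = 0.359, kind = "gamma"),
  na22  = data.frame(energy = c(511, 1274.5), intensity = c(0.898, 0.9994),
                     kind = c("pair", "gamma")),
  ga67  = data.frame(energy = c(93.31, 184.58, 208.95, 300.22, 393.53),
                     intensity = c(0.388, 0.212, 0.0233, 0.168, 0.0468),
                     kind = "gamma"),
  in111 = data.frame(energy = c(171.28, 245.35), intensity = c(0.907, 0.941),
                     kind = "gamma"),
  at211 = data.frame(energy = c(79.0, 569.7, 687.0, 897.8),
                     intensity = c(0.21, 0.0029, 0.0026, 0.0007),
                     kind = "gamma"),
  ba133 = data.frame(energy = c(53.16, 79.61, 81.00, 160.61, 223.24, 276.40,
                                302.85, 356.01, 383.85),
                     intensity = c(0.0214, 0.0265, 0.329, 0.00638, 0.0045,
                                   0.0716, 0.1834, 0.6205, 0.0894),
                     kind = "gamma")
)

#' Emission lines of a nuclide
#'
#' Returns the embedded gamma/annihilation emission table of a supported
#' nuclide: energies in keV and intensities in photons (or annihilation
#' pairs) per decay.  Low-energy X rays below the detector range are not
#' tabulated.
#'
#' @param nuclide one of `"cs137"`, `"am241"`, `"na22"`, `"ga67"`,
#'   `"in111"`, `"at211"`, `"ba133"`.
#' @return data.frame with columns `energy`, `intensity`, `kind`.
#' @export
nuclide_lines <- function(nuclide) {
  nuclide <- tolower(nuclide)
  if (!nuclide %in% names(.nuclide_lines))
    stop("unknown nuclide: ", nuclide)
  .nuclide_lines[[nuclide]]
}

# --- energy resolution model ------------------------------------------------

.default_resolution_points <- data.frame(
  energy  = c(662, 511, 60),
  fwhm_pc = c(7.3, 7.8, 22.8),
  fwhm_pc_err = c(0.8, 0.8, 1.2)
)

#' Fit the detector energy-resolution model
#'
#' The pixel energy resolution is modeled as
#' \eqn{FWHM(E)\,[\%] = \sqrt{\alpha + \beta / E}}, the usual statistical
#' photopeak-broadening form, fitted by least squares on FWHM^2 against 1/E.
#'
#' @param points data.frame with columns `energy` (keV) and `fwhm_pc`
#'   (FWHM in percent); defaults to the measured calibration points of the
#'   GAGG camera pixels (7.3\% at 662 keV, 7.8\% at 511 keV, 22.8\% at
#'   60 keV).
#' @return object of class `hcc_resolution` with elements `alpha`, `beta`
#'   and a `fwhm_pc(E)` evaluator.
#' @export
fit_resolution_model <- function(points = .default_resolution_points) {
  fit <- stats::lm(I(fwhm_pc^2) ~ I(1 / energy), data = points)
  alpha <- unname(stats::coef(fit)[1])
  beta <- unname(stats::coef(fit)[2])
  structure(list(alpha = alpha, beta = beta, points = points), # nolint
            class = "hcc_resolution")
}

#' Evaluate the fitted FWHM(E) resolution curve
#'
#' @param model an `hcc_resolution` object from [fit_resolution_model()].
#' @param energy_kev energies in keV.
#' @return FWHM in percent of the energy.
#' @export
resolution_fwhm_pc <- function(model, energy_kev) {
  sqrt(pmax(model$alpha + model$beta / energy_kev, 0))
}

#' Apply Gaussian energy blur
#'
#' Blurs deposited energies with the Gaussian whose FWHM follows the fitted
#' resolution model; results are floored at a small positive value so that
#' deposits remain physical.
#'
#' @param energy_kev true deposited energies in keV.
#' @param model an `hcc_resolution` object (default: the fitted calibration
#'   curve of the camera pixels).
#' @return blurred energies in keV.
#' @export
blur_energy <- function(energy_kev, model = fit_resolution_model()) {
  sigma <- resolution_fwhm_pc(model, energy_kev) / 100 * energy_kev / 2.3548
  pmax(energy_kev + stats::rnorm(length(energy_kev), 0, sigma), 0.1)
}

#' @export
print.hcc_resolution <- function(x, ...) {
  cat(sprintf("Energy resolution model: FWHM%%(E) = sqrt(%.3f + %.1f/E)\n",
              x$alpha, x$beta))
  invisible(x)
}
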