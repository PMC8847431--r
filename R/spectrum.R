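# Spectral analysis for the body-component study: energy histograms,
# Gaussian + linear-background photopeak fits, the 81/356 keV
# photopeak-ratio-vs-water-thickness calibration, and thickness inversion.
#
# Beer-Lambert physics makes ln R linear in thickness with slope
# -(mu(81) - mu(356)) ~ -0.072 /cm, so the calibration is a weighted
# log-linear fit and the inversion is closed form.

#' Energy spectrum of events
#'
#' Histograms the per-event total deposited energy.  If the input carries an
#' `event_id` column (see [group_coincidences()]) deposits are summed per
#' event first; otherwise each hit is its own event.
#'
#' @param events hits data.frame.
#' @param bin_width bin width in keV.
#' @param range energy range in keV (two values).
#' @param live_time_s live time bookkeeping (seconds), stored on the
#'   spectrum.
#' @return a `hcc_spectrum`: list with `edges` (bin edges, keV), `counts`
#'   and `live_time_s`.
#' @export
histogram_spectrum <- function(events, bin_width = 1, range = c(0, 800),
                               live_time_s = NA_real_) {
  stopifnot(bin_width > 0, length(range) == 2, range[2] > range[1])
  edges <- seq(range[1], range[2], by = bin_width)
  if (nrow(events) == 0) {
    e_tot <- numeric(0)
  } else if ("event_id" %in% names(events)) {
    e_tot <- as.vector(tapply(events$energy_kev, events$event_id, sum))
  } else {
    e_tot <- events$energy_kev
  }
  e_tot <- e_tot[e_tot >= range[1] & e_tot < range[2]]
  counts <- tabulate(findInterval(e_tot, edges, rightmost.closed = FALSE),
                     nbins = length(edges) - 1)
  structure(list(edges = edges, counts = counts, live_time_s = live_time_s),
            class = "hcc_spectrum")
}

#' Merge spectra (additivity over runs)
#'
#' @param a,b `hcc_spectrum` objects with identical binning.
#' @export
merge_spectra <- function(a, b) {
  stopifnot(identical(a$edges, b$edges))
  structure(list(edges = a$edges, counts = a$counts + b$counts,
                 live_time_s = a$live_time_s + b$live_time_s),
            class = "hcc_spectrum")
}

#' @export
print.hcc_spectrum <- function(x, ...) {
  cat(sprintf("Spectrum: %d bins [%g, %g] keV, %d counts\n",
              length(x$counts), min(x$edges), max(x$edges), sum(x$counts)))
  invisible(x)
}

#' Fit a photopeak with a Gaussian plus linear background
#'
#' Least-squares fit of `A exp(-(E-c)^2 / 2s^2) + b0 + b1 (E-E0)` inside
#' the window `[E0 - w, E0 + w]`.  The net area is the Gaussian integral in
#' counts.  The local linear background makes the area robust to the
#' Compton-scatter continuum that grows with absorber thickness.
#'
#' @param spec a `hcc_spectrum`.
#' @param e0 nominal peak energy, keV.
#' @param window window half width in keV (must cover at least 5 bins).
#' @return a `hcc_peakfit`: `centroid`, `sigma`, `area` (net counts),
#'   `area_err`, plus the fit object.
#' @export
fit_photopeak <- function(spec, e0, window) {
  bw <- diff(spec$edges)[1]
  if (2 * window / bw < 5) stop("window must cover at least 5 bins")
  mid <- spec$edges[-length(spec$edges)] + bw / 2
  sel <- mid >= e0 - window & mid <= e0 + window
  x <- mid[sel]; y <- spec$counts[sel]
  if (sum(y) == 0) stop("no counts in the fit window")
  xc <- x - e0
  bg0 <- min(y)
  amp0 <- max(y) - bg0
  cen0 <- sum(x * pmax(y - bg0, 0)) / max(sum(pmax(y - bg0, 0)), 1)
  resid_fn <- function(p)
    y - (p[1] * exp(-(x - p[2])^2 / (2 * p[3]^2)) + p[4] + p[5] * xc)
  out <- tryCatch(
    minpack.lm::nls.lm(par = c(A = max(amp0, 1), cen = cen0,
                               sig = window / 3, b0 = bg0, b1 = 0),
                       fn = resid_fn,
                       lower = c(0, e0 - window, bw / 2, -Inf, -Inf),
                       upper = c(Inf, e0 + window, 2 * window, Inf, Inf),
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("photopeak fit failed near ", e0, " keV: ",
                             conditionMessage(e)))
  if (out$info %in% c(0, 5, 9))
    stop("photopeak fit did not converge near ", e0, " keV: ", out$message)
  cf <- out$par
  # parameter covariance from the Gauss-Newton hessian
  vc <- tryCatch({
    rdf <- length(out$fvec) - length(cf)
    chol2inv(chol(out$hessian)) * stats::deviance(out) / rdf
  }, error = function(e) matrix(0, 5, 5))
  area <- cf[["A"]] * abs(cf[["sig"]]) * sqrt(2 * pi) / bw
  # delta method on (A, sig)
  gA <- abs(cf[["sig"]]) * sqrt(2 * pi) / bw
  gs <- cf[["A"]] * sqrt(2 * pi) / bw
  var_area <- gA^2 * vc[1, 1] + gs^2 * vc[3, 3] + 2 * gA * gs * vc[1, 3]
  structure(list(centroid = unname(cf[["cen"]]), sigma = abs(cf[["sig"]]),
                 area = max(area, 0), area_err = sqrt(max(var_area, 0)),
                 fit = out),
            class = "hcc_peakfit")
}

#' Build the photopeak-ratio vs thickness calibration
#'
#' For each (thickness, spectrum) node, fits the two photopeaks and forms
#' the net-area ratio `R = area(peak1)/area(peak2)`; then fits the
#' log-linear attenuation model `ln R = ln R0 - dmu * d` by weighted least
#' squares (weights from the propagated ratio errors).
#'
#' @param thicknesses slab thicknesses in cm (>= 3 distinct values).
#' @param spectra list of `hcc_spectrum`, one per thickness.
#' @param peaks the two peak energies in keV (default 81 and 356).
#' @param window fit window half widths in keV for the two peaks.
#' @return a `hcc_calibration`: node table, `R0`, `dmu` (cm^-1), and the
#'   underlying `lm` fit.
#' @export
build_calibration <- function(thicknesses, spectra, peaks = c(81, 356),
                              window = c(25, 35)) {
  stopifnot(length(thicknesses) == length(spectra),
            length(unique(thicknesses)) >= 3)
  nodes <- lapply(seq_along(thicknesses), function(i) {
    f1 <- fit_photopeak(spectra[[i]], peaks[1], window[1])
    f2 <- fit_photopeak(spectra[[i]], peaks[2], window[2])
    R <- f1$area / f2$area
    rel <- sqrt((f1$area_err / f1$area)^2 + (f2$area_err / f2$area)^2)
    data.frame(thickness = thicknesses[i], ratio = R, ratio_err = R * rel)
  })
  nodes <- do.call(rbind, nodes)
  ord <- order(nodes$thickness)
  rr <- nodes$ratio[ord]
  if (any(diff(rr) > 3 * sqrt(nodes$ratio_err[ord][-1]^2 +
                              nodes$ratio_err[ord][-length(rr)]^2)))
    warning("photopeak ratios are non-monotone in thickness beyond noise")
  w <- 1 / pmax(nodes$ratio_err / nodes$ratio, 1e-6)^2
  fit <- stats::lm(log(ratio) ~ thickness, data = nodes, weights = w)
  cf <- stats::coef(fit)
  structure(list(nodes = nodes, R0 = exp(unname(cf[1])),
                 dmu = -unname(cf[2]), fit = fit,
                 vcov = stats::vcov(fit), peaks = peaks),
            class = "hcc_calibration")
}

#' @export
print.hcc_calibration <- function(x, ...) {
  cat(sprintf("Photopeak-ratio calibration: R0 = %.4f, dmu = %.4f /cm (%d nodes)\n",
              x$R0, x$dmu, nrow(x$nodes)))
  invisible(x)
}

#' Invert the calibration for material thickness
#'
#' Closed-form inversion of the log-linear model,
#' \eqn{\hat d = \ln(R_0 / R) / \Delta\mu}, with the uncertainty propagated
#' from the measured-ratio error and the calibration-fit covariance.
#'
#' @param ratio measured photopeak ratio (> 0).
#' @param curve a `hcc_calibration`.
#' @param ratio_err standard error of the measured ratio.
#' @return list with `thickness_cm` and `thickness_err_cm`.
#' @export
estimate_thickness <- function(ratio, curve, ratio_err = 0) {
  stopifnot(ratio > 0)
  b0 <- log(curve$R0); slope <- -curve$dmu
  d <- (b0 - log(ratio)) / curve$dmu
  g <- c(1 / curve$dmu, d / curve$dmu)   # d(d)/d(b0), d(d)/d(slope)
  var_fit <- as.numeric(t(g) %*% curve$vcov %*% g)
  var_r <- (ratio_err / (curve$dmu * ratio))^2
  err <- sqrt(var_fit + var_r)
  if (d < 0 && abs(d) > max(3 * err, 0.5))
    stop("measured ratio exceeds R0 beyond tolerance (negative thickness)")
  list(thickness_cm = d, thickness_err_cm = err)
}
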