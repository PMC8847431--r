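test_that("spectra histogram per-event totals and add over runs", {
  ev <- data.frame(time_ns = c(0, 5), camera_id = 0L,
                   plane = c("front", "rear"), ix = 22L, iy = 22L,
                   energy_kev = c(100, 256), event_id = 1L)
  sp <- histogram_spectrum(ev, bin_width = 1, range = c(0, 800))
  expect_equal(sum(sp$counts), 1)
  expect_equal(sp$counts[357], 1)           # bin [356, 357)
  # additivity: two half runs equal one full run
  set.seed(19)
  hits <- data.frame(time_ns = sort(runif(400, 0, 1e6)), camera_id = 0L,
                     plane = "rear", ix = 22L, iy = 22L,
                     energy_kev = runif(400, 20, 700))
  ha <- hits[1:200, ]; hb <- hits[201:400, ]
  spa <- histogram_spectrum(group_coincidences(ha), live_time_s = 10)
  spb <- histogram_spectrum(group_coincidences(hb), live_time_s = 10)
  spf <- histogram_spectrum(group_coincidences(hits), live_time_s = 20)
  m <- merge_spectra(spa, spb)
  expect_equal(m$counts, spf$counts)
  expect_equal(m$live_time_s, 20)
  expect_equal(sum(histogram_spectrum(hits[0, ])$counts), 0)
})

test_that("photopeak fit recovers a known Gaussian over background", {
  set.seed(20)
  edges <- seq(0, 800, 1)
  mid <- edges[-length(edges)] + 0.5
  truth_area <- 1e4
  lam <- truth_area * dnorm(mid, 356, 5) + 20
  counts <- rpois(length(lam), lam)
  sp <- structure(list(edges = edges, counts = counts, live_time_s = 1),
                  class = "hcc_spectrum")
  f <- fit_photopeak(sp, 356, 30)
  expect_equal(f$centroid, 356, tolerance = 0.5)
  expect_lt(abs(f$area - truth_area), 3 * sqrt(truth_area + f$area_err^2))
  # empty window errors
  sp0 <- structure(list(edges = edges, counts = integer(799),
                        live_time_s = 1), class = "hcc_spectrum")
  expect_error(fit_photopeak(sp0, 356, 30), "no counts")
  expect_error(fit_photopeak(sp, 356, 2), "5 bins")
})

test_that("noise-free attenuation nodes recover the known mu difference", {
  edges <- seq(0, 800, 1)
  mid <- edges[-length(edges)] + 0.5
  mu81 <- attenuation_mu(81, "water"); mu356 <- attenuation_mu(356, "water")
  ths <- seq(0, 12, 2)
  spectra <- lapply(ths, function(d) {
    lam <- 5e5 * exp(-mu81 * d) * dnorm(mid, 81, 8) +
      2e5 * exp(-mu356 * d) * dnorm(mid, 356, 15) + 50
    structure(list(edges = edges, counts = round(lam), live_time_s = 1),
              class = "hcc_spectrum")
  })
  cal <- build_calibration(ths, spectra)
  expect_equal(cal$dmu, mu81 - mu356, tolerance = 5e-3)
  expect_gt(cal$R0, 0)
  # inverse consistency: a ratio on the fitted curve returns its thickness
  for (d in c(0, 3.3, 7)) {
    r <- cal$R0 * exp(-cal$dmu * d)
    expect_equal(estimate_thickness(r, cal)$thickness_cm, d,
                 tolerance = 1e-9)
  }
  expect_error(estimate_thickness(cal$R0 * 3, cal), "negative")
})

test_that("simulated round trip estimates a held-out thickness", {
  set.seed(27)
  setup <- acquisition_setup(n_cameras = 1, angles_deg = 0)
  src <- source_spec("ba133", 3.7e5, c(0, 0, -30))
  run <- function(d, dur = 300) {
    ph <- if (d > 0) phantom_slab(d, 0L) else NULL
    h <- simulate_acquisition(src, setup, phantoms = ph, duration_s = dur)
    histogram_spectrum(group_coincidences(h), live_time_s = dur)
  }
  ths <- seq(0, 12, 2)
  cal <- build_calibration(ths, lapply(ths, run))
  sp3 <- run(3)
  f1 <- fit_photopeak(sp3, 81, 25); f2 <- fit_photopeak(sp3, 356, 35)
  est <- estimate_thickness(f1$area / f2$area, cal)
  expect_lt(abs(est$thickness_cm - 3), 0.5)
  # the ratio estimator is invariant under live-time rescaling
  spl <- run(3, dur = 600)
  g1 <- fit_photopeak(spl, 81, 25); g2 <- fit_photopeak(spl, 356, 35)
  expect_equal(g1$area / g2$area, f1$area / f2$area, tolerance = 0.15)
})
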