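test_that("Klein-Nishina sampler matches the Compton relation and pdf", {
  # forward limit and the 662 keV back-scatter energy
  expect_equal(662 / (1 + 662 / 511 * (1 - cos(pi))), 184.3, tolerance = 0.1)
  set.seed(11)
  kn <- sample_klein_nishina(rep(662, 2e5))
  expect_true(all(kn$energy_out <= 662 & kn$energy_out >= 184))
  expect_equal(kn$energy_out,
               662 / (1 + 662 / 511 * (1 - cos(kn$theta))), tolerance = 1e-9)
  # chi-square goodness of fit of cos(theta) against the analytic dcs
  set.seed(12)
  kn <- sample_klein_nishina(rep(662, 1e6))
  br <- seq(-1, 1, length.out = 41)
  obs <- tabulate(findInterval(cos(kn$theta), br, rightmost.closed = TRUE,
                               all.inside = TRUE), 40)
  dens <- vapply(seq_len(40), function(i)
    stats::integrate(function(c) klein_nishina_dcs(662, c),
                     br[i], br[i + 1])$value, numeric(1))
  expd <- dens / sum(dens) * length(kn$theta)
  chi2 <- sum((obs - expd)^2 / expd)
  p <- stats::pchisq(chi2, df = 39, lower.tail = FALSE)
  expect_gt(p, 0.01)
})

test_that("aperture-passing photons project into the axial hole shadow", {
  # thick front slab removes septal penetration, so every rear hit comes
  # through the hole; for a source at the origin the 3 mm hole projects to
  # a 3.8 mm shadow (150/190 magnification) on the rear plane
  setup <- shielded_setup()
  src <- mono_source(59.54, 3e6)
  hits <- simulate_acquisition(src, setup, duration_s = 1, seed = 21,
                               blur = FALSE)
  # full-energy rear hits are the aperture passers; rear hits from photons
  # Compton-scattered inside the front slab carry less energy
  rear <- hits[hits$plane == "rear" & hits$energy_kev == 59.54, ]
  expect_gt(nrow(rear), 100)
  u <- rear$ix - 22  # pixel offsets; shadow half width 1.9 mm spans +/- 2 px
  v <- rear$iy - 22
  expect_true(all(abs(u) <= 2 & abs(v) <= 2))
})

test_that("pinhole rate scales with aperture area", {
  src <- mono_source(59.54, 3e6)
  n_rear <- function(hw) {
    h <- simulate_acquisition(src, shielded_setup(hole_hw = hw),
                              duration_s = 1, seed = 22, blur = FALSE)
    sum(h$plane == "rear" & h$energy_kev == 59.54)  # aperture passers
  }
  n1 <- n_rear(1.5)
  n2 <- n_rear(3.0)
  expect_equal(n2 / n1, 4, tolerance = 4 * sqrt(1 / n1 + 1 / n2))
})

test_that("annihilation pairs arrive back to back in opposite cameras", {
  setup <- single_angle_setup()
  # pure annihilation-pair emitter isolates the coincidence geometry from
  # cascade-gamma contamination
  pos_src <- source_spec("custom", 5e4,
                         lines = data.frame(energy = 511, intensity = 1,
                                            kind = "pair"))
  hits <- simulate_acquisition(pos_src, setup, duration_s = 5, seed = 23,
                               blur = FALSE)
  pairs <- pair_pet_events(group_coincidences(hits), setup)
  expect_gt(nrow(pairs), 50)
  expect_true(all(abs(pairs$cam_a - pairs$cam_b) == 2))  # opposite cameras
  # every LOR passes within about a pixel pitch of the emission point
  ap <- as.matrix(pairs[, c("ax", "ay", "az")])
  bp <- as.matrix(pairs[, c("bx", "by", "bz")])
  d <- ap - bp
  tpar <- rowSums(-bp * d) / rowSums(d^2)
  closest <- bp + d * tpar
  expect_lt(max(sqrt(rowSums(closest^2))), 2.4)
})

test_that("energy is conserved through the camera (blur off)", {
  setup <- single_angle_setup()
  hits <- simulate_acquisition(mono_source(661.66, 5e5), setup,
                               duration_s = 1, seed = 24, blur = FALSE,
                               threshold_kev = 0)
  ev <- group_coincidences(hits)
  # per-event deposits exceed the emitted energy only through the rare
  # random coincidence of two photons inside one window
  tot <- tapply(ev$energy_kev, ev$event_id, sum)
  expect_gt(mean(tot <= 661.66 + 1e-9), 0.99)
  ce <- extract_compton_events(ev, setup, "cs137")
  expect_gt(nrow(ce), 10)
  expect_gt(mean(abs(ce$E_f + ce$E_r - 661.66) < 1e-9), 0.9)
})

test_that("water-slab transmission follows exp(-mu d)", {
  setup <- acquisition_setup(n_cameras = 1, angles_deg = 0)
  for (cfg in list(list(e = 356, d = 5), list(e = 81, d = 5))) {
    src <- mono_source(cfg$e, 4e5)
    n0 <- nrow(simulate_acquisition(src, setup, duration_s = 1, seed = 25,
                                    blur = FALSE))
    nd <- nrow(simulate_acquisition(src, setup,
                                    phantoms = phantom_slab(cfg$d, 0L),
                                    duration_s = 1, seed = 26, blur = FALSE))
    expected <- exp(-attenuation_mu(cfg$e, "water") * cfg$d)
    sigma <- expected * sqrt(1 / nd + 1 / n0)
    # 3 sigma binomial plus a 1% allowance for the slant-path spread
    expect_lt(abs(nd / n0 - expected), 3 * sigma + 0.01 * expected)
  }
})

test_that("simulation is reproducible and efficiency is stable in size", {
  setup <- single_angle_setup()
  src <- source_spec("am241", 1e6)
  h1 <- simulate_acquisition(src, setup, duration_s = 1, seed = 31)
  h2 <- simulate_acquisition(src, setup, duration_s = 1, seed = 31)
  expect_identical(h1, h2)
  eff <- function(dur, seed) {
    h <- simulate_acquisition(src, setup, duration_s = dur, seed = seed)
    ph <- extract_pinhole_events(group_coincidences(h), setup, "am241")
    absolute_efficiency(nrow(ph), h, 59.54)
  }
  e1 <- eff(1, 32)
  e2 <- eff(2, 33)
  expect_equal(e1, e2, tolerance = 6 / sqrt(300))  # binomial-level agreement
  expect_equal(absolute_efficiency(0, 100), 0)
})
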