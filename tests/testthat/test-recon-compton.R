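test_that("cone kernel evaluates the system-matrix formula", {
  # Theta = theta = 90 deg, a = 2 mm, d = 100 mm
  sc <- c(0, 0, 0); ab <- c(0, 0, 40)      # axis = -z; voxel at 90 deg
  t90 <- system_matrix_element(sc, ab, pi / 2, c(100, 0, 0), 2, 0.05)
  expect_equal(t90, 2 * pi * (1 - 100 / sqrt(10004)), tolerance = 1e-12)
  # one Gaussian width off the cone scales by exp(-1/2)
  sigma <- 2.5 * pi / 180
  th <- pi / 3
  vox_on <- c(sin(th) * 100, 0, -cos(th) * 100)
  vox_off <- c(sin(th + sigma) * 100, 0, -cos(th + sigma) * 100)
  t_on <- system_matrix_element(sc, ab, th, vox_on, 2, sigma)
  t_off <- system_matrix_element(sc, ab, th, vox_off, 2, sigma)
  expect_equal(t_off / t_on, exp(-0.5), tolerance = 1e-9)
  # far-field decay
  expect_lt(system_matrix_element(sc, ab, pi / 2, c(1e6, 0, 0), 2, 0.05),
            1e-10)
})

test_that("compiled cone matrix matches the scalar transcription", {
  set.seed(5)
  K <- 20; J <- 10
  sc <- cbind(runif(K, -20, 20), runif(K, -20, 20), rep(150, K))
  ab <- sc + matrix(rnorm(3 * K, sd = 3), K, 3); ab[, 3] <- 190
  th <- runif(K, 0.3, 1.2)
  vox <- cbind(runif(J, -25, 25), runif(J, -25, 25), runif(J, -25, 25))
  ev <- data.frame(sx = sc[, 1], sy = sc[, 2], sz = sc[, 3],
                   ax = ab[, 1], ay = ab[, 2], az = ab[, 3],
                   theta = th, angle_id = 0L)
  grid <- voxel_grid(2, 2.3)  # only used for a; compare on explicit voxels
  sigma <- 2.5 * pi / 180
  tri <- hccimager:::cpp_cone_tkj(sc, hccimager:::.unit_rows(sc - ab), th,
                                  vox, 1.15, sigma, 1e9)
  dense <- matrix(0, K, J)
  dense[cbind(tri$i, tri$j)] <- tri$x
  for (k in seq_len(K)) for (j in seq_len(J)) {
    ref <- system_matrix_element(sc[k, ], ab[k, ], th[k], vox[j, ],
                                 1.15, sigma)
    # compare at 1e-12 relative inside the 3-sigma shell that the sparse
    # path retains; in the far Gaussian tail the z^2 exponent amplifies
    # last-bit angle rounding, so only agreement in magnitude is meaningful
    axis <- (sc[k, ] - ab[k, ]) / sqrt(sum((sc[k, ] - ab[k, ])^2))
    v <- vox[j, ] - sc[k, ]
    Theta <- acos(sum(v * axis) / sqrt(sum(v^2)))
    if (abs(Theta - th[k]) <= 3 * sigma) {
      expect_equal(dense[k, j], ref, tolerance = 1e-12)
    } else {
      expect_equal(dense[k, j], ref, tolerance = 1e-6)
    }
  }
})

test_that("list-mode MLEM matches the dense-loop oracle", {
  set.seed(6)
  K <- 15; J <- 8
  sc <- cbind(runif(K, -10, 10), runif(K, -10, 10), rep(150, K))
  ab <- sc; ab[, 3] <- 190
  th <- runif(K, 0.2, 0.5)
  grid <- voxel_grid(2, 12)   # 8 voxels
  vox <- voxel_centers(grid)
  sens <- matrix(runif(J, 0.5, 2), J, 1)
  oracle <- mlem_listmode_oracle(sc, ab, th, rep(0L, K), vox, 6,
                                 2.5 * pi / 180, sens, 5)
  ev <- data.frame(sx = sc[, 1], sy = sc[, 2], sz = sc[, 3],
                   ax = ab[, 1], ay = ab[, 2], az = ab[, 3],
                   E_f = 50, E_r = 600, theta = th, angle_id = 0L)
  img <- mlem_listmode(ev, grid, sens, sigma_deg = 2.5, n_iter = 5,
                       nsig = 1e9)
  expect_equal(as.vector(img$values), oracle, tolerance = 1e-12)
  expect_true(all(img$values >= 0))
})

test_that("single-voxel MLEM collapses to K/s and validates inputs", {
  grid <- voxel_grid(1, 4)
  K <- 7; s <- 0.35
  ev <- data.frame(sx = 0, sy = 0, sz = 150, ax = 0, ay = 0, az = 190,
                   E_f = rep(50, K), E_r = 600, theta = 0.4, angle_id = 0L)
  img <- mlem_listmode(ev, grid, matrix(s, 1, 1), sigma_deg = 50,
                       n_iter = 1, nsig = 1e9)
  expect_equal(as.vector(img$values), K / s, tolerance = 1e-12)
  expect_error(mlem_listmode(ev, grid, matrix(s, 1, 1), n_iter = 0))
})

test_that("log-likelihood is non-decreasing on small instances", {
  set.seed(8)
  K <- 30
  sc <- cbind(runif(K, -15, 15), runif(K, -15, 15), rep(150, K))
  ab <- sc; ab[, 3] <- 190
  th <- runif(K, 0.1, 0.4)
  grid <- voxel_grid(5, 8)
  ev <- data.frame(sx = sc[, 1], sy = sc[, 2], sz = sc[, 3],
                   ax = ab[, 1], ay = ab[, 2], az = ab[, 3],
                   E_f = 50, E_r = 600, theta = th, angle_id = 0L)
  img <- mlem_listmode(ev, grid, matrix(0.5, 125, 1), sigma_deg = 2.5,
                       n_iter = 12, nsig = 1e9)
  ll <- attr(img, "loglik")
  expect_true(all(diff(ll) > -1e-8 * abs(ll[-1])))
})

test_that("noiseless cones pass near the source and MLEM recovers it", {
  setup <- acquisition_setup()
  src_pos <- c(20, 0, 20)
  ev <- synthetic_compton_events(setup, src_pos, n_per_angle = 60, seed = 9)
  # cone consistency: the event cone surface contains the source direction
  axis <- hccimager:::.unit_rows(
    as.matrix(ev[, c("sx", "sy", "sz")]) - as.matrix(ev[, c("ax", "ay", "az")]))
  v <- matrix(src_pos, nrow(ev), 3, byrow = TRUE) -
    as.matrix(ev[, c("sx", "sy", "sz")])
  Theta <- acos(rowSums(v * axis) / sqrt(rowSums(v^2)))
  expect_lt(max(abs(Theta - ev$theta)), 1e-9)
  grid <- voxel_grid(21, 2.3)
  img <- mlem_listmode(ev, grid, NULL, sigma_deg = 2.5, n_iter = 10)
  pk <- find_peak(img)
  expect_true(all(abs(pk$position - src_pos) <= 2.3 + 1e-9))
})

test_that("sensitivity map is positive, smooth and reproducible", {
  setup <- acquisition_setup(4, c(0, 30))
  grid <- voxel_grid(9, 5)
  s1 <- sensitivity_mc(setup, grid, "cs137", n_photons = 2e5, seed = 10)
  expect_equal(dim(s1$s), c(729, 2))
  expect_true(all(s1$s > 0))
  s2 <- sensitivity_mc(setup, grid, "cs137", n_photons = 2e5, seed = 10)
  expect_identical(s1$s, s2$s)
  expect_error(sensitivity_mc(setup, grid, "am241"), "Compton")
})
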