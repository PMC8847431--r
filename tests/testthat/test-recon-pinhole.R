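test_that("system-matrix elements are solid angle times stopping power", {
  setup <- single_angle_setup()
  grid <- voxel_grid(5, 2.3)
  C <- pinhole_system_matrix(setup, grid, 60)
  jc <- (prod(grid$n) + 1) / 2              # voxel at the world origin
  i0 <- hccimager:::.bin_index(setup, 0L, 0L, 22L, 22L)
  omega <- 1 / 190^2                        # 1 mm^2 pixel at 190 mm, cos 0
  pint <- 1 - exp(-attenuation_mu(60, "gagg") * 0.5)
  expect_equal(C[i0, jc], omega * pint, tolerance = 1e-9)
  # 10 mm off-axis rear pixel is blocked by the front slab
  expect_equal(C[hccimager:::.bin_index(setup, 0L, 0L, 32L, 22L), jc], 0)
  # rear-slab interaction probability falls with energy
  pints <- vapply(c(60, 100, 245, 400), function(e)
    1 - exp(-attenuation_mu(e, "gagg") * 0.5), numeric(1))
  expect_true(all(diff(pints) < 0))
})

test_that("hist-mode MLEM reproduces hand-computed updates", {
  g1 <- voxel_grid(1, 2)
  # 1 voxel, 1 bin, c = 1, y = 5 -> lambda = 5
  C <- Matrix::sparseMatrix(i = 1, j = 1, x = 1, dims = c(1, 1))
  expect_equal(as.vector(mlem_hist(5, C, g1, 1)$values), 5)
  # 1 voxel, 2 bins, c = (1,1), y = (3,7) -> lambda = 5
  C2 <- Matrix::sparseMatrix(i = 1:2, j = c(1, 1), x = 1, dims = c(2, 1))
  expect_equal(as.vector(mlem_hist(c(3, 7), C2, g1, 1)$values), 5)
  # exact data are a fixed point of the update
  set.seed(13)
  g8 <- voxel_grid(2, 2)
  Cd <- Matrix::Matrix(matrix(runif(12 * 8, 0.1, 1), 12, 8), sparse = TRUE)
  lam_star <- runif(8, 0.5, 2)
  y <- as.vector(Cd %*% lam_star)
  img <- mlem_hist(y, Cd, g8, 1, lambda0 = lam_star)
  expect_equal(as.vector(img$values), lam_star, tolerance = 1e-12)
  expect_warning(mlem_hist(rep(0, 12), Cd, g8, 5), "all-zero")
})

test_that("hist-mode MLEM matches the dense-loop oracle and conserves counts", {
  set.seed(14)
  nI <- 9; J <- 8
  Cd <- matrix(runif(nI * J, 0.05, 1), nI, J)
  y <- rpois(nI, 30)
  oracle <- mlem_hist_oracle(y, Cd, 6)
  img <- mlem_hist(y, Matrix::Matrix(Cd, sparse = TRUE), voxel_grid(2, 2), 6)
  expect_equal(as.vector(img$values), oracle, tolerance = 1e-12)
  expect_true(all(img$values >= 0))
  # count conservation after every iteration
  for (n in 1:4) {
    lam <- as.vector(mlem_hist(y, Matrix::Matrix(Cd, sparse = TRUE),
                               voxel_grid(2, 2), n)$values)
    expect_equal(sum(Cd %*% lam), sum(y), tolerance = 1e-9)
  }
})

test_that("mirrored histograms give the mirrored image", {
  setup <- acquisition_setup(n_cameras = 1, angles_deg = 0)
  grid <- voxel_grid(7, 3)
  C <- pinhole_system_matrix(setup, grid, 60)
  set.seed(15)
  y <- integer(nrow(C))
  nz_bins <- which(Matrix::rowSums(C) > 0)
  y[sample(nz_bins, 40)] <- rpois(40, 20) + 1
  # vertical mirror: iy -> 44 - iy leaves the camera geometry invariant
  idx <- expand.grid(ix = 0:44, iy = 0:44)
  bin <- hccimager:::.bin_index(setup, 0L, 0L, idx$ix, idx$iy)
  bin_m <- hccimager:::.bin_index(setup, 0L, 0L, idx$ix, 44L - idx$iy)
  ym <- integer(length(y)); ym[bin_m] <- y[bin]
  im <- mlem_hist(y, C, grid, 8)$values
  imm <- mlem_hist(ym, C, grid, 8)$values
  expect_equal(imm, im[, rev(seq_len(7)), ], tolerance = 1e-12)
})

test_that("a simulated low-energy point source is recovered at its position", {
  set.seed(16)
  setup <- acquisition_setup()
  src <- source_spec("am241", 3.93e6, c(-20, 0, -20))
  ph <- collect_mode_events(src, setup, "pinhole", "am241",
                            target_n = 6000, chunk_s = 2, max_chunks = 3)
  expect_gt(nrow(ph), 2000)
  grid <- voxel_grid(21, 2.3)
  C <- pinhole_system_matrix(setup, grid, 60)
  img <- mlem_hist(pinhole_histogram(ph, setup), C, grid, 20)
  pk <- find_peak(img)
  expect_true(all(abs(pk$position - c(-20, 0, -20)) <= 2.3 + 1e-9))
})
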