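test_that("peak finding reports position, ties and axis equivariance", {
  g <- voxel_grid(7, 2)
  v <- numeric(343); arr <- array(v, c(7, 7, 7))
  arr[3, 4, 5] <- 1
  img <- hcc_image(arr, g)
  pk <- find_peak(img)
  expect_equal(pk$index, c(3, 4, 5))
  expect_equal(pk$position, g$origin + (c(3, 4, 5) - 0.5) * 2)
  # tie broken by the lowest flattened index
  arr2 <- arr; arr2[6, 6, 6] <- 1
  expect_equal(find_peak(hcc_image(arr2, g))$index, c(3, 4, 5))
  expect_error(find_peak(hcc_image(array(0, c(7, 7, 7)), g)), "all-zero")
  # permuting the grid axes permutes the reported index
  arrp <- aperm(arr, c(3, 1, 2))
  expect_equal(find_peak(hcc_image(arrp, g))$index, c(5, 3, 4))
  # FWHM of a separable Gaussian blob
  vc <- voxel_centers(g)
  blob <- exp(-rowSums(vc^2) / (2 * 3^2))
  fw <- find_peak(hcc_image(blob, g))$fwhm_mm
  expect_equal(fw, rep(2.3548 * 3, 3), tolerance = 0.2)
})

test_that("ROI ratios behave symmetrically", {
  g <- voxel_grid(15, 2)
  ca <- c(-8, 0, 0); cb <- c(8, 0, 0)
  uni <- hcc_image(rep(1, prod(g$n)), g)
  expect_equal(roi_ratio(uni, ca, cb, radius = 5)$ratio, 1)
  # 2 delta_a + 1 delta_b -> ratio 2
  arr <- array(0, g$n)
  arr[3, 8, 8] <- 2   # voxel centered at (-10, 0, 0)... see below
  vox_a <- round((ca - g$origin) / g$pitch + 0.5)
  vox_b <- round((cb - g$origin) / g$pitch + 0.5)
  arr <- array(0, g$n)
  arr[vox_a[1], vox_a[2], vox_a[3]] <- 2
  arr[vox_b[1], vox_b[2], vox_b[3]] <- 1
  img <- hcc_image(arr, g)
  r <- roi_ratio(img, ca, cb, radius = 5)
  expect_equal(r$ratio, 2)
  # reciprocity is exact
  expect_equal(r$ratio * roi_ratio(img, cb, ca, radius = 5)$ratio, 1)
  expect_error(roi_ratio(uni, c(0, 0, 0), c(1, 0, 0), radius = 5), "overlap")
  expect_error(roi_ratio(uni, c(-14, 0, 0), cb, radius = 5), "outside")
})

test_that("multi-modal fusion normalizes channels on a shared grid", {
  g <- voxel_grid(5, 2)
  mk <- function(i, j, k, val) {
    a <- array(0, g$n); a[i, j, k] <- val; hcc_image(a, g)
  }
  one <- fuse_multimodal(list(mk(1, 1, 1, 7)))
  expect_equal(max(one$channels), 1)
  fu <- fuse_multimodal(list(mk(1, 1, 1, 7), mk(3, 3, 3, 2), mk(5, 5, 5, 9)),
                        tags = c("compton", "pet", "pinhole"))
  expect_equal(dim(fu$channels), c(5, 5, 5, 3))
  for (i in 1:3) {
    ch <- fu$channels[, , , i]
    expect_equal(max(ch), 1)
    expect_equal(sum(ch > 0), 1)
  }
  expect_error(fuse_multimodal(list()), "empty")
  expect_error(fuse_multimodal(list(mk(1, 1, 1, 1),
                                    hcc_image(rep(0, 27), voxel_grid(3, 2)))),
               "grid")
})

test_that("slice extraction partitions the image", {
  g <- voxel_grid(c(6, 10, 4), 2.3)
  set.seed(28)
  img <- hcc_image(runif(prod(g$n)), g)
  sl <- extract_slices(img, axis = 2)
  expect_length(sl, 10)
  expect_equal(sum(vapply(sl, sum, numeric(1))), sum(img$values))
  expect_true(all(diff(attr(sl, "coords")) > 0))
  sl2 <- extract_slices(img, axis = 2, pitch_mm = 4.6)
  expect_length(sl2, 5)
  expect_error(extract_slices(img, axis = 4), "axis")
  expect_error(extract_slices(img, axis = 2, pitch_mm = 3), "multiple")
  # 16-bit TIFF export round-trips the slice values to quantization
  d <- withr::local_tempdir()
  export_slices_tiff(img, d, axis = 3)
  files <- list.files(d, pattern = "tiff$", full.names = TRUE)
  expect_length(files, 4)
  meta <- jsonlite::read_json(file.path(d, "scale.json"))
  back <- tiff::readTIFF(files[1]) * meta$value_at_65535
  expect_equal(back, img$values[, , 1], tolerance = 1e-4)
})
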