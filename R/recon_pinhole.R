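# Hist-mode MLEM pinhole reconstruction.  Detector bins are per
# (acquisition angle, camera, rear pixel); all angles share one image.  The
# system matrix element is the solid angle subtended by the rear pixel at
# the voxel center (small-angle form; the 1 mm pixel is tiny compared with
# the ~190 mm distances, relative error < 1e-4) times the interaction
# probability in the 5 mm rear slab with a 1/cos(alpha) slant path,
# gated by the front-plane aperture test.

.n_bins <- function(setup) {
  npix <- setup$cameras[[1]]$rear$n_pix
  length(setup$angles_deg) * length(setup$cameras) * npix^2
}

.bin_index <- function(setup, angle_id, camera_id, ix, iy) {
  npix <- setup$cameras[[1]]$rear$n_pix
  ncam <- length(setup$cameras)
  (angle_id * ncam + camera_id) * npix^2 + iy * npix + ix + 1L
}

#' Pinhole system matrix
#'
#' Builds the sparse (detector bin x voxel) matrix
#' \eqn{c_{ij} = \Omega_{ij}\, p_{int}(E)} over every (angle, camera, rear
#' pixel) bin; `c_ij = 0` whenever the pixel-to-voxel ray misses the
#' front-plane aperture.
#'
#' @param setup a `hcc_setup`.
#' @param grid a `hcc_grid`.
#' @param energy_kev photon energy used for the interaction probability.
#' @return a `Matrix::sparseMatrix` of dimension (bins x voxels) with
#'   attribute `setup_dims`.
#' @export
pinhole_system_matrix <- function(setup, grid, energy_kev) {
  stopifnot(energy_kev > 0)
  poses <- build_multi_angle(setup)
  cams <- unlist(lapply(poses, function(a) a$cameras), recursive = FALSE)
  fc <- t(vapply(cams, function(g) g$center, numeric(3)))
  ex <- t(vapply(cams, function(g) g$ex, numeric(3)))
  ey <- t(vapply(cams, function(g) g$ey, numeric(3)))
  nn <- t(vapply(cams, function(g) g$n_out, numeric(3)))
  g1 <- setup$cameras[[1]]
  vox <- voxel_centers(grid)
  tri <- cpp_pinhole_cij(fc, ex, ey, nn, vox,
                         g1$rear$n_pix, g1$rear$pixel_pitch,
                         g1$front$hole_half_width, g1$plane_separation,
                         g1$rear$thickness / 10,
                         attenuation_mu(energy_kev, "gagg", "total"))
  M <- Matrix::sparseMatrix(i = tri$i, j = tri$j, x = tri$x,
                            dims = c(.n_bins(setup), nrow(vox)))
  attr(M, "setup_dims") <- c(n_angles = length(setup$angles_deg),
                             n_cameras = length(setup$cameras),
                             n_pix = g1$rear$n_pix)
  M
}

#' Histogram pinhole events into detector bins
#'
#' @param events data.frame from [extract_pinhole_events()].
#' @param setup the `hcc_setup` (defines the bin layout).
#' @return integer vector of counts, one per (angle, camera, rear pixel)
#'   bin in the same layout as [pinhole_system_matrix()].
#' @export
pinhole_histogram <- function(events, setup) {
  y <- integer(.n_bins(setup))
  if (nrow(events)) {
    idx <- .bin_index(setup, events$angle_id, events$camera_id,
                      events$ix, events$iy)
    tab <- table(idx)
    y[as.integer(names(tab))] <- as.integer(tab)
  }
  y
}

#' Hist-mode MLEM
#'
#' Multiplicative EM for binned counts:
#' \eqn{\lambda_j \leftarrow \lambda_j / (\sum_i c_{ij}) \sum_i c_{ij} y_i /
#' (\sum_{j'} c_{ij'} \lambda_{j'})} from a uniform positive start.  Voxels
#' whose system-matrix column is entirely zero (their rays miss every
#' aperture) are masked out of the support rather than floored.
#'
#' @param y counts per detector bin (see [pinhole_histogram()]).
#' @param C system matrix from [pinhole_system_matrix()] (bins x voxels).
#' @param grid the `hcc_grid` the matrix was built on.
#' @param n_iter number of iterations (>= 1).
#' @param lambda0 starting image (default uniform positive).
#' @param fov_radius_mm optional cylindrical field-of-view radius about the
#'   vertical axis; voxels outside are excluded from the support.  Useful
#'   for single-angle acquisitions, where weakly sampled grid corners can
#'   otherwise accumulate the diffuse septal-penetration background.
#' @return a `hcc_image`; all-zero input yields a zero image with a
#'   warning.
#' @export
mlem_hist <- function(y, C, grid, n_iter = 20, lambda0 = NULL,
                      fov_radius_mm = NULL) {
  stopifnot(n_iter >= 1, length(y) == nrow(C))
  J <- ncol(C)
  colsum <- Matrix::colSums(C)
  support <- colsum > 0
  if (!is.null(fov_radius_mm)) {
    vc <- voxel_centers(grid)
    support <- support & (vc[, 1]^2 + vc[, 3]^2 <= fov_radius_mm^2)
  }
  lambda <- numeric(J)
  if (sum(y) == 0) {
    warning("all-zero histogram: returning a zero image")
    return(hcc_image(lambda, grid, n_iter = 0L))
  }
  lambda[support] <- 1
  if (!is.null(lambda0)) {
    stopifnot(length(lambda0) == J, all(lambda0 >= 0))
    lambda <- as.numeric(lambda0) * (colsum > 0)
  }
  Cs <- C[, support, drop = FALSE]
  cs <- colsum[support]
  lam <- lambda[support]
  for (it in seq_len(n_iter)) {
    q <- as.vector(Cs %*% lam)
    ratio <- ifelse(q > 0, y / q, 0)
    lam <- lam / cs * as.vector(Matrix::crossprod(Cs, ratio))
  }
  lambda[support] <- lam
  hcc_image(lambda, grid, n_iter = n_iter)
}
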