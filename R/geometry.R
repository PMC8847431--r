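# Camera and acquisition geometry.
#
# World frame: right-handed, y is the vertical (rotation) axis, camera
# optical axes lie in the x-z plane.  A camera at azimuth phi (about +y,
# measured from +z) has its front entrance-face center at
# ring_radius * (sin phi, 0, cos phi) and looks toward the world origin.
# Multi-angle acquisition rotates the source by +theta, implemented as
# rotating the cameras by -theta about y.
#
# Pixel indexing is 0-based (ix, iy), ix along the in-plane ex axis, iy
# along ey (vertical for unrotated cameras), origin at the corner pixel.
# Voxel intervals are half-open; a point on a boundary belongs to the
# lower-index voxel.

#' Detector plane description
#'
#' @param role `"front"` or `"rear"`.
#' @param n_pix pixels per side (45 by default).
#' @param pixel_pitch pixel pitch in mm.
#' @param thickness slab thickness in mm (3 mm front, 5 mm rear).
#' @param hole_half_width half width in mm of the central square aperture
#'   (1.5 mm on the front plane, 0 on the rear).
#' @return a `hcc_plane` list.
#' @export
detector_plane <- function(role = c("front", "rear"), n_pix = 45,
                           pixel_pitch = 1,
                           thickness = if (match.arg(role) == "front") 3 else 5,
                           hole_half_width = if (match.arg(role) == "front") 1.5 else 0) {
  role <- match.arg(role)
  stopifnot(n_pix >= 1, pixel_pitch > 0, thickness > 0, hole_half_width >= 0)
  structure(list(role = role, n_pix = n_pix, pixel_pitch = pixel_pitch,
                 thickness = thickness, hole_half_width = hole_half_width),
            class = "hcc_plane")
}

#' Two-plane hybrid camera
#'
#' A camera is a front scatterer/pinhole-shield plane and a rear absorber
#' plane 40 mm behind it, both 45 x 45 pixels of 1 mm pitch.  The pose is
#' given by the front entrance-face center and an orthonormal frame
#' (`ex`, `ey`, `n_out`), with `n_out` pointing outward (away from the
#' imaged volume); the optical axis is `-n_out`.
#'
#' @param center front-face center, world mm (length-3).
#' @param ex,ey in-plane unit vectors.
#' @param front,rear [detector_plane()] descriptions.
#' @param plane_separation front-to-rear entrance-face distance in mm.
#' @return a `hcc_camera` list.
#' @export
camera_geometry <- function(center, ex, ey,
                            front = detector_plane("front"),
                            rear = detector_plane("rear"),
                            plane_separation = 40) {
  center <- as.numeric(center); ex <- as.numeric(ex); ey <- as.numeric(ey)
  stopifnot(length(center) == 3, length(ex) == 3, length(ey) == 3,
            plane_separation > 0)
  ex <- ex / sqrt(sum(ex^2)); ey <- ey / sqrt(sum(ey^2))
  n_out <- c(ex[2] * ey[3] - ex[3] * ey[2],
             ex[3] * ey[1] - ex[1] * ey[3],
             ex[1] * ey[2] - ex[2] * ey[1])
  structure(list(center = center, ex = ex, ey = ey, n_out = n_out,
                 front = front, rear = rear,
                 plane_separation = plane_separation),
            class = "hcc_camera")
}

#' Camera at a ring azimuth
#'
#' Places a default camera on the acquisition ring at azimuth `phi_deg`
#' about the vertical axis, facing the world origin.
#'
#' @param phi_deg azimuth in degrees (0 puts the camera on the +z axis).
#' @param ring_radius distance from origin to the front face in mm.
#' @param ... passed to [camera_geometry()].
#' @export
ring_camera <- function(phi_deg, ring_radius = 150, ...) {
  phi <- phi_deg * pi / 180
  center <- ring_radius * c(sin(phi), 0, cos(phi))
  ex <- c(cos(phi), 0, -sin(phi))
  ey <- c(0, 1, 0)
  camera_geometry(center, ex, ey, ...)
}

#' Multi-camera multi-angle acquisition setup
#'
#' The default is the 4-camera ring with opposite front faces 300 mm apart
#' and three source rotations of 30 degrees, i.e. 12 effective view angles.
#'
#' @param n_cameras number of cameras, equally spaced on the ring.
#' @param angles_deg source rotation angles in degrees, strictly increasing,
#'   each in `[0, 360)`.
#' @param ring_diameter distance between opposite front faces in mm.
#' @return a `hcc_setup` list with elements `cameras`, `angles_deg`,
#'   `ring_diameter`.
#' @export
acquisition_setup <- function(n_cameras = 4, angles_deg = c(0, 30, 60),
                              ring_diameter = 300) {
  stopifnot(n_cameras >= 1, length(angles_deg) >= 1, ring_diameter > 0)
  if (any(diff(angles_deg) <= 0) || any(angles_deg < 0 | angles_deg >= 360))
    stop("angles must be strictly increasing and in [0, 360)")
  cams <- lapply(seq_len(n_cameras) - 1L, function(i)
    ring_camera(360 / n_cameras * i, ring_radius = ring_diameter / 2))
  structure(list(cameras = cams, angles_deg = angles_deg,
                 ring_diameter = ring_diameter),
            class = "hcc_setup")
}

#' @export
print.hcc_setup <- function(x, ...) {
  cat(sprintf("Acquisition: %d cameras, %d rotations (%s deg) -> %d angles, ring %g mm\n",
              length(x$cameras), length(x$angles_deg),
              paste(x$angles_deg, collapse = ","),
              length(x$cameras) * length(x$angles_deg), x$ring_diameter))
  invisible(x)
}

.rot_y <- function(v, theta_deg) {
  th <- theta_deg * pi / 180
  c(cos(th) * v[1] + sin(th) * v[3], v[2],
    -sin(th) * v[1] + cos(th) * v[3])
}

#' Rotate a camera about the vertical axis
#'
#' @param camera a `hcc_camera`.
#' @param theta_deg rotation angle in degrees (right-handed about +y).
#' @export
rotate_camera <- function(camera, theta_deg) {
  camera$center <- .rot_y(camera$center, theta_deg)
  camera$ex <- .rot_y(camera$ex, theta_deg)
  camera$ey <- .rot_y(camera$ey, theta_deg)
  camera$n_out <- .rot_y(camera$n_out, theta_deg)
  camera
}

#' Expand a setup into per-angle camera poses
#'
#' Rotating the source by `+theta` is implemented as rotating every camera
#' by `-theta` about the vertical axis.  Angle ids enumerate the rotation
#' angles `0..(n_angles - 1)`.
#'
#' @param setup a `hcc_setup`.
#' @return list with one element per angle: `list(angle_id, cameras)`.
#' @export
build_multi_angle <- function(setup) {
  if (length(setup$angles_deg) == 0) stop("empty angle list")
  lapply(seq_along(setup$angles_deg), function(i) {
    list(angle_id = i - 1L,
         cameras = lapply(setup$cameras, rotate_camera,
                          theta_deg = -setup$angles_deg[i]))
  })
}

#' World position of a pixel center
#'
#' @param camera a `hcc_camera`.
#' @param plane `"front"` or `"rear"`.
#' @param ix,iy 0-based pixel indices (vectorized).
#' @return matrix with one row per pixel, world mm.
#' @export
pixel_center_world <- function(camera, plane = c("front", "rear"), ix, iy) {
  plane <- match.arg(plane)
  pl <- camera[[plane]]
  if (any(ix < 0 | ix >= pl$n_pix | iy < 0 | iy >= pl$n_pix))
    stop("pixel index out of range")
  u <- (ix - (pl$n_pix - 1) / 2) * pl$pixel_pitch
  v <- (iy - (pl$n_pix - 1) / 2) * pl$pixel_pitch
  base <- camera$center
  if (plane == "rear") base <- base + camera$plane_separation * camera$n_out
  t(base + outer(camera$ex, u) + outer(camera$ey, v))
}

#' Does a ray pass the front-plane aperture?
#'
#' Tests whether the segment `src -> dst` crosses the front entrance plane
#' inside the central square aperture.  The test is applied at the entrance
#' plane only; edge penetration through the 3 mm slab is not modeled.
#'
#' @param camera a `hcc_camera`.
#' @param src,dst world positions in mm (length-3 vectors or n x 3 matrices).
#' @return logical vector.
#' @export
ray_passes_hole <- function(camera, src, dst) {
  src <- matrix(src, ncol = 3); dst <- matrix(dst, ncol = 3)
  d <- dst - src
  denom <- d %*% camera$n_out
  if (any(abs(denom) < 1e-12)) stop("segment parallel to the front plane")
  tt <- as.vector(((matrix(camera$center, nrow(src), 3, byrow = TRUE) - src) %*%
                     camera$n_out) / denom)
  q <- src + d * tt
  rel <- q - matrix(camera$center, nrow(q), 3, byrow = TRUE)
  u <- as.vector(rel %*% camera$ex)
  v <- as.vector(rel %*% camera$ey)
  hw <- camera$front$hole_half_width
  abs(u) <= hw & abs(v) <= hw
}

# --- voxel grid -------------------------------------------------------------

#' Reconstruction voxel grid
#'
#' A regular grid of cubic voxels; by default centered on the world origin
#' with the 2.3 mm pitch used for reconstructed slices.  Voxel intervals are
#' half-open: a world point on a boundary belongs to the lower-index voxel.
#'
#' @param n voxel counts per axis (length 1 or 3).
#' @param pitch voxel pitch in mm.
#' @param origin lower corner of the grid in world mm; default centers the
#'   grid on the origin.
#' @return a `hcc_grid` list with fields `n`, `pitch`, `origin`.
#' @export
voxel_grid <- function(n = 31, pitch = 2.3, origin = NULL) {
  n <- as.integer(rep(n, length.out = 3))
  stopifnot(all(n >= 1), pitch > 0)
  if (is.null(origin)) origin <- -n * pitch / 2
  structure(list(n = n, pitch = pitch, origin = as.numeric(origin)),
            class = "hcc_grid")
}

#' @export
print.hcc_grid <- function(x, ...) {
  cat(sprintf("Voxel grid: %d x %d x %d, pitch %g mm, origin (%g, %g, %g) mm\n",
              x$n[1], x$n[2], x$n[3], x$pitch,
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Voxel centers of a grid
#'
#' Flattened ordering is column-major in (ix, iy, iz): ix varies fastest,
#' matching R's array layout for `array(lambda, grid$n)`.
#'
#' @param grid a `hcc_grid`.
#' @return `prod(n) x 3` matrix of world positions (mm).
#' @export
voxel_centers <- function(grid) {
  cx <- grid$origin[1] + (seq_len(grid$n[1]) - 0.5) * grid$pitch
  cy <- grid$origin[2] + (seq_len(grid$n[2]) - 0.5) * grid$pitch
  cz <- grid$origin[3] + (seq_len(grid$n[3]) - 0.5) * grid$pitch
  as.matrix(expand.grid(x = cx, y = cy, z = cz, KEEP.OUT.ATTRS = FALSE))
}

#' Half width of a voxel
#'
#' The cone system matrix's solid-angle term uses the voxel half size
#' `a = pitch / 2`.
#'
#' @param grid a `hcc_grid`.
#' @export
voxel_half_width <- function(grid) grid$pitch / 2

#' 3D image on a voxel grid
#'
#' @param values numeric vector or array of length `prod(grid$n)`.
#' @param grid a `hcc_grid`.
#' @param n_iter iteration count that produced the image (0 for back
#'   projection).
#' @return a `hcc_image` with the values stored as a 3D array.
#' @export
hcc_image <- function(values, grid, n_iter = 0L) {
  stopifnot(length(values) == prod(grid$n))
  structure(list(values = array(as.numeric(values), dim = grid$n),
                 grid = grid, n_iter = as.integer(n_iter)),
            class = "hcc_image")
}

#' @export
print.hcc_image <- function(x, ...) {
  cat(sprintf("3D image %d x %d x %d (pitch %g mm), %d iterations, max %.4g\n",
              x$grid$n[1], x$grid$n[2], x$grid$n[3], x$grid$pitch,
              x$n_iter, max(x$values)))
  invisible(x)
}
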