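# List-mode MLEM Compton reconstruction with the simplified cone system
# matrix
#   t_kj = 2*pi*(1 - d/sqrt(d^2 + a^2))
#          * exp(-((|Theta_j| - |theta_k|)/sigma)^2 / 2) / sin(theta_k)
# where d is the scatter-pixel-to-voxel distance, a the voxel half width,
# Theta_j the angle between the scatter axis (absorption -> scatter
# direction) and the voxel direction, and theta_k the energy-derived
# scattering angle.  The update is
#   lambda_j <- lambda_j * sum_k t_kj v_k /
#               (s_j^{l_k} * sum_j' t_kj' lambda_j'),
# with v_k = 1 for all events (kept as a hook for future event weighting).

#' Cone system-matrix element
#'
#' Literal scalar evaluation of the Compton cone kernel; the fast
#' reconstruction path evaluates the same expression in compiled code with
#' sparsification at `nsig` Gaussian widths.
#'
#' @param scatter_pos,absorb_pos world positions (mm) of the scatter and
#'   absorption pixels.
#' @param theta_k energy-derived scattering angle, radians, in (0, pi).
#' @param voxel_center world position (mm) of the voxel center.
#' @param a voxel half width in mm.
#' @param sigma Gaussian angular width in radians.
#' @return the system-matrix element t_kj.
#' @export
system_matrix_element <- function(scatter_pos, absorb_pos, theta_k,
                                  voxel_center, a, sigma) {
  stopifnot(a > 0, sigma > 0, theta_k > 0, theta_k < pi)
  axis <- scatter_pos - absorb_pos
  axis <- axis / sqrt(sum(axis^2))
  r <- voxel_center - scatter_pos
  d <- sqrt(sum(r^2))
  if (d == 0) {
    solid <- 2 * pi
    Theta <- theta_k
  } else {
    solid <- 2 * pi * (1 - d / sqrt(d^2 + a^2))
    Theta <- acos(min(1, max(-1, sum(r * axis) / d)))
  }
  solid * exp(-0.5 * ((abs(Theta) - abs(theta_k)) / sigma)^2) / sin(theta_k)
}

#' Sparse cone system matrix for a set of events
#'
#' Rows are events, columns voxels; elements outside the
#' `|Theta_j - theta_k| <= nsig * sigma` shell are dropped (they are
#' numerically negligible and their removal cuts cost roughly tenfold).
#'
#' @param events data.frame from [extract_compton_events()].
#' @param grid a `hcc_grid`.
#' @param sigma_deg Gaussian angular width in degrees (default 2.5).
#' @param nsig sparsification cut in Gaussian widths (default 3).
#' @return a `Matrix::sparseMatrix` (K x J).
#' @export
compton_system_matrix <- function(events, grid, sigma_deg = 2.5, nsig = 3) {
  vox <- voxel_centers(grid)
  sc <- as.matrix(events[, c("sx", "sy", "sz")])
  ab <- as.matrix(events[, c("ax", "ay", "az")])
  axis <- .unit_rows(sc - ab)
  tri <- cpp_cone_tkj(sc, axis, events$theta, vox,
                      voxel_half_width(grid), sigma_deg * pi / 180, nsig)
  Matrix::sparseMatrix(i = tri$i, j = tri$j, x = tri$x,
                       dims = c(nrow(events), nrow(vox)))
}

.box_smooth3 <- function(arr) {
  # one pass of a 3x3x3 box filter with edge replication
  d <- dim(arr)
  out <- array(0, d)
  wt <- array(0, d)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    xs <- pmin(pmax(seq_len(d[1]) + dx, 1), d[1])
    ys <- pmin(pmax(seq_len(d[2]) + dy, 1), d[2])
    zs <- pmin(pmax(seq_len(d[3]) + dz, 1), d[3])
    out <- out + arr[xs, ys, zs]
    wt <- wt + 1
  }
  out / wt
}

#' Monte Carlo sensitivity map
#'
#' Estimates the per-voxel, per-angle Compton detection probability
#' \eqn{s_j^l} by irradiating each angle's camera poses with a uniform
#' source of target-energy photons drawn from the grid volume, running the
#' full transport + selection chain, and normalizing by the effective
#' number of photons emitted per voxel.  Because the true map varies slowly
#' over the field of view while the per-voxel Monte Carlo counts are sparse,
#' the tally runs on a grid coarsened by `coarse_factor` along every axis
#' and is then smoothed: either (default) by fitting a log-quadratic
#' Poisson response surface to the tally, which pools every accepted event
#' into ten coefficients and tracks the smooth geometric variation of the
#' map, or by `smooth_passes` 3x3x3 box passes.  The smoothed map is
#' expanded back to the reconstruction grid and floored at 1\% of its
#' positive median (prevents division blow-up at the edge of the field of
#' view).
#'
#' @param setup a `hcc_setup`.
#' @param grid a `hcc_grid`.
#' @param target Compton energy-cut target (see [energy_cut()]).
#' @param n_photons aimed photons per acquisition angle.
#' @param seed RNG seed (optional).
#' @param blur logical, apply energy blur in the transport.
#' @param smoothing `"quadratic"` (Poisson response surface) or `"box"`.
#' @param smooth_passes number of 3x3x3 box-smoothing passes when
#'   `smoothing = "box"`.
#' @param coarse_factor tally-grid coarsening along each axis.
#' @return a `hcc_sensitivity` object: matrix `s` (voxels x angles), plus
#'   the grid and sampling metadata.
#' @export
sensitivity_mc <- function(setup, grid, target = "cs137", n_photons = 2e6,
                           seed = NULL, blur = TRUE,
                           smoothing = c("quadratic", "box"),
                           smooth_passes = 1, coarse_factor = 4) {
  smoothing <- match.arg(smoothing)
  if (prod(grid$n) == 0) stop("grid has zero voxels")
  if (!is.null(seed)) set.seed(seed)
  cut <- energy_cut(target)
  if (is.null(cut$front)) stop("sensitivity target must be a Compton row")
  e0 <- cut$target_kev
  blur_model <- if (blur) fit_resolution_model() else NULL
  poses <- build_multi_angle(setup)
  nc <- pmax(ceiling(grid$n / coarse_factor), 1L)   # coarse tally dims
  cpitch <- grid$n * grid$pitch / nc                # per-axis coarse pitch
  Jc <- prod(nc)
  L <- length(poses)
  s <- matrix(0, prod(grid$n), L)
  corners <- as.matrix(expand.grid(grid$origin[1] + c(0, grid$n[1] * grid$pitch),
                                   grid$origin[2] + c(0, grid$n[2] * grid$pitch),
                                   grid$origin[3] + c(0, grid$n[3] * grid$pitch)))
  # fine-voxel -> coarse-cell lookup
  fidx <- voxel_centers(grid)
  cmap <- 1L +
    pmin(floor((fidx[, 1] - grid$origin[1]) / cpitch[1]), nc[1] - 1L) +
    nc[1] * pmin(floor((fidx[, 2] - grid$origin[2]) / cpitch[2]), nc[2] - 1L) +
    nc[1] * nc[2] * pmin(floor((fidx[, 3] - grid$origin[3]) / cpitch[3]),
                         nc[3] - 1L)
  for (li in seq_len(L)) {
    cams <- poses[[li]]$cameras
    delta <- .aim_half_angle(corners, cams)
    frac <- length(cams) * (1 - cos(delta)) / 2
    acc <- numeric(Jc)
    emi <- numeric(Jc)
    for (i0 in seq(1, n_photons, by = 500000L)) {
      kk <- as.integer(min(500000L, n_photons - i0 + 1))
      pts <- cbind(grid$origin[1] + stats::runif(kk) * grid$n[1] * grid$pitch,
                   grid$origin[2] + stats::runif(kk) * grid$n[2] * grid$pitch,
                   grid$origin[3] + stats::runif(kk) * grid$n[3] * grid$pitch)
      vj <- 1L +
        pmin(floor((pts[, 1] - grid$origin[1]) / cpitch[1]), nc[1] - 1L) +
        nc[1] * pmin(floor((pts[, 2] - grid$origin[2]) / cpitch[2]), nc[2] - 1L) +
        nc[1] * nc[2] * pmin(floor((pts[, 3] - grid$origin[3]) / cpitch[3]),
                             nc[3] - 1L)
      emi <- emi + tabulate(vj, nbins = Jc)
      cam_aim <- sample.int(length(cams), kk, replace = TRUE)
      centers <- t(vapply(cams, function(g) g$center, numeric(3)))
      axis <- .unit_rows(centers[cam_aim, , drop = FALSE] - pts)
      dirs <- .cone_dirs(axis, delta)
      meta <- data.frame(photon = seq_len(kk), voxel = vj)
      h <- .transport_photons(pts, dirs, rep(e0, kk), meta, cams,
                              NULL, blur_model)
      if (nrow(h) == 0) next
      dt <- data.table::as.data.table(h)
      sm <- dt[, .(E_f = sum(energy_kev[plane == "front"]),
                   E_r = sum(energy_kev[plane == "rear"]),
                   nf = sum(plane == "front"), nr = sum(plane == "rear"),
                   voxel = voxel[1]),
               by = .(photon, camera_id)]
      ok <- sm$nf > 0 & sm$nr > 0 & apply_energy_cut(sm$E_f, sm$E_r, cut)
      if (any(ok))
        ok[ok] <- !is.na(compute_scatter_angle(sm$E_f[ok], sm$E_r[ok]))
      acc <- acc + tabulate(sm$voxel[ok], nbins = Jc)
    }
    if (smoothing == "quadratic" && sum(acc) >= 20) {
      # Poisson response surface: log s is quadratic in scaled coordinates
      half <- grid$n * grid$pitch / 2
      ctr <- grid$origin + half
      cc <- as.matrix(expand.grid(
        grid$origin[1] + (seq_len(nc[1]) - 0.5) * cpitch[1],
        grid$origin[2] + (seq_len(nc[2]) - 0.5) * cpitch[2],
        grid$origin[3] + (seq_len(nc[3]) - 0.5) * cpitch[3]))
      u <- sweep(sweep(cc, 2, ctr), 2, half, "/")
      df <- data.frame(acc = acc, u1 = u[, 1], u2 = u[, 2], u3 = u[, 3],
                       off = log(pmax(emi, 0.5) / frac))
      fit <- tryCatch(
        stats::glm(acc ~ u1 + u2 + u3 + I(u1^2) + I(u2^2) + I(u3^2) +
                     u1:u2 + u1:u3 + u2:u3 + offset(off),
                   family = stats::poisson, data = df),
        error = function(e) NULL)
      if (!is.null(fit)) {
        uf <- sweep(sweep(fidx, 2, ctr), 2, half, "/")
        nd <- data.frame(u1 = uf[, 1], u2 = uf[, 2], u3 = uf[, 3], off = 0)
        s[, li] <- exp(stats::predict(fit, nd, type = "link"))
      } else {
        s[, li] <- sum(acc) / (sum(emi) / frac)   # flat fallback
      }
    } else if (smoothing == "quadratic") {
      s[, li] <- sum(acc) / max(sum(emi) / frac, 1)  # too few events: flat
    } else {
      raw <- array(ifelse(emi > 0, acc / (emi / frac), 0), nc)
      for (sp in seq_len(smooth_passes)) raw <- .box_smooth3(raw)
      s[, li] <- as.vector(raw)[cmap]
    }
  }
  med <- stats::median(s[s > 0])
  if (!is.finite(med) || med <= 0) med <- 1
  s[s < 0.01 * med] <- 0.01 * med
  structure(list(s = s, grid = grid, n_photons = n_photons,
                 target = if (is.list(target)) "custom" else target),
            class = "hcc_sensitivity")
}

#' List-mode MLEM reconstruction of Compton events
#'
#' Runs the multiplicative EM update for `n_iter` iterations from a uniform
#' positive start (`lambda0 = 1`), with the cone system matrix sparsified
#' at `nsig` Gaussian widths and the per-angle sensitivity applied inside
#' the event sum.  Events whose system-matrix row is entirely zero are
#' dropped with a warning.  Nonnegativity of the image is preserved by
#' construction.
#'
#' @param events data.frame from [extract_compton_events()].
#' @param grid a `hcc_grid`.
#' @param sens a `hcc_sensitivity`, a voxels x angles matrix, or `NULL` for
#'   a uniform sensitivity.
#' @param sigma_deg Gaussian angular width in degrees (default 2.5).
#' @param n_iter number of iterations (>= 1); 20 is used for tri-modal
#'   point-source work, 10 for distributed-source runs.
#' @param nsig sparsification cut (default 3).
#' @return a `hcc_image` with attributes `loglik` (per-iteration
#'   log-likelihood trace) and `n_dropped`.
#' @export
mlem_listmode <- function(events, grid, sens = NULL, sigma_deg = 2.5,
                          n_iter = 20, nsig = 3) {
  stopifnot(n_iter >= 1)
  if (nrow(events) == 0) stop("no events to reconstruct")
  J <- prod(grid$n)
  L <- max(events$angle_id) + 1L
  if (is.null(sens)) {
    smat <- matrix(1, J, L)
  } else if (inherits(sens, "hcc_sensitivity")) {
    smat <- sens$s
  } else {
    smat <- as.matrix(sens)
  }
  if (nrow(smat) != J) stop("sensitivity voxel count mismatch")
  if (ncol(smat) < L) stop("event angle without a sensitivity layer")
  vox <- voxel_centers(grid)
  sc <- as.matrix(events[, c("sx", "sy", "sz")])
  ab <- as.matrix(events[, c("ax", "ay", "az")])
  axis <- .unit_rows(sc - ab)
  res <- cpp_compton_mlem(sc, axis, events$theta,
                          as.integer(events$angle_id), vox,
                          voxel_half_width(grid), sigma_deg * pi / 180,
                          smat, as.integer(n_iter), nsig)
  n_drop <- sum(!res$kept)
  if (n_drop > 0)
    warning(n_drop, " event(s) with an all-zero system-matrix row dropped")
  img <- hcc_image(res$lambda, grid, n_iter = n_iter)
  attr(img, "loglik") <- res$loglik
  attr(img, "n_dropped") <- n_drop
  img
}
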