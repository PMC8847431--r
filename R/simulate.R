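# Monte Carlo list-mode event generator for the hybrid-Compton-camera ring.
#
# Transport model (per photon): optional water-slab traversal with
# narrow-beam survival exp(-mu(E) d); photons entering a camera front face
# either pass the central aperture (no front interaction), interact in the
# 3 mm front slab (photoelectric full stop or Compton scatter with
# Klein-Nishina kinematics), or transmit; whatever reaches the rear plane is
# absorbed there with its own interaction probability (full energy deposit).
# Interaction positions are pixel centers (no depth of interaction); the
# tungsten case is a perfect absorber for photons missing the front face.
#
# Directions are drawn by solid-angle importance sampling: photons are aimed
# into cones that cover the camera front faces and the effective emitted
# count is corrected by the sampled cone fraction.  This is an unbiased
# variance reduction because photons outside those cones can never reach a
# detector.

#' Radioactive source specification
#'
#' @param nuclide nuclide name (see [nuclide_lines()]), or any label when
#'   `lines` is supplied.
#' @param activity_bq activity in Bq.
#' @param position world position in mm.
#' @param radius source extent: 0 for a point source, otherwise the radius
#'   in mm of a uniform sphere.
#' @param lines optional custom emission table (data.frame with `energy`,
#'   `intensity`, `kind`) overriding the embedded nuclide table, e.g. for
#'   monoenergetic test sources.
#' @export
source_spec <- function(nuclide, activity_bq, position = c(0, 0, 0),
                        radius = 0, lines = NULL) {
  stopifnot(activity_bq > 0, radius >= 0, length(position) == 3)
  if (is.null(lines)) lines <- nuclide_lines(nuclide)
  stopifnot(all(c("energy", "intensity", "kind") %in% names(lines)))
  structure(list(nuclide = tolower(nuclide), activity_bq = activity_bq,
                 position = as.numeric(position), radius = radius,
                 lines = lines),
            class = "hcc_source")
}

#' Water (or other material) slab between source and a camera
#'
#' The slab is normal to the camera's optical axis and intercepts every
#' photon heading into that camera's front face; traversal length scales
#' with 1/cos of the incidence angle.  Scattered photons are removed from
#' the beam (narrow-beam model).
#'
#' @param thickness_cm slab thickness in cm.
#' @param camera_id 0-based id of the camera the slab faces.
#' @param material attenuation-table material (default `"water"`).
#' @export
phantom_slab <- function(thickness_cm, camera_id = 0L, material = "water") {
  stopifnot(thickness_cm >= 0)
  structure(list(thickness_cm = thickness_cm, camera_id = as.integer(camera_id),
                 material = material), class = "hcc_slab")
}

#' Klein-Nishina differential cross section (relative)
#'
#' Unnormalized Klein-Nishina differential cross section per unit solid
#' angle for incident energy `energy_kev` at scattering-angle cosine
#' `cos_theta`.
#'
#' @param energy_kev incident photon energy in keV.
#' @param cos_theta cosine of the scattering angle (vectorized).
#' @export
klein_nishina_dcs <- function(energy_kev, cos_theta) {
  alpha <- energy_kev / .electron_mass_kev
  r <- 1 / (1 + alpha * (1 - cos_theta))   # E'/E
  r^2 * (r + 1 / r - (1 - cos_theta^2))
}

#' Sample Compton scattering angles from the Klein-Nishina distribution
#'
#' Rejection sampling of the scattering-angle cosine from the Klein-Nishina
#' differential cross section, with the scattered energy from the Compton
#' relation \eqn{E' = E / (1 + (E/511)(1 - \cos\theta))}.
#'
#' @param energy_kev incident energies in keV (vectorized; one sample per
#'   element).
#' @return list with `theta` (radians) and `energy_out` (keV).
#' @export
sample_klein_nishina <- function(energy_kev) {
  n <- length(energy_kev)
  cth <- rep(NA_real_, n)
  todo <- seq_len(n)
  # envelope: uniform in cos(theta); the KN maximum is at forward scatter
  fmax <- klein_nishina_dcs(energy_kev, 1)
  while (length(todo)) {
    cand <- stats::runif(length(todo), -1, 1)
    acc <- stats::runif(length(todo)) * fmax[todo] <
      klein_nishina_dcs(energy_kev[todo], cand)
    cth[todo[acc]] <- cand[acc]
    todo <- todo[!acc]
  }
  e_out <- energy_kev / (1 + energy_kev / .electron_mass_kev * (1 - cth))
  list(theta = acos(cth), energy_out = e_out)
}

.cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

.unit_rows <- function(m) m / sqrt(rowSums(m^2))

# rotate unit rows `dir` by polar angle theta (radians), uniform azimuth
.scatter_direction <- function(dir, theta) {
  n <- nrow(dir)
  h <- matrix(rep(c(1, 0, 0), each = n), n, 3)
  swap <- abs(dir[, 1]) > 0.9
  h[swap, ] <- matrix(rep(c(0, 1, 0), each = sum(swap)), ncol = 3)
  e1 <- .unit_rows(.cross3(dir, h))
  e2 <- .cross3(dir, e1)
  phi <- stats::runif(n, 0, 2 * pi)
  cos(theta) * dir + sin(theta) * (cos(phi) * e1 + sin(phi) * e2)
}

# Transport photons already assigned directions.  `meta` is a data.frame of
# per-photon payload (time_ns, origin indices, ...) carried onto the hits.
.transport_photons <- function(pos, dir, energy, meta, cameras,
                               slabs = NULL, blur_model = NULL,
                               threshold_kev = 1) {
  empty <- data.frame(camera_id = integer(0), plane = character(0),
                      ix = integer(0), iy = integer(0),
                      energy_kev = numeric(0))
  if (nrow(pos) == 0)
    return(cbind(meta[0, , drop = FALSE], empty))
  C <- length(cameras)
  N <- nrow(pos)
  front <- cameras[[1]]$front
  rear <- cameras[[1]]$rear
  hw_face <- front$n_pix * front$pixel_pitch / 2
  hole_hw <- front$hole_half_width
  sep <- cameras[[1]]$plane_separation
  cam <- integer(N)
  uu <- vv <- cosA <- rep(NA_real_, N)
  for (cc in seq_len(C)) {
    g <- cameras[[cc]]
    dn <- as.vector(dir %*% g$n_out)
    tnum <- sum(g$center * g$n_out) - as.vector(pos %*% g$n_out)
    tt <- tnum / dn
    q <- pos + dir * tt
    u <- as.vector(q %*% g$ex) - sum(g$center * g$ex)
    v <- as.vector(q %*% g$ey) - sum(g$center * g$ey)
    hit <- !is.na(tt) & dn > 1e-9 & tt > 1e-6 &
      abs(u) <= hw_face & abs(v) <= hw_face & cam == 0L
    cam[hit] <- cc
    uu[hit] <- u[hit]; vv[hit] <- v[hit]; cosA[hit] <- dn[hit]
  }
  sel <- cam > 0L
  if (!any(sel)) return(cbind(meta[0, , drop = FALSE], empty))
  pos <- pos[sel, , drop = FALSE]; dir <- dir[sel, , drop = FALSE]
  energy <- energy[sel]; meta <- meta[sel, , drop = FALSE]
  cam <- cam[sel]; uu <- uu[sel]; vv <- vv[sel]; cosA <- cosA[sel]
  N <- length(energy)

  # water slab (narrow beam): survival along the slant path
  if (length(slabs)) {
    alive <- rep(TRUE, N)
    for (sl in slabs) {
      if (sl$thickness_cm <= 0) next
      on_cam <- cam == sl$camera_id + 1L
      if (!any(on_cam)) next
      mu <- attenuation_mu(energy[on_cam], sl$material, "total")
      p <- exp(-mu * sl$thickness_cm / cosA[on_cam])
      alive[on_cam] <- alive[on_cam] & stats::runif(sum(on_cam)) < p
    }
    if (!all(alive)) {
      pos <- pos[alive, , drop = FALSE]; dir <- dir[alive, , drop = FALSE]
      energy <- energy[alive]; meta <- meta[alive, , drop = FALSE]
      cam <- cam[alive]; uu <- uu[alive]; vv <- vv[alive]; cosA <- cosA[alive]
      N <- length(energy)
    }
  }
  if (N == 0) return(cbind(meta[0, , drop = FALSE], empty))

  half <- (front$n_pix - 1) / 2
  pix_of <- function(u) pmin(pmax(floor(u / front$pixel_pitch + front$n_pix / 2),
                                  0), front$n_pix - 1L)
  in_hole <- abs(uu) <= hole_hw & abs(vv) <= hole_hw
  mu_front <- attenuation_mu(energy, "gagg", "total")
  p_front <- 1 - exp(-mu_front * (front$thickness / 10) / cosA)
  interact_f <- !in_hole & stats::runif(N) < p_front
  is_pe <- stats::runif(N) < photoelectric_fraction(energy, "gagg")
  pe_f <- interact_f & is_pe
  co_f <- interact_f & !is_pe

  hits <- vector("list", 4)
  # photoelectric stop in the front slab
  if (any(pe_f)) {
    hits[[1]] <- cbind(meta[pe_f, , drop = FALSE],
                       data.frame(camera_id = cam[pe_f] - 1L, plane = "front",
                                  ix = as.integer(pix_of(uu[pe_f])),
                                  iy = as.integer(pix_of(vv[pe_f])),
                                  energy_kev = energy[pe_f]))
  }
  # Compton scatter in the front slab: recoil deposit + scattered photon
  if (any(co_f)) {
    kn <- sample_klein_nishina(energy[co_f])
    e_sc <- kn$energy_out
    hits[[2]] <- cbind(meta[co_f, , drop = FALSE],
                       data.frame(camera_id = cam[co_f] - 1L, plane = "front",
                                  ix = as.integer(pix_of(uu[co_f])),
                                  iy = as.integer(pix_of(vv[co_f])),
                                  energy_kev = energy[co_f] - e_sc))
  }
  # rear-plane stage: pass-through photons keep (u, v, dir); scattered
  # photons restart from the front pixel center with the new direction
  ru <- rv <- re <- rc <- numeric(0)
  rmeta <- meta[0, , drop = FALSE]
  rdir <- matrix(numeric(0), 0, 3)
  thru <- !interact_f  # includes the aperture passers
  if (any(thru)) {
    ru <- uu[thru]; rv <- vv[thru]; re <- energy[thru]; rc <- cam[thru]
    rdir <- dir[thru, , drop = FALSE]
    rmeta <- meta[thru, , drop = FALSE]
  }
  if (any(co_f)) {
    d2 <- .scatter_direction(dir[co_f, , drop = FALSE], kn$theta)
    ru <- c(ru, (pix_of(uu[co_f]) - half) * front$pixel_pitch)
    rv <- c(rv, (pix_of(vv[co_f]) - half) * front$pixel_pitch)
    re <- c(re, e_sc); rc <- c(rc, cam[co_f])
    rdir <- rbind(rdir, d2)
    rmeta <- rbind(rmeta, meta[co_f, , drop = FALSE])
  }
  if (length(re)) {
    n2 <- length(re)
    u2 <- v2 <- dn2 <- rep(NA_real_, n2)
    for (cc in seq_len(C)) {
      g <- cameras[[cc]]
      idx <- which(rc == cc)
      if (!length(idx)) next
      dn <- as.vector(rdir[idx, , drop = FALSE] %*% g$n_out)
      fwd <- dn > 1e-9
      t2 <- ifelse(fwd, sep / dn, NA_real_)
      u2[idx] <- ru[idx] + t2 * as.vector(rdir[idx, , drop = FALSE] %*% g$ex)
      v2[idx] <- rv[idx] + t2 * as.vector(rdir[idx, , drop = FALSE] %*% g$ey)
      dn2[idx] <- dn
    }
    ok <- !is.na(u2) & abs(u2) <= hw_face & abs(v2) <= hw_face
    if (any(ok)) {
      mu_r <- attenuation_mu(re[ok], "gagg", "total")
      p_r <- 1 - exp(-mu_r * (rear$thickness / 10) / dn2[ok])
      absb <- stats::runif(sum(ok)) < p_r
      if (any(absb)) {
        iok <- which(ok)[absb]
        hits[[3]] <- cbind(rmeta[iok, , drop = FALSE],
                           data.frame(camera_id = rc[iok] - 1L, plane = "rear",
                                      ix = as.integer(pix_of(u2[iok])),
                                      iy = as.integer(pix_of(v2[iok])),
                                      energy_kev = re[iok]))
      }
    }
  }
  out <- data.table::rbindlist(hits[!vapply(hits, is.null, logical(1))])
  out <- as.data.frame(out)
  if (nrow(out) == 0) return(cbind(meta[0, , drop = FALSE], empty))
  if (!is.null(blur_model))
    out$energy_kev <- blur_energy(out$energy_kev, blur_model)
  out[out$energy_kev >= threshold_kev, , drop = FALSE]
}

# cone-fraction helper: half-angle covering every front face from `points`
.aim_half_angle <- function(points, cameras, margin_mm = 1.5) {
  centers <- t(vapply(cameras, function(g) g$center, numeric(3)))
  half_diag <- cameras[[1]]$front$n_pix * cameras[[1]]$front$pixel_pitch /
    2 * sqrt(2)
  dmin <- Inf
  for (cc in seq_len(nrow(centers))) {
    d <- sqrt(rowSums((points - matrix(centers[cc, ], nrow(points), 3,
                                       byrow = TRUE))^2))
    dmin <- min(dmin, d)
  }
  atan((half_diag + margin_mm) / dmin)
}

# sample directions uniformly inside the cone of half-angle delta around
# each row of `axis`
.cone_dirs <- function(axis, delta) {
  n <- nrow(axis)
  cth <- 1 - stats::runif(n) * (1 - cos(delta))
  sth <- sqrt(pmax(1 - cth^2, 0))
  phi <- stats::runif(n, 0, 2 * pi)
  h <- matrix(rep(c(1, 0, 0), each = n), n, 3)
  swap <- abs(axis[, 1]) > 0.9
  h[swap, ] <- matrix(rep(c(0, 1, 0), each = sum(swap)), ncol = 3)
  e1 <- .unit_rows(.cross3(axis, h))
  e2 <- .cross3(axis, e1)
  cth * axis + sth * (cos(phi) * e1 + sin(phi) * e2)
}

.sample_sphere_points <- function(n, center, radius) {
  if (radius <= 0)
    return(matrix(center, n, 3, byrow = TRUE))
  m <- matrix(stats::rnorm(3 * n), n, 3)
  r <- radius * stats::runif(n)^(1 / 3)
  .unit_rows(m) * r + matrix(center, n, 3, byrow = TRUE)
}

#' Simulate a multi-angle list-mode acquisition
#'
#' Generates blurred list-mode hits for the given sources, camera setup and
#' optional water slabs.  Decays form a Poisson process at the summed
#' activity; emission lines are sampled by intensity, annihilation pairs are
#' emitted back to back, and photons are transported through the two-plane
#' camera model.  Directional importance sampling aims photons into cones
#' covering the camera front faces; the `emitted` attribute records the
#' effective number of photons emitted into the full sphere per line, so
#' absolute efficiencies remain unbiased.
#'
#' @param sources list of [source_spec()] objects (or a single one).
#' @param setup an `hcc_setup`.
#' @param phantoms list of [phantom_slab()] objects (or `NULL`).
#' @param duration_s acquisition duration per angle, seconds.
#' @param seed RNG seed (optional).
#' @param blur logical: apply the Gaussian energy resolution model.
#' @param bias logical: use the cone importance sampling (disable for fully
#'   isotropic emission, e.g. asymmetric single-camera PET studies).
#' @param threshold_kev readout threshold; deposits below it are dropped.
#' @return data.frame of hits (`angle_id`, `time_ns`, `camera_id`, `plane`,
#'   `ix`, `iy`, `energy_kev`), time-sorted within each angle, with
#'   attribute `emitted` (per-line effective emitted photon counts).
#' @export
simulate_acquisition <- function(sources, setup, phantoms = NULL,
                                 duration_s = 60, seed = NULL,
                                 blur = TRUE, bias = TRUE,
                                 threshold_kev = 1) {
  if (inherits(sources, "hcc_source")) sources <- list(sources)
  if (inherits(phantoms, "hcc_slab")) phantoms <- list(phantoms)
  stopifnot(duration_s > 0)
  if (length(setup$cameras) == 0) stop("setup has no cameras")
  if (!is.null(seed)) set.seed(seed)
  blur_model <- if (blur) fit_resolution_model() else NULL
  poses <- build_multi_angle(setup)
  emitted <- list()
  chunks <- list()
  for (ang in poses) {
    cams <- ang$cameras
    for (src in sources) {
      delta <- .aim_half_angle(matrix(src$position, 1, 3), cams) +
        atan(src$radius / 100)
      frac <- length(cams) * (1 - cos(delta)) / 2
      if (!bias) frac <- 1
      n_decays <- src$activity_bq * duration_s
      for (li in seq_len(nrow(src$lines))) {
        line <- src$lines[li, ]
        n_emit <- n_decays * line$intensity *
          (if (line$kind == "pair") 2 else 1)
        emitted[[length(emitted) + 1L]] <-
          data.frame(nuclide = src$nuclide, energy_kev = line$energy,
                     kind = line$kind, n_emitted = n_emit)
        k <- stats::rpois(1, n_decays * line$intensity * frac)
        if (k == 0) next
        # decay ids: without replacement within a line (a decay emits one
        # photon per line) but shared across lines, so cascade photons of
        # the same decay collide and share a timestamp
        ids_all <- if (n_decays < 2^31 - 1)
          sample.int(as.integer(ceiling(n_decays)), k)
        else ceiling(stats::runif(k) * n_decays)
        for (i0 in seq(1, k, by = 500000L)) {
          kk <- min(500000L, k - i0 + 1L)
          pts <- .sample_sphere_points(kk, src$position, src$radius)
          did <- ids_all[i0:(i0 + kk - 1L)]
          tns <- .decay_time_ns(did, duration_s)
          if (bias) {
            cam_aim <- sample.int(length(cams), kk, replace = TRUE)
            centers <- t(vapply(cams, function(g) g$center, numeric(3)))
            axis <- .unit_rows(centers[cam_aim, , drop = FALSE] - pts)
            dirs <- .cone_dirs(axis, delta)
          } else {
            dirs <- .unit_rows(matrix(stats::rnorm(3 * kk), kk, 3))
          }
          if (line$kind == "pair") {
            pts <- rbind(pts, pts)
            dirs <- rbind(dirs, -dirs)
            tns <- c(tns, tns)
          }
          meta <- data.frame(angle_id = ang$angle_id, time_ns = tns)
          h <- .transport_photons(pts, dirs, rep(line$energy, nrow(pts)),
                                  meta, cams, phantoms, blur_model,
                                  threshold_kev)
          if (nrow(h)) chunks[[length(chunks) + 1L]] <- h
        }
      }
    }
  }
  hits <- if (length(chunks)) as.data.frame(data.table::rbindlist(chunks))
          else data.frame(angle_id = integer(0), time_ns = numeric(0),
                          camera_id = integer(0), plane = character(0),
                          ix = integer(0), iy = integer(0),
                          energy_kev = numeric(0))
  hits <- hits[order(hits$angle_id, hits$time_ns), , drop = FALSE]
  rownames(hits) <- NULL
  em <- as.data.frame(data.table::rbindlist(emitted))
  em <- stats::aggregate(n_emitted ~ nuclide + energy_kev + kind, em, sum)
  attr(hits, "emitted") <- em
  attr(hits, "setup") <- setup
  hits
}

# deterministic per-decay time: hash the decay index into a uniform time so
# photons of the same decay (cascades, annihilation pairs) share a
# timestamp.  A multiplicative Weyl hash gives a uniform, collision-free
# mapping without materializing one value per decay.
.decay_time_ns <- function(decay_id, duration_s) {
  frac <- (decay_id * 0.6180339887498949) %% 1
  frac * duration_s * 1e9
}

#' Absolute detection efficiency of a mode
#'
#' Fraction of selected events with respect to the photons emitted at the
#' target energy, as recorded in the `emitted` attribute of a simulation.
#'
#' @param n_selected number of events surviving classification + energy cut.
#' @param hits the simulation output (for its `emitted` attribute), or a
#'   number of emitted photons.
#' @param target_kev the target emission energy in keV (matched against the
#'   emission table within 1 keV).
#' @export
absolute_efficiency <- function(n_selected, hits, target_kev = NULL) {
  if (is.numeric(hits)) return(n_selected / hits)
  em <- attr(hits, "emitted")
  if (is.null(em)) stop("hits carry no emitted-count attribute")
  if (!is.null(target_kev))
    em <- em[abs(em$energy_kev - target_kev) < 1, , drop = FALSE]
  if (nrow(em) == 0) stop("no emission line matches the target energy")
  n_selected / sum(em$n_emitted)
}
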