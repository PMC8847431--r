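# Shared fixtures for the test suite.  Everything is generated in code.

# the default 4-camera ring with a single view angle
single_angle_setup <- function(n_cameras = 4) {
  acquisition_setup(n_cameras = n_cameras, angles_deg = 0)
}

# a camera whose front slab is thick enough to suppress septal penetration,
# so only aperture-passing photons reach the rear plane
shielded_setup <- function(n_cameras = 4, angles_deg = 0, hole_hw = 1.5) {
  su <- acquisition_setup(n_cameras = n_cameras, angles_deg = angles_deg)
  su$cameras <- lapply(su$cameras, function(g) {
    g$front$thickness <- 30
    g$front$hole_half_width <- hole_hw
    g
  })
  su
}

# monoenergetic test source
mono_source <- function(energy_kev, activity_bq = 1e5,
                        position = c(0, 0, 0)) {
  source_spec("custom", activity_bq, position,
              lines = data.frame(energy = energy_kev, intensity = 1,
                                 kind = "gamma"))
}

# literal dense transcription of the list-mode MLEM update (Eq. form:
# lambda_j <- lambda_j * sum_k t_kj / (s_j^{l_k} sum_j' t_kj' lambda_j'))
mlem_listmode_oracle <- function(sc, ab, theta, angle, vox, a, sigma, sens,
                                 n_iter) {
  K <- nrow(sc); J <- nrow(vox)
  tmat <- matrix(0, K, J)
  for (k in seq_len(K)) for (j in seq_len(J))
    tmat[k, j] <- system_matrix_element(sc[k, ], ab[k, ], theta[k],
                                        vox[j, ], a, sigma)
  lambda <- rep(1, J)
  for (n in seq_len(n_iter)) {
    newl <- numeric(J)
    for (j in seq_len(J)) {
      acc <- 0
      for (k in seq_len(K)) {
        denom <- sum(tmat[k, ] * lambda)
        acc <- acc + tmat[k, j] / (sens[j, angle[k] + 1] * denom)
      }
      newl[j] <- lambda[j] * acc
    }
    lambda <- newl
  }
  lambda
}

# literal dense transcription of the hist-mode MLEM update
mlem_hist_oracle <- function(y, C, n_iter) {
  J <- ncol(C)
  lambda <- rep(1, J)
  for (n in seq_len(n_iter)) {
    newl <- numeric(J)
    for (j in seq_len(J)) {
      acc <- 0
      for (i in seq_along(y)) {
        denom <- sum(C[i, ] * lambda)
        acc <- acc + C[i, j] * y[i] / denom
      }
      newl[j] <- lambda[j] / sum(C[, j]) * acc
    }
    lambda <- newl
  }
  lambda
}

# events of a noiseless point source: pick scatter/absorb pixels on the
# default ring cameras and derive theta from the exact geometry
synthetic_compton_events <- function(setup, src_pos, n_per_angle = 50,
                                     seed = 1) {
  set.seed(seed)
  poses <- build_multi_angle(setup)
  out <- list()
  for (ang in poses) {
    for (rep in seq_len(n_per_angle)) {
      cam <- ang$cameras[[sample.int(length(ang$cameras), 1)]]
      fx <- sample(10:34, 1); fy <- sample(10:34, 1)
      rxp <- sample(10:34, 1); ryp <- sample(10:34, 1)
      sp <- pixel_center_world(cam, "front", fx, fy)[1, ]
      ap <- pixel_center_world(cam, "rear", rxp, ryp)[1, ]
      axis <- (sp - ap) / sqrt(sum((sp - ap)^2))
      v <- src_pos - sp
      theta <- acos(sum(v * axis) / sqrt(sum(v^2)))
      if (theta < 0.05 || theta > pi - 0.05) next
      out[[length(out) + 1L]] <-
        data.frame(sx = sp[1], sy = sp[2], sz = sp[3],
                   ax = ap[1], ay = ap[2], az = ap[3],
                   E_f = NA_real_, E_r = NA_real_, theta = theta,
                   angle_id = ang$angle_id)
    }
  }
  do.call(rbind, out)
}
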