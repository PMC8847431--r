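# List-mode data model: coincidence grouping, hit-pattern classification,
# per-nuclide energy windows and Compton kinematics.
#
# Hits are rows of a data.frame with columns
#   time_ns, camera_id (0-based), plane ("front"/"rear"), ix, iy, energy_kev
# and, for multi-angle acquisitions, angle_id.

.electron_mass_kev <- 511.0

# Per-target energy windows (keV).  Compton rows apply both the front-deposit
# window (eliminating back-scattering events) and the total-energy window;
# pinhole rows window the rear deposit; the PET row windows the per-camera
# total deposit.
.energy_cuts <- list(
  cs137    = list(mode = "compton", target_kev = 662, front = c(20, 80),
                  total = c(607, 717)),
  am241    = list(mode = "pinhole", target_kev = 60, rear = c(47, 73)),
  na22     = list(mode = "pet", target_kev = 511, percam = c(471, 551)),
  ga67_93  = list(mode = "pinhole", target_kev = 93, rear = c(75, 111)),
  ga67_300 = list(mode = "compton", target_kev = 300, front = c(20, 80),
                  total = c(273, 327)),
  in111    = list(mode = "compton", target_kev = 245, front = c(20, 80),
                  total = c(220, 270)),
  at211    = list(mode = "pinhole", target_kev = 79, rear = c(69, 89))
)

#' Energy-cut definition for a reconstruction target
#'
#' Returns the embedded per-nuclide energy windows: Compton targets carry a
#' front-deposit window plus a total-energy window, pinhole targets a
#' rear-deposit window, and the PET target a per-camera total window.
#'
#' @param target one of `"cs137"`, `"am241"`, `"na22"`, `"ga67_93"`,
#'   `"ga67_300"`, `"in111"`, `"at211"`, or a list with the same structure
#'   for user-supplied windows.
#' @return list with elements `mode`, `target_kev` and the window(s).
#' @export
energy_cut <- function(target) {
  if (is.list(target)) return(target)
  target <- tolower(target)
  if (!target %in% names(.energy_cuts))
    stop("unknown energy-cut target: ", target,
         " (supply explicit windows as a list)")
  .energy_cuts[[target]]
}

#' Group time-sorted hits into coincidence events
#'
#' Greedy grouping: an event opens at the first unassigned hit and absorbs
#' all hits within `window_ns` of that opener (the window is anchored at the
#' opener, not at the last hit).  When an `angle_id` column is present,
#' grouping is performed within each angle and event ids are unique across
#' angles.
#'
#' @param hits data.frame of hits, time-sorted within each angle.
#' @param window_ns coincidence window in ns (default 100).
#' @return the hits with an `event_id` column appended.
#' @export
group_coincidences <- function(hits, window_ns = 100) {
  stopifnot(window_ns > 0)
  if (nrow(hits) == 0) {
    hits$event_id <- integer(0)
    return(hits)
  }
  if (!"angle_id" %in% names(hits)) hits$angle_id <- 0L
  hits$event_id <- NA_integer_
  offset <- 0L
  for (a in unique(hits$angle_id)) {
    idx <- which(hits$angle_id == a)
    ids <- cpp_group_coincidences(hits$time_ns[idx], window_ns)
    hits$event_id[idx] <- ids + offset
    offset <- offset + max(ids)
  }
  hits
}

#' Compton scattering angle from the energy pair
#'
#' \eqn{\cos\theta = 1 - m_e c^2 (1/E_r - 1/(E_f + E_r))} with
#' \eqn{m_e c^2 = 511} keV, where the front deposit is the scatter recoil and
#' the rear deposit the absorbed scattered photon.  Kinematically invalid
#' pairs (\eqn{\cos\theta \notin (-1, 1)}) yield `NA` and must be discarded
#' upstream.
#'
#' @param E_f front-plane deposit in keV (> 0), vectorized.
#' @param E_r rear-plane deposit in keV (> 0), vectorized.
#' @return scattering angle in radians, `NA` where invalid.
#' @export
compute_scatter_angle <- function(E_f, E_r) {
  if (any(E_f <= 0) || any(E_r <= 0)) stop("deposits must be positive")
  cth <- 1 - .electron_mass_kev * (1 / E_r - 1 / (E_f + E_r))
  ifelse(cth > -1 & cth < 1, acos(cth), NA_real_)
}

#' Classify a single coincidence event into modality candidates
#'
#' Hit-pattern rules: a camera with at least one front and one rear hit is a
#' Compton candidate ("front && rear"); a camera with rear hit(s) and no
#' front hit is a pinhole candidate ("(not front) && rear"); two distinct
#' cameras with any deposit form a PET candidate pair ("cam X && cam Y").
#' An event may be a candidate for several modes at once; the final
#' per-modality selection is done by the energy cuts.
#'
#' @param event data.frame of the hits of one event.
#' @param mode `"compton"`, `"pinhole"` or `"pet"`.
#' @return for compton/pinhole, the integer camera ids that are candidates
#'   (possibly empty); for pet, a two-column matrix of candidate camera
#'   pairs.
#' @export
classify_event <- function(event, mode = c("compton", "pinhole", "pet")) {
  mode <- match.arg(mode)
  cams <- sort(unique(event$camera_id))
  has_front <- vapply(cams, function(cc)
    any(event$camera_id == cc & event$plane == "front"), logical(1))
  has_rear <- vapply(cams, function(cc)
    any(event$camera_id == cc & event$plane == "rear"), logical(1))
  if (mode == "compton") return(cams[has_front & has_rear])
  if (mode == "pinhole") return(cams[!has_front & has_rear])
  if (length(cams) < 2) return(matrix(integer(0), ncol = 2))
  t(utils::combn(cams, 2))
}

# per-(event, camera) plane summaries used by all extractors
.event_camera_summary <- function(hits) {
  dt <- data.table::as.data.table(hits)
  dt[, .(
    E_f = sum(energy_kev[plane == "front"]),
    E_r = sum(energy_kev[plane == "rear"]),
    n_front = sum(plane == "front"),
    n_rear = sum(plane == "rear"),
    fix = if (any(plane == "front"))
      ix[plane == "front"][which.max(energy_kev[plane == "front"])] else NA_integer_,
    fiy = if (any(plane == "front"))
      iy[plane == "front"][which.max(energy_kev[plane == "front"])] else NA_integer_,
    rix = if (any(plane == "rear"))
      ix[plane == "rear"][which.max(energy_kev[plane == "rear"])] else NA_integer_,
    riy = if (any(plane == "rear"))
      iy[plane == "rear"][which.max(energy_kev[plane == "rear"])] else NA_integer_
  ), by = .(angle_id, event_id, camera_id)]
}

.angle_cameras <- function(setup, angle_id) {
  build_multi_angle(setup)[[angle_id + 1L]]$cameras
}

#' Select and geometrize Compton events
#'
#' Applies the Compton hit pattern (front and rear hit in the same camera),
#' the per-target energy windows, and the kinematic validity check, then
#' converts pixel indices to world positions under the per-angle camera
#' poses.  Multi-hit events sum the deposits per plane and use the
#' highest-energy pixel per plane as the interaction position.
#'
#' @param events hits data.frame with `event_id` (see
#'   [group_coincidences()]).
#' @param setup the `hcc_setup` the data were acquired with.
#' @param target energy-cut target (see [energy_cut()]), a Compton row.
#' @return data.frame with scatter/absorb world positions (mm), `E_f`,
#'   `E_r`, `theta` (radians) and `angle_id`.
#' @export
extract_compton_events <- function(events, setup, target = "cs137") {
  cut <- energy_cut(target)
  if (is.null(cut$front) || is.null(cut$total))
    stop("target is not a Compton energy-cut row")
  sm <- .event_camera_summary(events)
  sel <- sm[sm$n_front > 0 & sm$n_rear > 0 &
              sm$E_f > cut$front[1] & sm$E_f < cut$front[2] &
              (sm$E_f + sm$E_r) > cut$total[1] &
              (sm$E_f + sm$E_r) < cut$total[2], ]
  if (nrow(sel) == 0)
    return(data.frame(sx = numeric(0), sy = numeric(0), sz = numeric(0),
                      ax = numeric(0), ay = numeric(0), az = numeric(0),
                      E_f = numeric(0), E_r = numeric(0),
                      theta = numeric(0), angle_id = integer(0)))
  theta <- compute_scatter_angle(sel$E_f, sel$E_r)
  ok <- !is.na(theta)
  sel <- sel[ok, ]; theta <- theta[ok]
  poses <- build_multi_angle(setup)
  out <- vector("list", nrow(sel))
  spos <- matrix(NA_real_, nrow(sel), 3)
  apos <- matrix(NA_real_, nrow(sel), 3)
  for (i in seq_len(nrow(sel))) {
    cam <- poses[[sel$angle_id[i] + 1L]]$cameras[[sel$camera_id[i] + 1L]]
    spos[i, ] <- pixel_center_world(cam, "front", sel$fix[i], sel$fiy[i])
    apos[i, ] <- pixel_center_world(cam, "rear", sel$rix[i], sel$riy[i])
  }
  data.frame(sx = spos[, 1], sy = spos[, 2], sz = spos[, 3],
             ax = apos[, 1], ay = apos[, 2], az = apos[, 3],
             E_f = sel$E_f, E_r = sel$E_r, theta = theta,
             angle_id = sel$angle_id)
}

#' Select pinhole events
#'
#' Applies the pinhole hit pattern (rear hit with no front hit in the same
#' camera) and the rear-deposit energy window.  The highest-energy rear
#' pixel carries the event.
#'
#' @inheritParams extract_compton_events
#' @param target a pinhole energy-cut row (e.g. `"am241"`).
#' @return data.frame with `angle_id`, `camera_id`, `ix`, `iy`, `E_r`.
#' @export
extract_pinhole_events <- function(events, setup, target = "am241") {
  cut <- energy_cut(target)
  if (is.null(cut$rear)) stop("target is not a pinhole energy-cut row")
  sm <- .event_camera_summary(events)
  sel <- sm[sm$n_front == 0 & sm$n_rear > 0 &
              sm$E_r > cut$rear[1] & sm$E_r < cut$rear[2], ]
  data.frame(angle_id = sel$angle_id, camera_id = sel$camera_id,
             ix = sel$rix, iy = sel$riy, E_r = sel$E_r)
}

#' Pair PET coincidences
#'
#' Emits one line of response per event in which exactly two cameras have a
#' per-camera total deposit inside the PET energy window; events with three
#' or more qualifying cameras are discarded as ambiguous.  The LOR endpoint
#' in a camera is the front-pixel center when the front plane fired, else
#' the rear-pixel center.
#'
#' @inheritParams extract_compton_events
#' @param window per-camera total-energy window in keV (default the 511 keV
#'   row, 471--551 keV).
#' @return data.frame with endpoint columns `ax..az`, `bx..bz` (world mm),
#'   energies `E_a`, `E_b`, camera ids and `angle_id`.
#' @export
pair_pet_events <- function(events, setup, window = c(471, 551)) {
  sm <- .event_camera_summary(events)
  tot <- sm$E_f + sm$E_r
  qual <- sm[tot > window[1] & tot < window[2], ]
  dtq <- data.table::as.data.table(qual)
  nq <- dtq[, .N, by = .(angle_id, event_id)]
  keep <- nq[nq$N == 2L, ]
  dtq <- dtq[paste(angle_id, event_id) %in% paste(keep$angle_id, keep$event_id)]
  if (nrow(dtq) == 0)
    return(data.frame(ax = numeric(0), ay = numeric(0), az = numeric(0),
                      bx = numeric(0), by = numeric(0), bz = numeric(0),
                      E_a = numeric(0), E_b = numeric(0),
                      cam_a = integer(0), cam_b = integer(0),
                      angle_id = integer(0)))
  data.table::setorderv(dtq, c("angle_id", "event_id", "camera_id"))
  poses <- build_multi_angle(setup)
  endpoint <- function(row) {
    cam <- poses[[row$angle_id + 1L]]$cameras[[row$camera_id + 1L]]
    if (row$n_front > 0)
      pixel_center_world(cam, "front", row$fix, row$fiy)
    else
      pixel_center_world(cam, "rear", row$rix, row$riy)
  }
  odd <- seq(1, nrow(dtq), by = 2)
  a <- t(vapply(odd, function(i) endpoint(dtq[i]), numeric(3)))
  b <- t(vapply(odd, function(i) endpoint(dtq[i + 1]), numeric(3)))
  data.frame(ax = a[, 1], ay = a[, 2], az = a[, 3],
             bx = b[, 1], by = b[, 2], bz = b[, 3],
             E_a = dtq$E_f[odd] + dtq$E_r[odd],
             E_b = dtq$E_f[odd + 1] + dtq$E_r[odd + 1],
             cam_a = dtq$camera_id[odd], cam_b = dtq$camera_id[odd + 1],
             angle_id = dtq$angle_id[odd])
}

#' Apply an energy cut to per-camera candidate summaries
#'
#' Lower-level surface over the per-target windows: given per-candidate
#' front/rear deposits, returns which candidates pass every window of the
#' target row.
#'
#' @param E_f,E_r front and rear deposits in keV (vectorized; use 0 for a
#'   plane that did not fire).
#' @param target energy-cut target or explicit window list.
#' @return logical vector.
#' @export
apply_energy_cut <- function(E_f, E_r, target) {
  cut <- energy_cut(target)
  keep <- rep(TRUE, length(E_f))
  if (!is.null(cut$front))
    keep <- keep & E_f > cut$front[1] & E_f < cut$front[2]
  if (!is.null(cut$total))
    keep <- keep & (E_f + E_r) > cut$total[1] & (E_f + E_r) < cut$total[2]
  if (!is.null(cut$rear))
    keep <- keep & E_r > cut$rear[1] & E_r < cut$rear[2]
  if (!is.null(cut$percam))
    keep <- keep & (E_f + E_r) > cut$percam[1] & (E_f + E_r) < cut$percam[2]
  keep
}
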