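mkhits <- function(t, camera = 0L, plane = "rear", e = 60) {
  n <- length(t)
  data.frame(time_ns = t, camera_id = rep_len(camera, n),
             plane = rep_len(plane, n), ix = rep_len(22L, n),
             iy = rep_len(22L, n), energy_kev = rep_len(e, n))
}

test_that("coincidence grouping is greedy and anchored at the opener", {
  ev <- group_coincidences(mkhits(c(0, 50, 1000)), 100)
  expect_equal(ev$event_id, c(1, 1, 2))
  # window anchored at the opener, not the last hit
  ev <- group_coincidences(mkhits(c(0, 90, 180)), 100)
  expect_equal(ev$event_id, c(1, 1, 2))
  expect_equal(nrow(group_coincidences(mkhits(numeric(0)))), 0)
  expect_error(group_coincidences(mkhits(c(10, 0))), "sorted")
})

test_that("grouping partitions hits and conserves deposited energy", {
  set.seed(42)
  n <- 500
  hits <- mkhits(sort(runif(n, 0, 1e6)), camera = sample(0:3, n, TRUE),
                 e = runif(n, 10, 700))
  ev <- group_coincidences(hits, 100)
  expect_false(any(is.na(ev$event_id)))
  expect_equal(nrow(ev), n)
  expect_equal(sum(ev$energy_kev), sum(hits$energy_kev))
  # within each event, all hits lie within the window of the opener
  sp <- split(ev$time_ns, ev$event_id)
  expect_true(all(vapply(sp, function(t) max(t) - min(t) <= 100, logical(1))))
})

test_that("hit patterns classify into modality candidates", {
  ev <- data.frame(camera_id = c(0L, 0L),
                   plane = c("front", "rear"),
                   ix = 22L, iy = 22L, energy_kev = c(150, 512))
  expect_equal(classify_event(ev, "compton"), 0L)
  expect_length(classify_event(ev, "pinhole"), 0)
  ev2 <- data.frame(camera_id = 1L, plane = "rear", ix = 22L, iy = 22L,
                    energy_kev = 60)
  expect_equal(classify_event(ev2, "pinhole"), 1L)
  ev3 <- data.frame(camera_id = c(0L, 2L), plane = "rear", ix = 22L,
                    iy = 22L, energy_kev = c(511, 511))
  expect_equal(classify_event(ev3, "pet"), matrix(c(0L, 2L), 1))
})

test_that("per-nuclide energy windows behave as tabulated", {
  # 662 keV row: front recoil window plus total window
  expect_true(apply_energy_cut(50, 600, "cs137"))
  expect_false(apply_energy_cut(150, 512, "cs137"))  # front cut (back-scatter)
  # 60 keV row: rear-only window
  expect_true(apply_energy_cut(0, 60, "am241"))
  expect_false(apply_energy_cut(0, 80, "am241"))
  expect_error(energy_cut("tc99m"), "unknown")
  custom <- list(mode = "pinhole", target_kev = 140, rear = c(120, 160))
  expect_true(apply_energy_cut(0, 140, custom))
})

test_that("scatter-angle kinematics match the Compton relation", {
  # vanishing recoil -> forward scatter
  expect_lt(compute_scatter_angle(1e-6, 662), 1e-3)
  expect_equal(compute_scatter_angle(100, 562) * 180 / pi, 30.38,
               tolerance = 1e-3)
  # kinematically impossible pair
  expect_true(is.na(compute_scatter_angle(400, 100)))
  expect_error(compute_scatter_angle(-1, 100), "positive")
  # round trip: E_f, E_r built from a known angle recover it exactly
  th <- seq(0.05, 3.0, length.out = 40)
  for (E in c(245, 356, 511, 662)) {
    e_sc <- E / (1 + E / 511 * (1 - cos(th)))
    got <- compute_scatter_angle(E - e_sc, e_sc)
    expect_lt(max(abs(got - th)), 1e-9)
  }
})
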