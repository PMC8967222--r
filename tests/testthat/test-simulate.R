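test_that("degenerate model with no motion and no noise gives frozen tracks", {
  m <- simulation_model(motion_state("free", 0), localization_sigma_um = 0,
                        seed = 2)
  sim <- simulate_tracks(m, protocol_fast(n_frames = 6), 4)
  tbl <- tibble::as_tibble(sim$tracks)
  per_track <- split(tbl, tbl$track_id)
  for (tr in per_track) {
    expect_true(all(tr$x_um == tr$x_um[1]))
    expect_true(all(tr$y_um == tr$y_um[1]))
  }
})

test_that("lag-1 displacement moments match the blurred-diffusion closed form", {
  # per-axis mean squared displacement 2D(dt - tE/3) + 2 sigma^2
  sim <- one_state_sim(11, n_tracks = 600, n_frames = 21)
  d <- track_displacements(sim$tracks)
  sq <- c(d$dx_um^2, d$dy_um^2)
  expect_gte(length(sq), 2e4)
  expected <- 2 * 0.5 * (0.012 - 0.010 / 3) + 2 * 0.03^2
  se <- stats::sd(sq) / sqrt(length(sq))
  expect_lt(abs(mean(sq) - expected), 3 * se)
})

test_that("lag-n MSD follows 4D(n dt - tE/3) + 4 sigma^2 for n = 1..5", {
  sim <- one_state_sim(12, n_tracks = 800, n_frames = 21)
  tbl <- tibble::as_tibble(sim$tracks)
  per_track <- split(tbl, tbl$track_id)
  for (lag in 1:5) {
    sq <- unlist(lapply(per_track, function(tr) {
      n <- nrow(tr)
      dx <- tr$x_um[(1 + lag):n] - tr$x_um[1:(n - lag)]
      dy <- tr$y_um[(1 + lag):n] - tr$y_um[1:(n - lag)]
      dx^2 + dy^2
    }))
    expected <- 4 * 0.5 * (lag * 0.012 - 0.010 / 3) + 4 * 0.03^2
    se <- stats::sd(sq) / sqrt(length(sq))
    expect_lt(abs(mean(sq) - expected), 3 * se)
  }
})

test_that("photobleaching truncates tracks with exponential lifetimes", {
  # k_b = 0: all tracks span the movie
  m0 <- simulation_model(motion_state("free", 0.1), bleach_rate_s = 0,
                         seed = 4)
  sim0 <- simulate_tracks(m0, protocol_fast(n_frames = 15), 50)
  expect_true(all(sim0$truth$tracks$n_frames_recorded == 15L))
  # k_b > 0: mean lifetime 1/k_b (exponential-lifetime oracle)
  m1 <- simulation_model(motion_state("free", 0.1), bleach_rate_s = 0.5,
                         seed = 5)
  sim1 <- simulate_tracks(m1, protocol_slow(n_frames = 800), 1500)
  life <- pmin(sim1$truth$tracks$bleach_time_s, 160)
  se <- stats::sd(life) / sqrt(length(life))
  expect_lt(abs(mean(life) - 2), 3 * se)
  # recorded frames never outlive the bleach event
  expect_true(all((sim1$truth$tracks$n_frames_recorded - 1) * 0.2 + 0.01 <=
                    sim1$truth$tracks$bleach_time_s))
})

test_that("confined states plateau at or below the disk geometry bound", {
  # lags far beyond L^2/(4D): MSD plateau <= L^2
  L <- 0.15
  m <- simulation_model(motion_state("confined", 0.2,
                                     confinement_radius_um = L),
                        localization_sigma_um = 0, seed = 6)
  sim <- simulate_tracks(m, protocol_fast(n_frames = 60), 300)
  tbl <- tibble::as_tibble(sim$tracks)
  per_track <- split(tbl, tbl$track_id)
  for (lag in c(30, 50)) {
    sq <- unlist(lapply(per_track, function(tr) {
      n <- nrow(tr)
      dx <- tr$x_um[(1 + lag):n] - tr$x_um[1:(n - lag)]
      dy <- tr$y_um[(1 + lag):n] - tr$y_um[1:(n - lag)]
      dx^2 + dy^2
    }))
    expect_lt(mean(sq), L^2)
    expect_gt(mean(sq), 0.5 * L^2)   # a genuine plateau, not frozen motion
  }
})

test_that("state occupancy converges to the stationary distribution", {
  # uniform destination choice => stationary occupancy proportional to the
  # mean dwell of each state
  m <- simulation_model(
    list(motion_state("bound", 0.01, mean_dwell_s = 0.3),
         motion_state("free", 0.3, mean_dwell_s = 0.1)),
    initial_weights = c(0.5, 0.5), localization_sigma_um = 0.01, seed = 7)
  sim <- simulate_tracks(m, protocol_fast(n_frames = 100), 300)
  lab <- sim$truth$displacements$state
  p1 <- mean(lab == 1L)
  expect_lt(abs(p1 - 0.75), 3 * sqrt(0.75 * 0.25 / 300) + 0.02)
  # every recorded displacement is labeled exactly once
  expect_identical(nrow(sim$truth$displacements),
                   nrow(track_displacements(sim$tracks)))
})

test_that("same seed gives byte-identical track sets", {
  m <- simulation_model(
    list(motion_state("confined", 0.05, confinement_radius_um = 0.2,
                      mean_dwell_s = 0.5),
         motion_state("free", 0.5, mean_dwell_s = 0.5)),
    initial_weights = c(0.4, 0.6), bleach_rate_s = 0.3, seed = 99)
  s1 <- simulate_tracks(m, protocol_fast(n_frames = 30), 80)
  s2 <- simulate_tracks(m, protocol_fast(n_frames = 30), 80)
  expect_identical(s1$tracks, s2$tracks)
  expect_identical(s1$truth, s2$truth)
})

test_that("invalid simulation inputs are rejected", {
  expect_error(motion_state("confined", 0.1), "confinement_radius_um")
  expect_error(
    simulation_model(list(motion_state("bound", 0.5),
                          motion_state("free", 0.1))),
    "smallest diffusivity")
  expect_error(simulation_model(motion_state("free", 0.1),
                                initial_weights = c(0.5, 0.5)),
               "initial_weights")
  expect_error(simulation_model(motion_state("free", 0.1), n_substeps = 4),
               "n_substeps")
})
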