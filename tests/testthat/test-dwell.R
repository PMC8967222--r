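slow_track <- function(id, n_frames, x, y, cell = "c1") {
  tibble::tibble(track_id = id, cell_id = cell, frame = seq_len(n_frames),
                 x_um = x, y_um = y)
}

test_that("a stationary 11-frame track gives one dwell of 2.0 s", {
  ts <- track_set(slow_track(1, 11, rep(0.5, 11), rep(0.5, 11)),
                  protocol_slow(n_frames = 11))
  dw <- extract_dwell_times(ts, bound_radius_um = 0.2, min_bound_frames = 2)
  expect_equal(nrow(dw), 1L)
  expect_equal(dw$dwell_s, 2.0)
})

test_that("fast-diffuser dwell events match the displacement-distribution oracle", {
  m <- simulation_model(motion_state("free", 0.5),
                        localization_sigma_um = 0.03, seed = 23)
  sim <- simulate_tracks(m, protocol_slow(n_frames = 30), 400)
  # Rayleigh oracle: per-axis displacement variance v = 2D(dt - tE/3) +
  # 2 sigma^2, so P(|d| <= r) = 1 - exp(-r^2 / (2v)) per displacement
  v <- 2 * 0.5 * (0.2 - 0.01 / 3) + 2 * 0.03^2
  p <- 1 - exp(-0.2^2 / (2 * v))
  d <- track_displacements(sim$tracks)
  frac_bound <- mean(sqrt(d$dx_um^2 + d$dy_um^2) <= 0.2)
  expect_lt(abs(frac_bound - p), 3 * sqrt(p * (1 - p) / nrow(d)))
  # dwell events are maximal bound runs; their expected count per track is
  # p + (n-1) p (1-p) for n = 29 independent displacements
  suppressWarnings(
    dw <- extract_dwell_times(sim$tracks, bound_radius_um = 0.2))
  expected_events <- 400 * (p + 28 * p * (1 - p))
  expect_lt(abs(nrow(dw) - expected_events) / expected_events, 0.1)
  # a tight radius well below the displacement scale silences fast tracks
  suppressWarnings(
    dw2 <- extract_dwell_times(sim$tracks, bound_radius_um = 0.02))
  expect_lt(nrow(dw2) / 400, 0.05)
})

test_that("exponential residence is recovered by extraction within 3 SE", {
  sim <- simulate_residence_tracks(protocol_slow(n_frames = 400), 3000,
                                   residence_exponential(2),
                                   bleach = NULL, seed = 24)
  suppressWarnings(dw <- extract_dwell_times(sim$tracks))
  # ground-truth oracle: a molecule visible for k frames should produce a
  # dwell of (k - 1) frame intervals (the bound criterion never splits a
  # stationary track)
  k <- sim$truth$tracks$n_frames_recorded
  expected <- mean((k[k >= 2] - 1) * 0.2)
  expect_equal(nrow(dw), sum(k >= 2))
  se <- stats::sd(dw$dwell_s) / sqrt(nrow(dw))
  expect_equal(mean(dw$dwell_s), expected, tolerance = 1e-9)
  # and the observed mean sits near the true 2 s residence (memoryless law:
  # conditioning on two visible frames compensates the lost first frame)
  expect_lt(abs(mean(dw$dwell_s) - 2), 3 * se + 0.15)
})

test_that("tracks without cell annotation fall into one synthetic cell", {
  ts <- track_set(slow_track(1, 5, rep(0, 5), rep(0, 5))[, -2],
                  protocol_slow(n_frames = 5))
  expect_warning(dw <- extract_dwell_times(ts), "cell_id")
  expect_equal(unique(dw$cell_id), "cell01")
})

test_that("pooling one cell reproduces its own empirical survival", {
  s <- dwell_samples(tibble::tibble(cell_id = "c1",
                                    dwell_s = c(0.2, 0.4, 0.4, 1.0)))
  dist <- pool_weighted(s)
  expect_equal(dist$support$t_s, c(0.2, 0.4, 1.0))
  expect_equal(dist$support$survival, c(1, 0.75, 0.25))
})

test_that("identical samples with different track counts pool to the same survival", {
  a <- dwell_samples(tibble::tibble(cell_id = "a", dwell_s = c(0.2, 0.6)),
                     tibble::tibble(cell_id = "a", n_tracks = 2L))
  b <- dwell_samples(tibble::tibble(cell_id = "b", dwell_s = c(0.2, 0.6)),
                     tibble::tibble(cell_id = "b", n_tracks = 20L))
  dist <- pool_weighted(list(a, b))
  expect_equal(dist$support$survival, c(1, 0.5))
})

test_that("disjoint-support pooling equals the brute-force weighted mixture", {
  a <- dwell_samples(tibble::tibble(cell_id = "a",
                                    dwell_s = c(0.2, 0.2, 0.4)),
                     tibble::tibble(cell_id = "a", n_tracks = 3L))
  b <- dwell_samples(tibble::tibble(cell_id = "b", dwell_s = c(1, 2)),
                     tibble::tibble(cell_id = "b", n_tracks = 1L))
  dist <- pool_weighted(list(a, b))
  w <- c(a = 0.75, b = 0.25)
  surv_a <- function(t) mean(c(0.2, 0.2, 0.4) >= t)
  surv_b <- function(t) mean(c(1, 2) >= t)
  for (t in dist$support$t_s) {
    expect_equal(dwell_survival(dist, t),
                 w["a"] * surv_a(t) + w["b"] * surv_b(t),
                 ignore_attr = TRUE)
  }
})

test_that("pooling nothing is an error", {
  s <- dwell_samples(tibble::tibble(cell_id = character(0),
                                    dwell_s = numeric(0)))
  expect_error(pool_weighted(s), "empty")
})
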