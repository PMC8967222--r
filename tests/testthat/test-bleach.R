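test_that("single-exponential control collapses the triple fit", {
  ctrl <- simulate_control_dwells(protocol_slow(n_frames = 800),
                                  bleach_model(1, 2), 5000, seed = 6)
  fit <- fit_triple_exponential(ctrl, seed = 1)
  expect_s3_class(fit, "smt_bleach")
  # the fit collapses onto one timescale: every component carrying real
  # amplitude recovers tau within 10%
  carrying <- fit$amplitudes > 0.05
  expect_true(any(carrying))
  expect_true(all(abs(fit$timescales_s[carrying] - 2) / 2 < 0.1))
})

test_that("a known triple mixture is recovered on the observed support", {
  true_b <- bench_bleach()
  ctrl <- simulate_control_dwells(protocol_slow(n_frames = 800),
                                  true_b, 10000, seed = 7)
  fit <- fit_triple_exponential(ctrl, seed = 2)
  dist <- pool_weighted(ctrl)
  tt <- dist$support$t_s
  # generator oracle: the midpoint frame quantization shifts the sample's
  # survival to S_true(t - dt/2) = sum A_i e^{dt/(2 tau_i)} e^{-t/tau_i};
  # the reported (renormalized) model should match that mixture
  A_ref <- true_b$amplitudes * exp(0.1 / true_b$timescales_s)
  A_ref <- A_ref / sum(A_ref)
  ref <- bleach_model(A_ref, true_b$timescales_s)
  dev <- abs(bleach_survival(fit, tt) - bleach_survival(ref, tt))
  expect_lt(max(dev), 0.02)
  # S(0) = 1 exactly by the amplitude constraint
  expect_equal(bleach_survival(fit, 0), 1, tolerance = 1e-12)
  expect_equal(sum(fit$amplitudes), 1, tolerance = 1e-12)
})

test_that("the control fit demands enough data", {
  small <- dwell_samples(tibble::tibble(cell_id = "c",
                                        dwell_s = seq(0.2, 2, by = 0.2)))
  expect_error(fit_triple_exponential(small), "at least 100")
  degenerate <- dwell_samples(tibble::tibble(cell_id = "c",
                                             dwell_s = rep(0.4, 500)))
  expect_error(fit_triple_exponential(degenerate), "degenerate")
})

test_that("a flat bleach model leaves the distribution unchanged", {
  s <- dwell_samples(tibble::tibble(cell_id = "c",
                                    dwell_s = c(0.2, 0.4, 0.4, 1, 3)))
  dist <- pool_weighted(s)
  flat <- bleach_model(1, 1e12)
  corr <- correct_photobleach(dist, flat)
  expect_equal(corr$support$survival, dist$support$survival,
               tolerance = 1e-9)
  expect_true(corr$corrected)
})

test_that("correction raises survival before renormalization and stays monotone", {
  ctrl <- simulate_control_dwells(protocol_slow(n_frames = 800),
                                  bleach_model(1, 3), 2000, seed = 8)
  dist <- pool_weighted(ctrl)
  b <- bleach_model(c(0.6, 0.4), c(1, 5))
  s_raw <- dist$support$survival / bleach_survival(b, dist$support$t_s)
  expect_true(all(s_raw >= dist$support$survival - 1e-12))
  corr <- correct_photobleach(dist, b)
  expect_true(all(diff(corr$support$survival) <= 1e-12))
  expect_equal(corr$support$survival[1], 1)
  # re-correcting is refused
  expect_error(correct_photobleach(corr, b), "already")
})

test_that("a bleach survival below the floor aborts the correction", {
  s <- dwell_samples(tibble::tibble(cell_id = "c",
                                    dwell_s = c(0.5, 1, 200)))
  dist <- pool_weighted(s)
  b <- bleach_model(1, 2)   # exp(-100) << 1e-6 at t = 200
  expect_error(correct_photobleach(dist, b), "shorter")
})

test_that("power-law residence seen through bleaching is restored by correction", {
  p <- protocol_slow(n_frames = 800)
  target <- simulate_residence_tracks(p, 3000, residence_power_law(2, 0.2),
                                      bleach = bench_bleach(), n_cells = 3,
                                      seed = 9)
  bare <- simulate_residence_tracks(p, 3000, residence_power_law(2, 0.2),
                                    bleach = NULL, n_cells = 3, seed = 9)
  dw_obs <- pool_weighted(extract_dwell_times(target$tracks))
  dw_bare <- pool_weighted(extract_dwell_times(bare$tracks))
  corr <- correct_photobleach(dw_obs, bench_bleach())
  grid <- dw_bare$support$t_s[dw_bare$support$t_s <= 10]
  dev <- abs(dwell_survival(corr, grid) - dwell_survival(dw_bare, grid))
  expect_lt(max(dev), 0.03)
})
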