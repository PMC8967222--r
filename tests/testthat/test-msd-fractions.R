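test_that("K = 1 posterior-weighted MSD equals the plain ensemble TA-MSD", {
  sim <- one_state_sim(15, n_tracks = 120, n_frames = 12)
  fit <- fit_pem(sim$tracks, K = 1, n_restarts = 1, n_perturbations = 0,
                 seed = 1)
  msd <- state_msd(fit, max_lag = 4)
  # brute-force ensemble average of per-track time-averaged MSDs
  tbl <- tibble::as_tibble(sim$tracks)
  per_track <- split(tbl, tbl$track_id)
  for (lag in 1:4) {
    plain <- mean(vapply(per_track, function(tr) {
      n <- nrow(tr)
      mean((tr$x_um[(1 + lag):n] - tr$x_um[1:(n - lag)])^2 +
             (tr$y_um[(1 + lag):n] - tr$y_um[1:(n - lag)])^2)
    }, numeric(1)))
    expect_equal(msd$msd_um2[msd$lag == lag], plain, tolerance = 1e-12)
  }
})

test_that("the slow state's MSD lies below the fast state's at every lag", {
  sim <- two_state_sim(16, n_tracks = 400)
  fit <- fit_pem(sim$tracks, K = 2, n_restarts = 1, n_perturbations = 1,
                 seed = 4)
  msd <- state_msd(fit, max_lag = 5)
  wide <- tidyr::pivot_wider(msd[, c("state", "lag", "msd_um2")],
                             names_from = "state", values_from = "msd_um2")
  expect_true(all(wide$`1` < wide$`2`))
})

test_that("a free state's MSD slope recovers 4D", {
  sim <- one_state_sim(17, n_tracks = 700, n_frames = 21)
  fit <- fit_pem(sim$tracks, K = 1, n_restarts = 1, n_perturbations = 0,
                 seed = 1)
  msd <- state_msd(fit, max_lag = 5)
  co <- stats::coef(stats::lm(msd_um2 ~ lag_s, data = msd))
  # slope 4D within a few percent (blur and noise act on the intercept)
  expect_lt(abs(co[["lag_s"]] - 4 * 0.5) / (4 * 0.5), 0.05)
})

test_that("max_lag beyond the shortest usable track errors", {
  sim <- one_state_sim(18, n_tracks = 50, n_frames = 6)
  fit <- fit_pem(sim$tracks, K = 1, n_restarts = 1, n_perturbations = 0,
                 seed = 1)
  expect_error(state_msd(fit, max_lag = 7), "max_lag")
})

test_that("fraction summary reproduces the headline bound/confined/free format", {
  model <- structure(
    list(K = 3, D = c(0.004, 0.02, 0.6), weights = c(0.36, 0.29, 0.35)),
    class = "pem_fit")
  fr <- summarize_fractions(model, bound_D_max = 0.03)
  expect_equal(fr$fraction_bound, 0.36)
  expect_equal(fr$fraction_confined, 0.29)
  expect_equal(fr$fraction_free, 0.35)
  expect_equal(fr$fraction_bound + fr$fraction_confined + fr$fraction_free,
               1, tolerance = 1e-9)
  expect_equal(fr$fraction_unbound, 0.35)
  expect_equal(fr$fraction_bound_class, 0.65)
})

test_that("a single free state gives fractions (0, 0, 1) with a warning", {
  model <- structure(list(K = 1, D = 0.5, weights = 1), class = "pem_fit")
  expect_warning(fr <- summarize_fractions(model), "no state")
  expect_equal(unlist(fr[, c("fraction_bound", "fraction_confined",
                             "fraction_free")], use.names = FALSE),
               c(0, 0, 1))
})

test_that("the bound fraction of the benchmark is recovered within 0.03", {
  sim <- two_state_sim(19, n_tracks = 1500)
  fit <- fit_pem(sim$tracks, K = 2, n_restarts = 1, n_perturbations = 2,
                 seed = 5)
  fr <- summarize_fractions(fit, bound_D_max = 0.03)
  expect_lt(abs(fr$fraction_bound - 0.3), 0.03)
})
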