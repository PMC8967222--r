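stationary_tracks <- function(x_um, y_um, n_frames = 3L) {
  n <- length(x_um)
  track_set(tibble::tibble(
    track_id = rep(seq_len(n), each = n_frames),
    frame = rep(seq_len(n_frames), n),
    x_um = rep(x_um, each = n_frames),
    y_um = rep(y_um, each = n_frames)),
    protocol_fast(n_frames = max(n_frames, 2L)))
}

test_that("a bright stationary emitter dominates every frame", {
  tr <- stationary_tracks(3.21, 2.14, 5)          # pixel (30, 20)
  st <- render_frames(tr, 1.3, photons_per_spot = 2e5, background = 1,
                      image_shape = c(48, 48), seed = 1)
  for (f in 1:5) {
    am <- which(st[, , f] == max(st[, , f]), arr.ind = TRUE)
    expect_equal(unname(am[1, ]), c(20, 30))
  }
})

test_that("emitter-free frames contain only background noise", {
  tr <- stationary_tracks(2.14, 2.14)             # dark emitter: 0 photons
  st <- render_frames(tr, 1.3, photons_per_spot = 0, background = 8,
                      image_shape = c(40, 40), n_frames = 20, seed = 2)
  expect_lt(abs(mean(st) - 8), 3 * sqrt(8 / length(st)))
})

test_that("integrated intensity matches the Poisson-sum oracle", {
  # two emitters 10 sigma apart
  tr <- stationary_tracks(c(2.14, 3.531), c(2.14, 2.14), 40) # 13 px apart
  st <- render_frames(tr, 1.3, photons_per_spot = 800, background = 2,
                      image_shape = c(40, 40), seed = 3)
  totals <- apply(st, 3, sum)
  expected <- 2 * 800 + 2 * 40 * 40
  se <- stats::sd(totals) / sqrt(length(totals))
  expect_lt(abs(mean(totals) - expected), 3 * se)
})

test_that("out-of-bounds positions are rejected", {
  tr <- stationary_tracks(10, 10)
  expect_error(render_frames(tr, 1.3, image_shape = c(16, 16)),
               "outside the image")
})

test_that("a noiseless emitter is localized to well under 0.05 px", {
  img <- 1e6 * tidysmt:::gauss_spot(32, 32, 17.3, 12.6, 1.3)
  sp <- detect_spots(img, threshold_sd = 3, psf_sigma_px = 1.3)
  expect_equal(nrow(sp), 1L)
  expect_lt(abs(sp$x_px - 17.3), 0.05)
  expect_lt(abs(sp$y_px - 12.6), 0.05)
})

test_that("blank frames yield zero detections in at least 99% of frames", {
  tr <- stationary_tracks(2.14, 2.14)
  st <- render_frames(tr, 1.3, photons_per_spot = 0, background = 5,
                      image_shape = c(64, 64), n_frames = 100, seed = 4)
  sp <- detect_spots(st, threshold_sd = 3, psf_sigma_px = 1.3)
  expect_lte(length(unique(sp$frame)), 1L)
})

test_that("two rendered emitters are recovered near their true positions", {
  tr <- stationary_tracks(c(2.14, 3.531), c(2.14, 3.0), 30)
  st <- render_frames(tr, 1.3, photons_per_spot = 2000, background = 5,
                      image_shape = c(40, 40), seed = 5)
  sp <- detect_spots(st, threshold_sd = 3, psf_sigma_px = 1.3)
  truth <- cbind(x = c(20, 33), y = c(20, 28.037))
  counts <- table(factor(sp$frame, levels = 1:30))
  expect_true(all(counts == 2))
  err <- vapply(seq_len(nrow(sp)), function(i) {
    min(sqrt((sp$x_px[i] - truth[, "x"])^2 + (sp$y_px[i] - truth[, "y"])^2))
  }, numeric(1))
  # photon-limited localization: RMSE of order psf_sigma/sqrt(N) ~ 0.03 px
  expect_lt(sqrt(mean(err^2)), 0.15)
})

test_that("TIFF round trip preserves photon counts", {
  tr <- stationary_tracks(2.14, 2.14, 3)
  st <- render_frames(tr, 1.3, photons_per_spot = 500, background = 5,
                      image_shape = c(24, 24), seed = 6)
  path <- withr::local_tempfile(fileext = ".tif")
  write_frames_tiff(st, path)
  back <- read_frames_tiff(path)
  expect_equal(dim(back), dim(st))
  expect_equal(back, st)
})
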