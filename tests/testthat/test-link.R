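test_that("a single slow molecule yields one track spanning all frames", {
  locs <- tibble::tibble(frame = 1:10,
                         x_px = 10 + cumsum(rep(0.5, 10)),
                         y_px = 20 + cumsum(rep(-0.3, 10)))
  ts <- link_tracks(locs, protocol_slow(n_frames = 10), max_disp_px = 4)
  tbl <- tibble::as_tibble(ts)
  expect_equal(dplyr::n_distinct(tbl$track_id), 1L)
  expect_equal(tbl$frame, 1:10)
  expect_equal(tbl$x_um, locs$x_px * 0.107)
})

test_that("crossing molecules take the pairing with least total squared displacement", {
  # frame 1 ends at x = 0 and 10; frame 2 detections at x = 2 and 9:
  # identity pairing costs 4 + 1 = 5, the swap costs 81 + 64 = 145
  locs <- tibble::tibble(frame = c(1, 1, 2, 2),
                         x_px = c(0, 10, 2, 9), y_px = 0)
  ts <- link_tracks(locs, protocol_slow(), max_disp_px = 4)
  tbl <- tibble::as_tibble(ts)
  t1 <- tbl[tbl$track_id == tbl$track_id[tbl$frame == 1 & tbl$x_um == 0], ]
  expect_equal(sort(um_to_px(protocol_slow(), t1$x_um)), c(0, 2))
  # brute-force enumeration of both pairings confirms the optimum
  cost_identity <- (2 - 0)^2 + (9 - 10)^2
  cost_swap <- (9 - 0)^2 + (2 - 10)^2
  expect_lt(cost_identity, cost_swap)
})

test_that("swap-ambiguous crossings resolve deterministically by row order", {
  # perfectly symmetric: both pairings cost 2; the first input row wins
  locs <- tibble::tibble(frame = c(1, 1, 2, 2),
                         x_px = c(0, 2, 1, 1), y_px = c(0, 0, 1, -1))
  ts1 <- link_tracks(locs, protocol_slow(), max_disp_px = 4)
  ts2 <- link_tracks(locs, protocol_slow(), max_disp_px = 4)
  expect_identical(tibble::as_tibble(ts1), tibble::as_tibble(ts2))
})

test_that("no link ever exceeds the gate and long jumps split tracks", {
  set.seed(31)
  locs <- tibble::tibble(frame = rep(1:40, each = 2),
                         x_px = runif(80, 0, 60),
                         y_px = runif(80, 0, 60))
  ts <- link_tracks(locs, protocol_slow(), max_disp_px = 4,
                    min_track_len = 2)
  d <- track_displacements(ts)
  max_step_um <- max(sqrt(d$dx_um^2 + d$dy_um^2))
  expect_lte(max_step_um, 4 * 0.107 + 1e-12)
})

test_that("linking is invariant to input row order", {
  m <- simulation_model(motion_state("free", 0.02),
                        localization_sigma_um = 0.02, seed = 17)
  sim <- simulate_tracks(m, protocol_slow(n_frames = 20), 10,
                         region_um = c(20, 20))
  tbl <- tibble::as_tibble(sim$tracks)
  locs <- tibble::tibble(frame = tbl$frame, x_um = tbl$x_um,
                         y_um = tbl$y_um)
  ts1 <- link_tracks(locs, protocol_slow(), max_disp_px = 4)
  set.seed(1)
  ts2 <- link_tracks(locs[sample(nrow(locs)), ], protocol_slow(),
                     max_disp_px = 4)
  # track ids are assigned in input order, so compare the partitions: each
  # track is identified by its sorted (frame, x, y) signature
  signatures <- function(ts) {
    tbl <- dplyr::arrange(tibble::as_tibble(ts), .data$track_id,
                          .data$frame)
    unname(sort(vapply(
      split(tbl, tbl$track_id),
      function(tr) paste(tr$frame, round(tr$x_um, 9), round(tr$y_um, 9),
                         collapse = ";"),
      character(1))))
  }
  expect_identical(signatures(ts1), signatures(ts2))
})

test_that("duplicate localizations are rejected with the frame named", {
  locs <- tibble::tibble(frame = c(3, 3), x_px = c(1, 1), y_px = c(2, 2))
  expect_error(link_tracks(locs, protocol_slow()), "frame\\(s\\) 3")
})

test_that("short tracks are discarded by min_track_len", {
  locs <- tibble::tibble(frame = c(1, 2, 3, 5),
                         x_px = c(1, 1.5, 2, 30), y_px = 1)
  ts <- link_tracks(locs, protocol_slow(), max_disp_px = 4,
                    min_track_len = 2)
  expect_equal(dplyr::n_distinct(tibble::as_tibble(ts)$track_id), 1L)
  expect_equal(nrow(ts), 3L)
})

test_that("ground-truth links are recovered at low density", {
  agreement <- link_truth_agreement(protocol_slow(n_frames = 60), 4, 0.02,
                                    seed = 21)
  expect_gte(agreement["agree"], 0.99)
})

test_that("link purity does not improve when density rises", {
  a_low <- link_truth_agreement(protocol_slow(n_frames = 40), 4, 0.02,
                                seed = 22, n_tracks = 8)
  a_high <- link_truth_agreement(protocol_slow(n_frames = 40), 4, 0.02,
                                 seed = 22, n_tracks = 160,
                                 region = c(15, 15))
  expect_lte(a_high["agree"], a_low["agree"] + 1e-9)
})
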