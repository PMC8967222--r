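# Canonical simulation settings shared across tests: a fast-acquisition
# two-state mixture (chromatin-bound-like D = 0.02 um^2/s at weight 0.3,
# free D = 0.5 um^2/s at weight 0.7) and its single-state counterpart.

bench_protocol <- function(n_frames = 21L) protocol_fast(n_frames = n_frames)

two_state_sim <- function(seed, n_tracks = 2000L, n_frames = 21L) {
  m <- simulation_model(
    list(motion_state("bound", 0.02), motion_state("free", 0.5)),
    initial_weights = c(0.3, 0.7),
    localization_sigma_um = 0.03, seed = seed)
  simulate_tracks(m, bench_protocol(n_frames), n_tracks)
}

one_state_sim <- function(seed, n_tracks = 2000L, n_frames = 21L,
                          D = 0.5) {
  m <- simulation_model(motion_state("free", D),
                        localization_sigma_um = 0.03, seed = seed)
  simulate_tracks(m, bench_protocol(n_frames), n_tracks)
}

# true state of each kept track (no switching in the benchmarks, so the
# initial state is the track's state)
kept_track_states <- function(sim) {
  tt <- sim$truth$tracks
  tt$initial_state[tt$n_frames_recorded >= 2L]
}

# triple-exponential bleaching used in residence tests
bench_bleach <- function() bleach_model(c(0.5, 0.3, 0.2), c(0.5, 2, 10))

# brute-force moment estimator of D from a track set (the K = 1 oracle):
# D = [Var(d) + 2 Cov(d_i, d_{i+1})] / (2 dt), pooled over axes and tracks
moment_D_oracle <- function(tracks) {
  d <- track_displacements(tracks)
  dt <- protocol_of(tracks)$frame_interval_s
  per_track <- split(d, d$track_id)
  s0 <- sum(vapply(per_track, function(x) sum(x$dx_um^2 + x$dy_um^2),
                   numeric(1)))
  n0 <- sum(vapply(per_track, nrow, integer(1))) * 2
  s1 <- sum(vapply(per_track, function(x) {
    n <- nrow(x)
    if (n < 2) return(0)
    sum(x$dx_um[-n] * x$dx_um[-1]) + sum(x$dy_um[-n] * x$dy_um[-1])
  }, numeric(1)))
  n1 <- sum(vapply(per_track, function(x) 2L * (nrow(x) - 1L), integer(1)))
  (s0 / n0 + 2 * s1 / n1) / (2 * dt)
}

# dense multivariate-normal log-density with tridiagonal Toeplitz
# covariance, via base chol(): the independent likelihood oracle
dense_tridiag_loglik <- function(x, a, b) {
  n <- length(x)
  S <- diag(a, n)
  if (n >= 2) {
    idx <- cbind(seq_len(n - 1), seq_len(n - 1) + 1L)
    S[idx] <- b
    S[idx[, 2:1, drop = FALSE]] <- b
  }
  R <- chol(S)
  z <- backsolve(R, x, transpose = TRUE)
  -0.5 * (n * log(2 * pi)) - sum(log(diag(R))) - 0.5 * sum(z^2)
}

# Simulate diffusing molecules over a field of view, pool their
# localizations (rows shuffled), relink, and score the fraction of links
# that join positions of the same true molecule.
link_truth_agreement <- function(protocol, max_disp_px, D, seed,
                                 n_tracks = 16L, region = c(30, 30)) {
  m <- simulation_model(motion_state("free", D),
                        localization_sigma_um = 0.03, seed = seed)
  sim <- simulate_tracks(m, protocol, n_tracks, region_um = region)
  tbl <- tibble::as_tibble(sim$tracks)
  locs <- withr::with_seed(seed, tbl[sample(nrow(tbl)),
                                     c("frame", "x_um", "y_um")])
  linked <- link_tracks(locs, protocol, max_disp_px = max_disp_px)
  lt <- tibble::as_tibble(linked)
  key <- function(df) paste(round(df$x_um, 9), round(df$y_um, 9))
  truth_map <- stats::setNames(tbl$track_id, key(tbl))
  lt$true_id <- truth_map[key(lt)]
  lt <- dplyr::arrange(lt, .data$track_id, .data$frame)
  same <- unlist(tapply(lt$true_id, lt$track_id,
                        function(v) v[-1] == v[-length(v)]))
  c(agree = mean(same), n_links = length(same))
}

# EM likelihood traces must be non-decreasing (small relative slack for
# floating-point noise)
expect_monotone_trace <- function(fit) {
  tr <- fit$trace
  expect_true(all(diff(tr) >= -1e-9 * pmax(abs(tr[-1]), 1)))
}
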