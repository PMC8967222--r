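#' Per-track displacement sequences
#'
#' Converts a track set into frame-to-frame displacement records: one row
#' per displacement with the per-axis components in micrometers. Counts are
#' conserved (a track of N positions yields N - 1 displacements), and the
#' acquisition protocol travels along as an attribute.
#'
#' @param tracks An [track_set()].
#' @return A tibble with columns `track_id`, `frame` (frame of the
#'   displacement start), `dx_um`, `dy_um`, carrying the protocol in
#'   `attr(, "protocol")`.
#' @export
track_displacements <- function(tracks) {
  stopifnot(inherits(tracks, "smt_tracks"))
  protocol <- protocol_of(tracks)
  tbl <- tibble::as_tibble(tracks)
  validate_track_frames(tbl)
  out <- tbl |>
    dplyr::group_by(.data$track_id) |>
    dplyr::mutate(dx_um = dplyr::lead(.data$x_um) - .data$x_um,
                  dy_um = dplyr::lead(.data$y_um) - .data$y_um) |>
    dplyr::filter(!is.na(.data$dx_um)) |>
    dplyr::ungroup() |>
    dplyr::select("track_id", "frame", "dx_um", "dy_um")
  attr(out, "protocol") <- protocol
  out
}

# Group tracks by displacement-sequence length for vectorized likelihood
# evaluation. Returns a list with, per unique length n: the n x T matrices
# of x and y displacements, the track ids, and per-track sufficient
# statistics s0 = sum(dx^2 + dy^2), s1 = sum of adjacent products (both
# axes). `track_id` gives the global track order used by all fit outputs.
disp_groups <- function(tracks) {
  d <- track_displacements(tracks)
  protocol <- attr(d, "protocol")
  split_d <- split(d, factor(d$track_id, levels = unique(d$track_id)))
  ids <- names(split_d)
  n_m <- vapply(split_d, nrow, integer(1))
  groups <- lapply(split(seq_along(split_d), n_m), function(idx) {
    n <- nrow(split_d[[idx[1]]])
    dx <- vapply(split_d[idx], `[[`, numeric(n), "dx_um")
    dy <- vapply(split_d[idx], `[[`, numeric(n), "dy_um")
    dx <- matrix(dx, nrow = n); dy <- matrix(dy, nrow = n)
    s1 <- if (n >= 2L) {
      colSums(dx[-1L, , drop = FALSE] * dx[-n, , drop = FALSE]) +
        colSums(dy[-1L, , drop = FALSE] * dy[-n, , drop = FALSE])
    } else rep(0, length(idx))
    list(n = n, dx = dx, dy = dy, idx = idx,
         s0 = colSums(dx^2) + colSums(dy^2), s1 = s1)
  })
  list(groups = groups, track_id = ids, n_m = n_m,
       n_tracks = length(ids), n_disp = sum(n_m), protocol = protocol)
}

# Log-density of one axis-stack of displacement sequences under the
# stationary blurred-diffusion model: tridiagonal Toeplitz covariance with
# diagonal `a` and off-diagonal `b`. `x` is an n x T matrix; returns T
# log-likelihood contributions. LDL' recursion: the pivots d_i are shared
# by all columns, the forward solve is vectorized across columns.
tridiag_loglik <- function(x, a, b) {
  n <- nrow(x)
  a <- max(a, 1e-300)
  dpiv <- numeric(n)
  dpiv[1L] <- a
  if (n >= 2L) for (i in 2:n) dpiv[i] <- a - b^2 / dpiv[i - 1L]
  if (any(dpiv <= 0)) return(rep(-Inf, ncol(x)))
  z <- x
  if (n >= 2L) {
    for (i in 2:n) z[i, ] <- x[i, ] - (b / dpiv[i - 1L]) * z[i - 1L, ]
  }
  quad <- colSums(z^2 / dpiv)
  -0.5 * (n * log(2 * pi) + sum(log(dpiv)) + quad)
}

# Per-track log-likelihood under each state: a_k = 2*D_k*dt + 2*eps2_k,
# b_k = -eps2_k (eps2 may be shared). Returns an n_tracks x K matrix in the
# global track order of `gd`.
state_loglik_matrix <- function(gd, D, eps2, dt) {
  K <- length(D)
  eps2 <- rep_len(eps2, K)
  ll <- matrix(NA_real_, gd$n_tracks, K)
  for (g in gd$groups) {
    for (k in seq_len(K)) {
      a <- 2 * D[k] * dt + 2 * eps2[k]
      b <- -eps2[k]
      ll[g$idx, k] <- tridiag_loglik(g$dx, a, b) + tridiag_loglik(g$dy, a, b)
    }
  }
  ll
}
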