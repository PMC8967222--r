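#' Extract chromatin-binding dwell times from slow-acquisition tracks
#'
#' A molecule is considered bound while every frame-to-frame displacement
#' stays within `bound_radius_um`; maximal bound stretches covering at
#' least `min_bound_frames` frames become dwell events of duration
#' `(frames - 1) * frame_interval`. Events are grouped per cell (column
#' `cell_id`; tracks without one fall into a single synthetic cell with a
#' warning).
#'
#' @param tracks An [track_set()] recorded under the slow (time-lapse)
#'   protocol; a warning is issued for fast protocols, where binding cannot
#'   be separated from slow diffusion.
#' @param bound_radius_um Maximum frame-to-frame displacement of a bound
#'   molecule (um). The default 0.2 um is of the order of the slow-channel
#'   tracking gate expressed in micrometers.
#' @param min_bound_frames Minimum number of frames of a bound stretch
#'   (>= 2).
#' @return A tibble of class `smt_dwell_samples` with columns `cell_id`,
#'   `dwell_s`; per-cell contributing track counts in `attr(, "cells")`,
#'   the protocol in `attr(, "protocol")`.
#' @export
extract_dwell_times <- function(tracks, bound_radius_um = 0.2,
                                min_bound_frames = 2L) {
  stopifnot(inherits(tracks, "smt_tracks"), is_scalar(bound_radius_um),
            bound_radius_um > 0, is_count(min_bound_frames, 2))
  protocol <- protocol_of(tracks)
  if (protocol$frame_interval_s < 0.1)
    warning("dwell extraction expects the slow (time-lapse) protocol; ",
            "frame interval is only ",
            1e3 * protocol$frame_interval_s, " ms")
  tbl <- tibble::as_tibble(tracks)
  if (!"cell_id" %in% names(tbl)) {
    warning("tracks carry no cell_id; grouping all tracks into one ",
            "synthetic cell")
    tbl$cell_id <- "cell01"
  }
  dt <- protocol$frame_interval_s
  min_run <- min_bound_frames - 1L        # displacements per bound stretch
  d <- track_displacements(tracks)
  cells <- tbl |> dplyr::distinct(.data$track_id, .data$cell_id)
  d <- dplyr::left_join(d, cells, by = "track_id")
  ev <- d |>
    dplyr::group_by(.data$track_id, .data$cell_id) |>
    dplyr::reframe(run = bound_run_lengths(
      sqrt(.data$dx_um^2 + .data$dy_um^2) <= bound_radius_um)) |>
    dplyr::filter(.data$run >= min_run) |>
    dplyr::mutate(dwell_s = .data$run * dt)
  n_by_cell <- ev |>
    dplyr::distinct(.data$cell_id, .data$track_id) |>
    dplyr::count(.data$cell_id, name = "n_tracks")
  out <- dwell_samples(ev[, c("cell_id", "dwell_s")], n_by_cell)
  attr(out, "protocol") <- protocol
  out
}

# lengths of maximal TRUE runs
bound_run_lengths <- function(flag) {
  r <- rle(flag)
  out <- r$lengths[r$values]
  if (!length(out)) integer(0) else out
}

#' Pool per-cell dwell samples into a weighted ensemble distribution
#'
#' Combines the dwell samples of several cells into one distribution whose
#' survival function is the cell-weighted ensemble average
#' \eqn{S(t) = \sum_c w_c S_c(t)} with \eqn{w_c \propto n_c}, the number of
#' tracks contributing in cell c. Equivalently, each dwell observation
#' carries the repetition weight \eqn{w_c / m_c} (with \eqn{m_c} dwells in
#' its cell).
#'
#' @param samples An `smt_dwell_samples` tibble (from
#'   [extract_dwell_times()] or [simulate_control_dwells()]) or a list of
#'   them.
#' @return An object of class `dwell_dist`: a list with `obs` (cell_id,
#'   dwell_s, weight), `support` (t_s, survival, mass), `cell_weights`,
#'   `n_obs`, `corrected` and the protocol (if known).
#' @export
pool_weighted <- function(samples) {
  if (inherits(samples, "smt_dwell_samples")) samples <- list(samples)
  stopifnot(is.list(samples), length(samples) >= 1L)
  protocol <- purrr::detect(purrr::map(samples, attr, "protocol"),
                            Negate(is.null))
  cells <- dplyr::bind_rows(purrr::map(samples, attr, "cells")) |>
    dplyr::count(.data$cell_id, wt = .data$n_tracks, name = "n_tracks")
  obs <- dplyr::bind_rows(purrr::map(samples, tibble::as_tibble))
  if (nrow(obs) == 0L) stop("all dwell samples are empty")
  cw <- cells |>
    dplyr::mutate(weight = .data$n_tracks / sum(.data$n_tracks))
  obs <- obs |>
    dplyr::add_count(.data$cell_id, name = "m_c") |>
    dplyr::left_join(cw[, c("cell_id", "weight")], by = "cell_id") |>
    dplyr::mutate(weight = .data$weight / .data$m_c) |>
    dplyr::select("cell_id", "dwell_s", "weight")
  new_dwell_dist(obs, cw, corrected = FALSE, protocol = protocol)
}

new_dwell_dist <- function(obs, cell_weights, corrected, protocol,
                           support = NULL) {
  if (is.null(support)) {
    support <- weighted_survival(obs$dwell_s, obs$weight)
  }
  stopifnot(all(diff(support$survival) <= 1e-12),
            abs(support$survival[1] - 1) < 1e-9)
  structure(list(obs = obs, support = support, cell_weights = cell_weights,
                 n_obs = nrow(obs), corrected = corrected,
                 protocol = protocol),
            class = "dwell_dist")
}

# survival S(t) = sum of weights of dwells >= t, on the sorted unique
# support; masses are the per-point weights (right-continuous ECDF
# convention).
weighted_survival <- function(t, w) {
  w <- w / sum(w)
  agg <- stats::aggregate(w, list(t_s = t), sum)
  agg <- agg[order(agg$t_s), ]
  tibble::tibble(t_s = agg$t_s,
                 survival = rev(cumsum(rev(agg$x))),
                 mass = agg$x)
}

#' Evaluate a dwell distribution's survival function
#'
#' Step-function (right-continuous, `P(T >= t)`) evaluation at arbitrary
#' times.
#' @param dist A `dwell_dist`.
#' @param t Times (s).
#' @return Survival values in `[0, 1]`.
#' @export
dwell_survival <- function(dist, t) {
  stopifnot(inherits(dist, "dwell_dist"))
  s <- dist$support
  n <- nrow(s)
  i <- findInterval(t, s$t_s, left.open = TRUE)   # support points < t
  ifelse(i >= n, 0, s$survival[pmin(i + 1L, n)])
}

#' @export
print.dwell_dist <- function(x, ...) {
  cat(sprintf(
    "<dwell_dist> %d dwell(s) from %d cell(s), support %.3g-%.3g s%s\n",
    x$n_obs, nrow(x$cell_weights), min(x$support$t_s), max(x$support$t_s),
    if (x$corrected) " [photobleach-corrected]" else ""))
  invisible(x)
}
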