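#' Simulate an H2B-like photobleaching control dwell sample
#'
#' Emulates the dwell-time measurement of a stably bound control protein
#' (histone H2B) imaged under the same acquisition conditions as the protein
#' of interest: the true residence is effectively unbounded, so the observed
#' dwell of each molecule is limited only by photobleaching and the movie
#' span. Lifetimes are drawn from a mixture of up to three exponentials,
#' truncated at the movie span, and quantized to the frame grid with the
#' midpoint convention (a lifetime in `[k, k+1)` frames is reported as
#' `(k + 1/2)` frames), which keeps the sample mean unbiased.
#'
#' @param protocol Acquisition protocol (or `"fast"`/`"slow"`).
#' @param bleach A [bleach_model()] with finite timescales.
#' @param n_tracks Number of control molecules (>= 1).
#' @param n_cells Number of cells to spread the molecules over.
#' @param seed Integer seed.
#' @return A tibble of class `smt_dwell_samples` with columns `cell_id`,
#'   `dwell_s`, and a per-cell `n_tracks` table in `attr(, "cells")`.
#' @examples
#' ctrl <- simulate_control_dwells(protocol_slow(), bleach_model(1, 2), 100)
#' mean(ctrl$dwell_s)
#' @export
simulate_control_dwells <- function(protocol, bleach, n_tracks,
                                    n_cells = 1L, seed = 1L) {
  protocol <- as_protocol(protocol)
  stopifnot(inherits(bleach, "smt_bleach"), is_count(n_tracks, 1),
            is_count(n_cells, 1))
  dt <- protocol$frame_interval_s
  span <- protocol$n_frames * dt
  with_substream(seed, "control_dwells", 0L, {
    life <- pmin(rbleach(n_tracks, bleach), span)
    k <- pmin(floor(life / dt), protocol$n_frames - 1L)
    dwell <- (k + 0.5) * dt
    cell <- sprintf("cell%02d", rep_len(seq_len(n_cells), n_tracks))
    dwell_samples(tibble::tibble(cell_id = cell, dwell_s = dwell))
  })
}

#' Construct a dwell sample table
#'
#' Tags a `(cell_id, dwell_s)` table as an `smt_dwell_samples` object and
#' records the per-cell contributing track counts used as pooling weights
#' by [pool_weighted()]. Useful for bringing externally measured dwell
#' times into the residence analysis.
#'
#' @param tbl Data frame with columns `cell_id` and `dwell_s` (seconds,
#'   positive).
#' @param n_tracks_by_cell Optional tibble with columns `cell_id`,
#'   `n_tracks`; defaults to the number of dwells per cell.
#' @return An `smt_dwell_samples` tibble.
#' @export
dwell_samples <- function(tbl, n_tracks_by_cell = NULL) {
  stopifnot(all(c("cell_id", "dwell_s") %in% names(tbl)))
  if (any(tbl$dwell_s <= 0)) stop("dwell times must be positive")
  cells <- n_tracks_by_cell %||%
    dplyr::count(tbl, .data$cell_id, name = "n_tracks")
  structure(tibble::as_tibble(tbl),
            class = c("smt_dwell_samples", class(tibble::tibble())),
            cells = cells)
}

#' Residence-time laws for bound-molecule simulation
#'
#' Constructors for the residence (true chromatin-binding time) laws used by
#' [simulate_residence_tracks()]: a power law with survival
#' \eqn{(t/t_{min})^{-(\alpha - 1)}} for `t >= t_min`, an exponential, or a
#' stable control that never unbinds (H2B-like).
#'
#' @param alpha Power-law exponent (> 1).
#' @param t_min_s Lower cutoff of the power law (s).
#' @param mean_s Mean of the exponential residence (s).
#' @return A `residence_law` list.
#' @export
residence_power_law <- function(alpha, t_min_s) {
  stopifnot(is_scalar(alpha), alpha > 1, is_scalar(t_min_s), t_min_s > 0)
  structure(list(type = "power_law", alpha = alpha, t_min_s = t_min_s),
            class = "residence_law")
}

#' @rdname residence_power_law
#' @export
residence_exponential <- function(mean_s) {
  stopifnot(is_scalar(mean_s), mean_s > 0)
  structure(list(type = "exponential", mean_s = mean_s),
            class = "residence_law")
}

#' @rdname residence_power_law
#' @export
residence_stable <- function() {
  structure(list(type = "stable"), class = "residence_law")
}

draw_residence <- function(law, n) {
  switch(law$type,
         power_law = law$t_min_s * runif(n)^(-1 / (law$alpha - 1)),
         exponential = rexp(n, 1 / law$mean_s),
         stable = rep(Inf, n),
         stop("unknown residence law"))
}

#' Simulate chromatin-bound molecules with a chosen residence law
#'
#' Generates tracks of bound molecules whose visible lifetime is
#' `min(residence, bleach lifetime, movie span)`: each molecule sits at a
#' fixed chromatin site (optionally with a small bound-state diffusivity),
#' its observed positions carry localization noise, and it disappears when
#' it unbinds or photobleaches. The number of recorded frames uses a uniform
#' random phase of the binding event relative to the frame clock. This is
#' the generator behind residence-time pipeline validation: the same
#' measurement operator ([extract_dwell_times()]) can be applied to a target
#' protein (power-law residence) and to a stable H2B-like control
#' (`residence_stable()`), exactly as in a real experiment.
#'
#' @param protocol Acquisition protocol (should be the slow preset for
#'   residence analysis).
#' @param n_tracks Number of molecules.
#' @param residence A [residence_power_law()], [residence_exponential()] or
#'   [residence_stable()] law.
#' @param bleach Optional [bleach_model()]; `NULL` disables bleaching (only
#'   allowed with a finite residence law or a finite movie).
#' @param localization_sigma_um Localization noise s.d. per axis (um).
#' @param diffusivity_um2_s Residual bound-state diffusivity (um^2/s).
#' @param n_cells Number of cells molecules are spread over.
#' @param region_um Field of view `c(width, height)` in um.
#' @param seed Integer seed.
#' @return A list of class `smt_sim` with `tracks` and `truth`.
#' @export
simulate_residence_tracks <- function(protocol, n_tracks, residence,
                                      bleach = NULL,
                                      localization_sigma_um = 0.03,
                                      diffusivity_um2_s = 0,
                                      n_cells = 1L,
                                      region_um = c(10, 10),
                                      seed = 1L) {
  protocol <- as_protocol(protocol)
  stopifnot(inherits(residence, "residence_law"), is_count(n_tracks, 1),
            is_count(n_cells, 1), is_scalar(localization_sigma_um),
            localization_sigma_um >= 0, is_scalar(diffusivity_um2_s),
            diffusivity_um2_s >= 0)
  if (!is.null(bleach)) stopifnot(inherits(bleach, "smt_bleach"))
  dt <- protocol$frame_interval_s
  nf <- protocol$n_frames

  with_substream(seed, "residence_tracks", 0L, {
    t_res <- draw_residence(residence, n_tracks)
    t_bleach <- if (is.null(bleach)) rep(Inf, n_tracks)
                else rbleach(n_tracks, bleach)
    visible <- pmin(t_res, t_bleach)
    if (any(!is.finite(visible)) && !is.finite(nf * dt))
      stop("unbounded visible lifetime: provide a bleach model or a finite ",
           "movie")
    n_rec <- pmin(nf, floor(visible / dt + runif(n_tracks)))
    cell <- sprintf("cell%02d", rep_len(seq_len(n_cells), n_tracks))
    cx <- runif(n_tracks, 0, region_um[1])
    cy <- runif(n_tracks, 0, region_um[2])

    keep <- which(n_rec >= 2L)
    rows <- purrr::map(keep, function(m) {
      k <- n_rec[m]
      sdd <- sqrt(2 * diffusivity_um2_s * dt)
      x <- cx[m] + cumsum(c(0, rnorm(k - 1L, 0, sdd))) +
        rnorm(k, 0, localization_sigma_um)
      y <- cy[m] + cumsum(c(0, rnorm(k - 1L, 0, sdd))) +
        rnorm(k, 0, localization_sigma_um)
      tibble::tibble(track_id = m, cell_id = cell[m],
                     frame = seq_len(k), x_um = x, y_um = y)
    })
    truth <- tibble::tibble(track_id = seq_len(n_tracks), cell_id = cell,
                            residence_s = t_res, bleach_time_s = t_bleach,
                            n_frames_recorded = as.integer(n_rec))
    if (!length(rows))
      stop("no molecule was visible for two frames; check the residence ",
           "law and protocol")
    tracks <- track_set(dplyr::bind_rows(rows), protocol,
                        provenance = list(source = "simulate_residence_tracks",
                                          seed = seed))
    structure(list(tracks = tracks, truth = list(tracks = truth)),
              class = "smt_sim")
  })
}
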