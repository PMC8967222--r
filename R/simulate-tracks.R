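#' Simulate switching multi-state trajectories with blur and bleaching
#'
#' Generates 2D single-molecule trajectories with the statistical structure
#' the downstream analysis assumes, plus ground-truth labels. The true
#' position evolves by Brownian sub-steps (at least 10 per exposure window);
#' confined states reflect off a disk of radius L centered on the position
#' where the state was entered; states switch at exponential times with a
#' uniform choice of destination. The observed position of each frame is the
#' average of the sub-step positions inside the exposure window (motion blur)
#' plus isotropic Gaussian localization noise of s.d. sigma per axis. Each
#' molecule photobleaches after an exponential lifetime with hazard
#' `bleach_rate_s`; a frame is recorded only if the molecule survives its
#' whole exposure, and tracks shorter than two recorded frames are dropped
#' from the track table (they still appear in the ground truth).
#'
#' With these conventions the per-axis lag-1 displacement variance of a free
#' state is \eqn{2D(\Delta t - t_E/3) + 2\sigma^2} up to a relative
#' discretization error of order `1/n_substeps^2`.
#'
#' @param model A [simulation_model()].
#' @param protocol An [acquisition_protocol()] or `"fast"`/`"slow"`.
#' @param n_tracks Number of molecules to simulate (>= 1).
#' @param region_um Optional `c(width, height)` in um; molecules start
#'   uniformly in this rectangle (default: all start at the origin).
#' @return A list of class `smt_sim` with elements `tracks` (an
#'   [track_set()] tibble) and `truth` (list of tibbles: `tracks` with
#'   per-molecule initial state and bleach time, `displacements` with the
#'   true state of every recorded displacement — labeled by the state
#'   occupied at the displacement's midpoint — and `dwells` with the true
#'   state intervals).
#' @examples
#' m <- simulation_model(motion_state("free", 0.5), seed = 7)
#' sim <- simulate_tracks(m, protocol_fast(n_frames = 10), n_tracks = 3)
#' sim$tracks
#' @export
simulate_tracks <- function(model, protocol, n_tracks, region_um = NULL) {
  stopifnot(inherits(model, "simulation_model"), is_count(n_tracks, 1))
  protocol <- as_protocol(protocol)
  if (!is.null(region_um))
    stopifnot(length(region_um) == 2L, all(region_um > 0))
  K <- length(model$states)
  D <- vapply(model$states, `[[`, numeric(1), "diffusivity_um2_s")
  L <- vapply(model$states, function(s) s$confinement_radius_um %||% NA_real_,
              numeric(1))
  confined <- !is.na(L)
  exit_rate <- 1 / vapply(model$states, `[[`, numeric(1), "mean_dwell_s")

  dt <- protocol$frame_interval_s
  tE <- protocol$exposure_s
  nf <- protocol$n_frames
  grid <- substep_grid(protocol, model$n_substeps)

  out <- with_substream(model$seed, "simulate_tracks", 0L, {
    start_xy <- if (is.null(region_um)) {
      matrix(0, n_tracks, 2)
    } else {
      cbind(runif(n_tracks, 0, region_um[1]), runif(n_tracks, 0, region_um[2]))
    }
    bleach <- if (model$bleach_rate_s > 0) {
      rexp(n_tracks, model$bleach_rate_s)
    } else {
      rep(Inf, n_tracks)
    }
    lapply(seq_len(n_tracks), function(m) {
      simulate_one_track(model, K, D, L, confined, exit_rate,
                         dt, tE, nf, grid, start_xy[m, ], bleach[m])
    })
  })

  n_rec <- vapply(out, `[[`, integer(1), "n_rec")
  labels <- vapply(model$states, `[[`, character(1), "label")
  truth_tracks <- tibble::tibble(
    track_id = seq_len(n_tracks),
    initial_state = vapply(out, `[[`, integer(1), "initial_state"),
    bleach_time_s = vapply(out, `[[`, numeric(1), "bleach_time"),
    n_frames_recorded = n_rec)
  kept <- which(n_rec >= 2L)
  if (!length(kept))
    stop("no track survived to two recorded frames; lower bleach_rate_s ",
         "or lengthen the movie")
  disp_state <- unlist(lapply(out[kept], `[[`, "disp_state"))
  truth_disp <- tibble::tibble(
    track_id = rep(kept, n_rec[kept] - 1L),
    frame = sequence(n_rec[kept] - 1L),
    state = disp_state,
    state_label = labels[disp_state])
  dw_n <- vapply(out, function(o) length(o$dwell_state), integer(1))
  truth_dwells <- tibble::tibble(
    track_id = rep(seq_len(n_tracks), dw_n),
    state = unlist(lapply(out, `[[`, "dwell_state")),
    t_enter_s = unlist(lapply(out, `[[`, "dwell_enter")),
    t_exit_s = unlist(lapply(out, `[[`, "dwell_exit"))) |>
    dplyr::mutate(state_label = labels[.data$state]) |>
    dplyr::filter(.data$t_exit_s > .data$t_enter_s)

  track_tbl <- tibble::tibble(
    track_id = rep(kept, n_rec[kept]),
    frame = sequence(n_rec[kept]),
    x_um = unlist(lapply(out[kept], `[[`, "x")),
    y_um = unlist(lapply(out[kept], `[[`, "y")))
  tracks <- track_set(track_tbl, protocol,
                      provenance = list(source = "simulate_tracks",
                                        seed = model$seed,
                                        n_tracks = n_tracks))
  structure(list(tracks = tracks,
                 truth = list(tracks = truth_tracks,
                              displacements = truth_disp,
                              dwells = truth_dwells)),
            class = "smt_sim")
}

#' @export
print.smt_sim <- function(x, ...) {
  cat("<smt_sim> simulated track set with ground truth\n")
  print(x$tracks)
  invisible(x)
}

# Sub-step layout of one frame interval: n_sub steps across the exposure,
# then dead-time steps no longer than the exposure itself.
substep_grid <- function(protocol, n_sub) {
  tE <- protocol$exposure_s
  tD <- protocol$frame_interval_s - tE
  dt_sub <- rep(tE / n_sub, n_sub)
  if (tD > 1e-12) {
    m_d <- max(1L, ceiling(tD / tE))
    dt_sub <- c(dt_sub, rep(tD / m_d, m_d))
  }
  list(dt_sub = dt_sub, n_expo = n_sub, n_per_frame = length(dt_sub))
}

simulate_one_track <- function(model, K, D, L, confined, exit_rate,
                               dt, tE, nf, grid, start, bleach_time) {
  # frames fully exposed before the bleach event are recorded
  n_rec <- if (is.finite(bleach_time)) {
    max(0L, min(nf, as.integer(floor((bleach_time - tE) / dt)) + 1L))
  } else nf
  s0 <- sample.int(K, 1L, prob = model$initial_weights)

  horizon <- if (n_rec >= 1L) (n_rec - 1L) * dt + tE else 0
  sched <- draw_schedule(s0, K, exit_rate, horizon)
  truth_horizon <- min(bleach_time, (nf - 1L) * dt + tE)

  base <- list(dwell_state = sched$states,
               dwell_enter = sched$t_enter,
               dwell_exit = pmin(sched$t_exit, truth_horizon),
               initial_state = s0, bleach_time = bleach_time,
               n_rec = n_rec, x = NULL, y = NULL, disp_state = NULL)
  if (n_rec < 2L) return(base)

  npf <- grid$n_per_frame
  dt_vec <- c(rep(grid$dt_sub, n_rec - 1L),
              grid$dt_sub[seq_len(grid$n_expo)])
  tg <- cumsum(c(0, dt_vec))                      # substep boundary times
  st <- if (length(sched$states) == 1L) {
    rep.int(sched$states, length(dt_vec))
  } else {
    sched$states[findInterval(tg[-length(tg)], sched$t_enter)]
  }

  pos <- propagate_positions(start, st, dt_vec, D, L, confined)

  # observed frame positions: mean over the exposure sub-step endpoints
  obs_idx <- outer(2:(grid$n_expo + 1L), (seq_len(n_rec) - 1L) * npf, `+`)
  ox <- colMeans(matrix(pos[obs_idx, 1], nrow = grid$n_expo))
  oy <- colMeans(matrix(pos[obs_idx, 2], nrow = grid$n_expo))
  sig <- model$localization_sigma_um
  if (sig > 0) {
    ox <- ox + rnorm(n_rec, 0, sig)
    oy <- oy + rnorm(n_rec, 0, sig)
  }
  base$x <- ox; base$y <- oy
  mid_t <- (seq_len(n_rec - 1L) - 1L) * dt + dt / 2
  base$disp_state <- if (length(sched$states) == 1L) {
    rep.int(sched$states, n_rec - 1L)
  } else {
    sched$states[findInterval(mid_t, sched$t_enter)]
  }
  base
}

# Exponential-holding-time state schedule with uniform destination choice.
draw_schedule <- function(s0, K, exit_rate, horizon) {
  states <- integer(0); t_enter <- numeric(0); t_exit <- numeric(0)
  s <- s0; t <- 0
  repeat {
    hold <- if (exit_rate[s] > 0 && K > 1L) rexp(1L, exit_rate[s]) else Inf
    states <- c(states, s); t_enter <- c(t_enter, t)
    t <- t + hold
    t_exit <- c(t_exit, t)
    if (t >= horizon || !is.finite(t)) break
    s <- sample_other(K, s)
  }
  list(states = states, t_enter = t_enter, t_exit = t_exit)
}

sample_other <- function(K, s) {
  cand <- seq_len(K)[-s]
  if (length(cand) == 1L) cand else sample(cand, 1L)
}

# Brownian propagation over sub-steps; confined segments reflect radially
# at a disk centered on the segment entry position.
propagate_positions <- function(start, st, dt_vec, D, L, confined) {
  n <- length(dt_vec)
  pos <- matrix(0, n + 1L, 2)
  pos[1L, ] <- start
  seg <- rle(st)
  i <- 1L
  for (k in seq_along(seg$lengths)) {
    len <- seg$lengths[k]
    s <- seg$values[k]
    idx <- i:(i + len - 1L)
    sdv <- sqrt(2 * D[s] * dt_vec[idx])
    stepx <- rnorm(len) * sdv
    stepy <- rnorm(len) * sdv
    p0 <- pos[i, ]
    if (confined[s]) {
      Ls <- L[s]
      cx <- p0[1]; cy <- p0[2]
      px <- p0[1]; py <- p0[2]
      for (j in seq_len(len)) {
        px <- px + stepx[j]; py <- py + stepy[j]
        dx <- px - cx; dy <- py - cy
        r <- sqrt(dx * dx + dy * dy)
        if (r > Ls) {
          # radial fold at the boundary; clamp pathological huge steps
          r2 <- abs(2 * Ls - r)
          if (r2 > Ls) r2 <- Ls
          px <- cx + dx * r2 / r
          py <- cy + dy * r2 / r
        }
        pos[i + j, 1] <- px
        pos[i + j, 2] <- py
      }
    } else {
      pos[idx + 1L, 1] <- p0[1] + cumsum(stepx)
      pos[idx + 1L, 2] <- p0[2] + cumsum(stepy)
    }
    i <- i + len
  }
  pos
}
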