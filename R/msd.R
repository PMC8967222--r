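#' Posterior-weighted mean-squared displacement per diffusive state
#'
#' For every state k, averages the time-averaged MSD of each track,
#' weighted by the track's posterior probability of belonging to that
#' state:
#' \deqn{MSD_k(n\Delta t) = \sum_m \gamma_{mk}\, msd_m(n) / \sum_m \gamma_{mk},}
#' where \eqn{msd_m(n)} is track m's time-averaged squared displacement at
#' lag n (both axes summed). Only tracks long enough to contribute a given
#' lag enter that lag's average; lags with zero effective weight are
#' dropped with a message.
#'
#' @param model A `pem_fit`.
#' @param tracks The [track_set()] the model was fitted to (matched by
#'   `track_id`); defaults to the data stored in the model.
#' @param max_lag Largest lag in frames.
#' @return A tibble of class `msd_curves` with columns `state`, `lag`
#'   (frames), `lag_s`, `msd_um2`, `n_eff` (summed posterior weight) and
#'   `n_tracks`.
#' @export
state_msd <- function(model, tracks = NULL, max_lag = 5L) {
  stopifnot(inherits(model, "pem_fit"), is_count(max_lag, 1))
  gd <- if (is.null(tracks)) model$data else disp_groups(tracks)
  if (!identical(gd$track_id, model$track_id))
    stop("tracks do not match the model's track ids")
  if (max_lag >= max(gd$n_m) + 1L)
    stop("max_lag must be below the longest usable track length")
  gamma <- model$posteriors
  K <- model$K
  dt <- gd$protocol$frame_interval_s
  # per-track time-averaged MSD at each lag
  msd_m <- matrix(NA_real_, gd$n_tracks, max_lag)
  for (g in gd$groups) {
    n_pos <- g$n + 1L
    x <- apply(g$dx, 2L, cumsum)
    y <- apply(g$dy, 2L, cumsum)
    x <- rbind(0, matrix(x, nrow = g$n))
    y <- rbind(0, matrix(y, nrow = g$n))
    for (lag in seq_len(min(max_lag, n_pos - 1L))) {
      i2 <- (1L + lag):n_pos
      i1 <- seq_len(n_pos - lag)
      dxl <- x[i2, , drop = FALSE] - x[i1, , drop = FALSE]
      dyl <- y[i2, , drop = FALSE] - y[i1, , drop = FALSE]
      msd_m[g$idx, lag] <- colMeans(dxl^2 + dyl^2)
    }
  }
  out <- purrr::map(seq_len(K), function(k) {
    purrr::map(seq_len(max_lag), function(lag) {
      ok <- !is.na(msd_m[, lag])
      w <- gamma[ok, k]
      if (sum(w) <= 0) return(NULL)
      tibble::tibble(state = k, lag = lag, lag_s = lag * dt,
                     msd_um2 = sum(w * msd_m[ok, lag]) / sum(w),
                     n_eff = sum(w), n_tracks = sum(ok))
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  dropped <- K * max_lag - nrow(out)
  if (dropped > 0)
    message(dropped, " state-lag combination(s) had zero effective weight ",
            "and were dropped")
  class(out) <- c("msd_curves", class(out))
  attr(out, "protocol") <- gd$protocol
  out
}
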