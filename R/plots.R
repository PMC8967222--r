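#' Plot trajectories
#'
#' Spatial paths of all tracks, colored by track id.
#' @param object An [track_set()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.smt_tracks <- function(object, ...) {
  tbl <- tibble::as_tibble(object)
  ggplot2::ggplot(tbl, ggplot2::aes(.data$x_um, .data$y_um,
                                    group = .data$track_id,
                                    color = factor(.data$track_id))) +
    ggplot2::geom_path(alpha = 0.7, show.legend = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  title = "Single-molecule trajectories") +
    ggplot2::theme_minimal()
}

#' Plot posterior-weighted MSD curves
#'
#' MSD versus lag time per diffusive state, the standard readout for
#' distinguishing bound, confined and free populations.
#' @param object An `msd_curves` tibble from [state_msd()].
#' @param log_scale Use log-log axes.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.msd_curves <- function(object, log_scale = TRUE, ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(.data$lag_s, .data$msd_um2,
                                    color = factor(.data$state))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "lag time (s)", y = "MSD (µm²)",
                  color = "state",
                  title = "Posterior-weighted MSD per diffusive state") +
    ggplot2::theme_minimal()
  if (log_scale) p <- p + ggplot2::scale_x_log10() + ggplot2::scale_y_log10()
  p
}

#' Plot a diffusive state spectrum
#'
#' Mixture weight against diffusivity for each state of a fitted model.
#' @param object A `pem_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pem_fit <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(.data$diffusivity_um2_s, .data$weight)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$diffusivity_um2_s,
                                       yend = 0)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "D (µm²/s)", y = "mixture weight",
                  title = sprintf("Diffusive state spectrum (K = %d)",
                                  object$K)) +
    ggplot2::theme_minimal()
}

#' Plot the BIC model-selection table
#'
#' @param object A `pem_selection`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pem_selection <- function(object, ...) {
  tbl <- object$bic_table[!is.na(object$bic_table$bic), ]
  ggplot2::ggplot(tbl, ggplot2::aes(.data$K, .data$bic)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_point(data = tbl[which.min(tbl$bic), ], color = "red",
                        size = 3) +
    ggplot2::labs(x = "number of diffusive states K", y = "BIC",
                  title = "BIC model selection") +
    ggplot2::theme_minimal()
}

#' Plot a dwell-time survival function
#'
#' Empirical survival on log-log axes; power-law residence appears as a
#' straight tail.
#' @param object A `dwell_dist`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dwell_dist <- function(object, ...) {
  ggplot2::ggplot(object$support, ggplot2::aes(.data$t_s, .data$survival)) +
    ggplot2::geom_step() + ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "dwell time (s)", y = "survival P(T ≥ t)",
                  title = if (object$corrected)
                    "Dwell-time survival (photobleach-corrected)"
                  else "Dwell-time survival") +
    ggplot2::theme_minimal()
}

#' Plot bound / confined / free fractions
#'
#' @param object A `fraction_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fraction_summary <- function(object, ...) {
  tbl <- tibble::tibble(
    class = factor(c("chromatin-bound", "confined", "free"),
                   levels = c("chromatin-bound", "confined", "free")),
    fraction = c(object$fraction_bound, object$fraction_confined,
                 object$fraction_free))
  ggplot2::ggplot(tbl, ggplot2::aes(.data$class, .data$fraction,
                                    fill = .data$class)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%",
                                                             100 * x)) +
    ggplot2::labs(x = NULL, y = "population fraction",
                  title = "Bound / confined / free fractions") +
    ggplot2::theme_minimal()
}
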