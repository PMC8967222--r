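#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a pEM state model
#'
#' @param x A `pem_fit`.
#' @param posterior_threshold Threshold for the per-state population
#'   column.
#' @param ... Unused.
#' @return One row per diffusive state: `state`, `diffusivity_um2_s`,
#'   `weight`, `population` (fraction of tracks with posterior above the
#'   threshold) and `eps2_um2`.
#' @export
tidy.pem_fit <- function(x, posterior_threshold = 0.6, ...) {
  tibble::tibble(state = seq_len(x$K),
                 diffusivity_um2_s = x$D,
                 weight = x$weights,
                 population = state_populations(x, posterior_threshold),
                 eps2_um2 = x$eps2,
                 sigma2_um2 = rep_len(x$sigma2, x$K))
}

#' @rdname tidy.pem_fit
#' @export
glance.pem_fit <- function(x, ...) {
  tibble::tibble(K = x$K, loglik = x$loglik, bic = x$bic,
                 n_tracks = x$n_tracks, n_disp = x$n_disp,
                 converged = x$converged, iterations = x$iterations,
                 sigma2_floored = x$sigma2_floored)
}

#' Tidy a BIC model-selection result
#'
#' @param x A `pem_selection`.
#' @param ... Unused.
#' @return `tidy()`: the BIC table (one row per candidate K); `glance()`:
#'   one row describing the selected model.
#' @export
tidy.pem_selection <- function(x, ...) x$bic_table

#' @rdname tidy.pem_selection
#' @export
glance.pem_selection <- function(x, ...) glance(x$best)

#' Tidy a photobleaching model
#'
#' @param x An `smt_bleach`.
#' @param ... Unused.
#' @return `tidy()`: one row per exponential component (`component`,
#'   `amplitude`, `timescale_s`); `glance()`: fit diagnostics.
#' @export
tidy.smt_bleach <- function(x, ...) {
  tibble::tibble(component = seq_along(x$amplitudes),
                 amplitude = x$amplitudes,
                 timescale_s = x$timescales_s)
}

#' @rdname tidy.smt_bleach
#' @export
glance.smt_bleach <- function(x, ...) {
  d <- x$diagnostics %||% list()
  tibble::tibble(n_components = length(x$amplitudes),
                 residual_norm = d$residual_norm %||% NA_real_,
                 n_points = d$n_points %||% NA_integer_,
                 converged = d$converged %||% NA)
}

#' Tidy a dwell-time distribution
#'
#' @param x A `dwell_dist`.
#' @param ... Unused.
#' @return `tidy()`: the survival support (`t_s`, `survival`, `mass`);
#'   `glance()`: sample counts and the corrected flag.
#' @export
tidy.dwell_dist <- function(x, ...) x$support

#' @rdname tidy.dwell_dist
#' @export
glance.dwell_dist <- function(x, ...) {
  tibble::tibble(n_obs = x$n_obs, n_cells = nrow(x$cell_weights),
                 corrected = x$corrected,
                 t_min_s = min(x$support$t_s), t_max_s = max(x$support$t_s))
}
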