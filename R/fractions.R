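#' Bound / confined / free population fractions
#'
#' Labels the diffusive states of a (filtered) state model by mobility:
#' states with \eqn{D_k \le} `bound_D_max` form the bound class — the
#' slowest of them is called chromatin-bound, any remaining bound-class
#' states are pooled as (nuclear-)confined — and everything faster is free.
#' Fractions are the corresponding sums of mixture weights. The simple
#' bound-versus-unbound split (bound class vs. the rest) is reported
#' alongside.
#'
#' @param model A `pem_fit`, ideally after [filter_states()].
#' @param bound_D_max Mobility ceiling for the bound class in um^2/s
#'   (default 0.03, the order of the apparent mobility floor set by
#'   localization noise for chromatin-bound molecules).
#' @return A one-row tibble of class `fraction_summary` with columns
#'   `fraction_bound` (chromatin-bound), `fraction_confined`,
#'   `fraction_free`, `fraction_bound_class`, `fraction_unbound`,
#'   `bound_D_max` and `n_states_bound_class`.
#' @export
summarize_fractions <- function(model, bound_D_max = 0.03) {
  stopifnot(inherits(model, "pem_fit"), is_scalar(bound_D_max),
            bound_D_max > 0)
  bound_class <- which(model$D <= bound_D_max)
  if (!length(bound_class)) {
    warning("no state has D <= ", bound_D_max,
            " um^2/s; reporting fractions (0, 0, 1)")
    f_bound <- 0; f_conf <- 0
  } else {
    slowest <- bound_class[which.min(model$D[bound_class])]
    f_bound <- model$weights[slowest]
    f_conf <- sum(model$weights[setdiff(bound_class, slowest)])
  }
  f_free <- 1 - f_bound - f_conf
  out <- tibble::tibble(
    fraction_bound = f_bound,
    fraction_confined = f_conf,
    fraction_free = f_free,
    fraction_bound_class = f_bound + f_conf,
    fraction_unbound = f_free,
    bound_D_max = bound_D_max,
    n_states_bound_class = length(bound_class))
  class(out) <- c("fraction_summary", class(out))
  out
}
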