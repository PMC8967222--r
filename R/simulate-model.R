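#' Define a diffusive motion state
#'
#' A motion state is one component of the mixture a nuclear protein explores:
#' freely diffusing, confined to a sub-nuclear region, or chromatin-bound.
#' Confined states move by Brownian motion reflected at a disk of radius
#' `confinement_radius_um` centered on the position where the state was
#' entered; bound states simply carry a small diffusivity.
#'
#' @param label One of `"free"`, `"confined"`, `"bound"`.
#' @param diffusivity_um2_s Diffusion coefficient D in um^2/s (>= 0).
#' @param confinement_radius_um Disk radius L in um; required for (and only
#'   meaningful for) confined states.
#' @param mean_dwell_s Mean residence in this state before switching, in
#'   seconds; `Inf` means the state never exits.
#' @return A `motion_state` list.
#' @export
motion_state <- function(label = c("free", "confined", "bound"),
                         diffusivity_um2_s,
                         confinement_radius_um = NULL,
                         mean_dwell_s = Inf) {
  label <- match.arg(label)
  stopifnot(is_scalar(diffusivity_um2_s), diffusivity_um2_s >= 0)
  if (label == "confined") {
    if (is.null(confinement_radius_um) || !is_scalar(confinement_radius_um) ||
        confinement_radius_um <= 0)
      stop("confined states require a finite confinement_radius_um > 0")
  } else {
    confinement_radius_um <- NULL
  }
  if (!(is.numeric(mean_dwell_s) && length(mean_dwell_s) == 1L &&
        mean_dwell_s > 0))
    stop("mean_dwell_s must be > 0 (possibly Inf)")
  structure(list(label = label,
                 diffusivity_um2_s = as.numeric(diffusivity_um2_s),
                 confinement_radius_um = confinement_radius_um,
                 mean_dwell_s = as.numeric(mean_dwell_s)),
            class = "motion_state")
}

#' Define a multi-state trajectory simulation model
#'
#' Collects the generative assumptions behind the analysis: a set of motion
#' states, their initial occupancies, exponential state switching (uniform
#' choice of destination), static localization noise, and a per-molecule
#' photobleaching hazard. All randomness downstream flows from `seed` through
#' named substreams, so stages can be re-run independently and
#' bit-reproducibly.
#'
#' @param states List of [motion_state()] objects.
#' @param initial_weights Initial state probabilities; must sum to 1 (within
#'   1e-9). Default: uniform.
#' @param localization_sigma_um Static localization precision sigma (s.d. per
#'   axis, um) added to every observed position.
#' @param bleach_rate_s Photobleaching hazard k_b (1/s); 0 disables bleaching.
#' @param n_substeps Sub-steps per exposure window used to integrate the true
#'   motion (>= 10); controls motion-blur accuracy.
#' @param seed Integer master seed.
#' @return A `simulation_model` list.
#' @export
simulation_model <- function(states, initial_weights = NULL,
                             localization_sigma_um = 0.03,
                             bleach_rate_s = 0,
                             n_substeps = 10L,
                             seed = 1L) {
  if (inherits(states, "motion_state")) states <- list(states)
  stopifnot(length(states) >= 1L,
            all(vapply(states, inherits, logical(1), "motion_state")))
  K <- length(states)
  if (is.null(initial_weights)) initial_weights <- rep(1 / K, K)
  if (length(initial_weights) != K || any(initial_weights < 0) ||
      abs(sum(initial_weights) - 1) > 1e-9)
    stop("initial_weights must be ", K, " non-negative values summing to 1")
  stopifnot(is_scalar(localization_sigma_um), localization_sigma_um >= 0,
            is_scalar(bleach_rate_s), bleach_rate_s >= 0,
            is_count(n_substeps, 1))
  if (n_substeps < 10L)
    stop("n_substeps must be >= 10 for adequate motion-blur integration")
  D <- vapply(states, `[[`, numeric(1), "diffusivity_um2_s")
  lab <- vapply(states, `[[`, character(1), "label")
  if (any(lab == "bound") && any(lab != "bound") &&
      max(D[lab == "bound"]) > min(D[lab != "bound"]))
    stop("bound states must have the smallest diffusivity in the model")
  structure(list(states = states,
                 initial_weights = as.numeric(initial_weights),
                 localization_sigma_um = as.numeric(localization_sigma_um),
                 bleach_rate_s = as.numeric(bleach_rate_s),
                 n_substeps = as.integer(n_substeps),
                 seed = as.integer(seed)),
            class = "simulation_model")
}

#' @export
print.simulation_model <- function(x, ...) {
  cat(sprintf("<simulation_model> %d state(s), sigma = %g um, k_b = %g /s\n",
              length(x$states), x$localization_sigma_um, x$bleach_rate_s))
  for (i in seq_along(x$states)) {
    s <- x$states[[i]]
    cat(sprintf("  [%d] %-8s D = %g um^2/s%s, weight %.3g, mean dwell %g s\n",
                i, s$label, s$diffusivity_um2_s,
                if (!is.null(s$confinement_radius_um))
                  sprintf(", L = %g um", s$confinement_radius_um) else "",
                x$initial_weights[i], s$mean_dwell_s))
  }
  invisible(x)
}

#' Photobleaching survival model (mixture of up to three exponentials)
#'
#' Describes fluorophore survival \eqn{S_b(t) = \sum_i A_i e^{-t/\tau_i}}
#' with non-negative amplitudes summing to 1. Used both to generate control
#' dwell samples and (when estimated from a histone H2B control by
#' [fit_triple_exponential()]) to correct observed dwell-time distributions.
#'
#' @param amplitudes Mixture amplitudes A_i (1 to 3 values, >= 0, sum 1).
#' @param timescales_s Time constants tau_i in seconds (> 0, finite).
#' @param diagnostics Optional list of fit diagnostics.
#' @return An object of class `smt_bleach`.
#' @export
bleach_model <- function(amplitudes, timescales_s, diagnostics = NULL) {
  amplitudes <- as.numeric(amplitudes)
  timescales_s <- as.numeric(timescales_s)
  if (length(amplitudes) < 1L || length(amplitudes) > 3L)
    stop("bleach mixture must have 1 to 3 components")
  if (length(timescales_s) != length(amplitudes))
    stop("amplitudes and timescales_s must have equal length")
  if (any(amplitudes < 0)) stop("negative amplitudes are not allowed")
  if (abs(sum(amplitudes) - 1) > 1e-9) stop("amplitudes must sum to 1")
  if (any(!is.finite(timescales_s)) || any(timescales_s <= 0))
    stop("timescales must be finite and > 0 (an unbounded component would ",
         "make observed dwells unbounded)")
  o <- order(timescales_s)
  structure(list(amplitudes = amplitudes[o], timescales_s = timescales_s[o],
                 diagnostics = diagnostics),
            class = "smt_bleach")
}

#' Evaluate a photobleaching survival function
#' @param bleach An [bleach_model()] object.
#' @param t Times (s).
#' @return S_b(t), in (0, 1].
#' @export
bleach_survival <- function(bleach, t) {
  stopifnot(inherits(bleach, "smt_bleach"))
  drop(exp(-outer(t, 1 / bleach$timescales_s)) %*% bleach$amplitudes)
}

#' @export
print.smt_bleach <- function(x, ...) {
  cat("<smt_bleach> S(t) =",
      paste(sprintf("%.3g*exp(-t/%.3g)", x$amplitudes, x$timescales_s),
            collapse = " + "), "\n")
  invisible(x)
}

# Draw n bleach lifetimes from a mixture-of-exponentials survival.
rbleach <- function(n, bleach) {
  comp <- sample.int(length(bleach$amplitudes), n, replace = TRUE,
                     prob = bleach$amplitudes)
  rexp(n, rate = 1 / bleach$timescales_s[comp])
}
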