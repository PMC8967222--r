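#' Fit a triple-exponential photobleaching model to a control dwell sample
#'
#' Least-squares fit of the log empirical survival of a stably bound
#' control (histone H2B imaged under identical acquisition conditions) to a
#' mixture of up to three exponentials,
#' \eqn{S_b(t) = \sum_i A_i e^{-t/\tau_i}}, with constraints
#' \eqn{A_i \ge 0}, \eqn{\sum A_i = 1} (so \eqn{S_b(0) = 1} exactly) and
#' \eqn{\tau_i > 0}. The constraints are enforced by a softmax / log
#' reparametrization and the objective is minimized from `n_starts` seeded
#' starting points to avoid local minima; the best fit is returned.
#'
#' @param control A `dwell_dist` (or `smt_dwell_samples`, pooled
#'   automatically) with at least 100 dwells.
#' @param n_components Number of exponential components (1 to 3).
#' @param n_starts Number of seeded multi-starts.
#' @param seed Integer seed for the starts.
#' @return An [bleach_model()] with fit diagnostics (`residual_norm`,
#'   `n_points`, `converged`) in `$diagnostics`.
#' @export
fit_triple_exponential <- function(control, n_components = 3L,
                                   n_starts = 10L, seed = 1L) {
  if (inherits(control, "smt_dwell_samples")) control <- pool_weighted(control)
  stopifnot(inherits(control, "dwell_dist"), is_count(n_components, 1),
            n_components <= 3L, is_count(n_starts, 1))
  if (control$n_obs < 100L)
    stop("need at least 100 control dwells to estimate photobleaching ",
         "(have ", control$n_obs, ")")
  s <- control$support
  if (nrow(s) < max(3L, 2L * n_components))
    stop("degenerate control sample: only ", nrow(s),
         " distinct dwell value(s)")
  tt <- s$t_s
  ls_emp <- log(s$survival)
  # inverse-variance weights: Var(log S_emp(t)) ~ (1 - S)/(N S), so the
  # sparse far tail does not dominate the least squares
  n_eff <- control$n_obs
  wts <- n_eff * s$survival / pmax(1 - s$survival, 1 / n_eff)
  nc <- n_components

  # A free overall log-scale absorbs the left-truncation of the control
  # sample (dwells shorter than the minimum track length are unobservable,
  # so the empirical survival is conditioned on t >= t_min); the reported
  # amplitudes are renormalized to sum to 1, and the photobleaching
  # correction is invariant to the scale.
  unpack <- function(par) {
    logits <- c(0, par[seq_len(nc - 1)])
    A <- exp(logits) / sum(exp(logits))
    tau <- exp(par[nc:(2 * nc - 1)])
    list(A = A, tau = tau, log_scale = par[2 * nc])
  }
  obj <- function(par) {
    p <- unpack(par)
    mdl <- drop(exp(-outer(tt, 1 / p$tau)) %*% p$A)
    sum(wts * (ls_emp - p$log_scale - log(pmax(mdl, 1e-300)))^2)
  }

  t_lo <- log(max(min(tt) / 2, 1e-4))
  t_hi <- log(max(tt) * 2)
  best <- NULL
  for (st in seq_len(n_starts)) {
    par0 <- with_substream(seed, "bleach_fit", st, {
      c(rnorm(nc - 1, 0, 1), sort(runif(nc, t_lo, t_hi)), 0)
    })
    fit <- tryCatch(
      stats::optim(par0, obj, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best))
    stop("photobleaching fit failed to converge from any start; ",
         "check the control dwell distribution")
  p <- unpack(best$par)
  o <- order(p$tau)
  bleach_model(p$A[o], p$tau[o],
               diagnostics = list(residual_norm = sqrt(best$value),
                                  n_points = length(tt),
                                  converged = best$convergence == 0L,
                                  scale = exp(p$log_scale),
                                  n_starts = n_starts))
}

#' Correct a dwell distribution for photobleaching
#'
#' Divides the observed dwell survival by the fitted photobleaching
#' survival, \eqn{S_{corr}(t) = S_{obs}(t) / S_b(t)}, then renormalizes so
#' the corrected survival is 1 at the smallest observed dwell and projects
#' it onto non-increasing step functions (cumulative minimum), which keeps
#' it a valid survival function in the presence of sampling noise. Before
#' renormalization the correction can only raise the survival
#' (\eqn{S_b \le 1}). Division uses the full fitted mixture survival; set
#' `component` to divide by a single exponential component instead.
#'
#' @param target An uncorrected `dwell_dist`.
#' @param bleach An [bleach_model()], e.g. from
#'   [fit_triple_exponential()].
#' @param component `NULL` (default: full mixture survival) or the index of
#'   the single component to divide by.
#' @return A corrected `dwell_dist` (flag `corrected = TRUE`); its
#'   point masses are recomputed from the corrected survival so downstream
#'   fits treat them as repetition weights.
#' @export
correct_photobleach <- function(target, bleach, component = NULL) {
  stopifnot(inherits(target, "dwell_dist"), inherits(bleach, "smt_bleach"))
  if (target$corrected)
    stop("distribution is already photobleach-corrected")
  s <- target$support
  sb <- if (is.null(component)) {
    bleach_survival(bleach, s$t_s)
  } else {
    stopifnot(is_count(component, 1), component <= length(bleach$amplitudes))
    exp(-s$t_s / bleach$timescales_s[component])
  }
  if (any(sb < 1e-6))
    stop("photobleaching survival falls below 1e-6 at observed dwells; ",
         "restrict the analysis to a shorter time window")
  s_corr <- s$survival / sb
  s_corr <- s_corr / s_corr[1]
  s_corr <- cummin(s_corr)
  mass <- -diff(c(s_corr, 0))
  support <- tibble::tibble(t_s = s$t_s, survival = s_corr, mass = mass)
  obs <- tibble::tibble(cell_id = "(pooled)", dwell_s = s$t_s,
                        weight = mass)
  out <- new_dwell_dist(obs, target$cell_weights, corrected = TRUE,
                        protocol = target$protocol, support = support)
  out$n_obs <- target$n_obs
  out
}
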