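#' Classify trajectories into diffusive states by perturbation EM
#'
#' Fits a K-state mixture over whole trajectories. Under state k a track's
#' per-axis displacement sequence is zero-mean Gaussian with stationary
#' variance \eqn{2 D_k \Delta t + 2\epsilon_k^2}, covariance
#' \eqn{-\epsilon_k^2} between adjacent displacements and zero beyond lag
#' one (the standard moments of blurred single-particle tracking), where
#' \eqn{\epsilon_k^2 = \sigma^2 - D_k t_E / 3} is the effective
#' localization noise of state k: one static localization variance
#' \eqn{\sigma^2} is shared across states (one camera, one noise floor),
#' and the state-dependent motion-blur term \eqn{-D_k t_E/3} follows from
#' it. \eqn{\epsilon_k^2} may legitimately be negative when blur exceeds
#' the static noise; the tridiagonal covariance remains positive definite
#' for any \eqn{D_k \ge 0}, \eqn{\sigma^2 \ge 0} and
#' \eqn{t_E \le \Delta t}.
#'
#' The E-step evaluates the tridiagonal Gaussian likelihood of every track
#' under every state; the M-step updates the mixture weights and
#' re-estimates each \eqn{D_k} from the posterior-weighted lag-0 and lag-1
#' displacement covariances via \eqn{D_k = (Var + 2 Cov) / (2 \Delta t)}
#' (this combination is free of blur and noise bias) and \eqn{\sigma^2}
#' from the pooled lag-1 covariances (\eqn{\sigma^2} is floored at 0 with a
#' warning flag if the estimate is negative). A backtracking safeguard
#' halves the parameter step whenever a proposed update would lower the
#' log-likelihood, so the recorded likelihood trace is non-decreasing
#' within every EM run.
#'
#' After each converged run the diffusivities are perturbed by log-normal
#' factors (s.d. 0.3 in log-space) and EM is re-run, keeping the best
#' likelihood over `n_perturbations` trials and `n_restarts` independent
#' initializations — the "perturbation" in perturbation EM, used to escape
#' local maxima.
#'
#' @param tracks An [track_set()] (fast-acquisition data is the intended
#'   input: short exposures minimize motion blur).
#' @param K Number of diffusive states (>= 1); needs at least `10 * K`
#'   tracks.
#' @param n_restarts Independent initializations.
#' @param n_perturbations Perturbation trials per initialization.
#' @param seed Integer seed; the fit is deterministic given the seed.
#' @param shared_noise Share one static localization variance across states
#'   (default); `FALSE` estimates a per-state noise instead.
#' @param max_iter,tol EM stopping rule: relative log-likelihood change
#'   below `tol` or `max_iter` iterations.
#' @return An object of class `pem_fit` with elements `K`, `weights`,
#'   `D` (um^2/s, ascending), `sigma2` (static localization variance,
#'   um^2), `eps2` (per-state effective noise, um^2), `posteriors` (matrix,
#'   tracks x states), `track_id`, `loglik`, `bic`, `n_disp`, `trace`
#'   (log-likelihood per iteration of the winning run), `converged`,
#'   `sigma2_floored`, and the protocol. Supports [generics::tidy()],
#'   [generics::glance()] and `autoplot()`.
#' @export
fit_pem <- function(tracks, K, n_restarts = 5L, n_perturbations = 10L,
                    seed = 1L, shared_noise = TRUE, max_iter = 500L,
                    tol = 1e-7) {
  stopifnot(inherits(tracks, "smt_tracks"), is_count(K, 1),
            is_count(n_restarts, 1), is_count(n_perturbations, 0))
  gd <- disp_groups(tracks)
  fit_pem_gd(gd, K, n_restarts, n_perturbations, seed, shared_noise,
             max_iter, tol)
}

fit_pem_gd <- function(gd, K, n_restarts, n_perturbations, seed,
                       shared_noise, max_iter, tol) {
  if (gd$n_tracks < 10L * K)
    stop("need at least 10*K = ", 10L * K, " tracks to fit K = ", K,
         " states (have ", gd$n_tracks, ")")
  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- with_substream(seed, "pem_init", r,
                           pem_init(gd, K, jitter = r > 1L))
    run <- run_em(gd, init, shared_noise, max_iter, tol)
    if (is.null(best) || run$loglik > best$loglik) best <- run
    base <- run
    for (j in seq_len(n_perturbations)) {
      pert <- base[c("D", "sigma2", "weights")]
      pert$D <- with_substream(seed, "pem_perturb", (r - 1L) * 1000L + j,
                               base$D * exp(rnorm(K, 0, 0.3)))
      run_j <- run_em(gd, pert, shared_noise, max_iter, tol)
      if (run_j$loglik > base$loglik) base <- run_j
      if (run_j$loglik > best$loglik) best <- run_j
    }
  }
  new_pem_fit(best, gd, K, shared_noise, seed)
}

new_pem_fit <- function(run, gd, K, shared_noise, seed) {
  # canonical order: diffusivities ascending
  o <- order(run$D)
  D <- run$D[o]
  sigma2 <- if (shared_noise) run$sigma2 else run$sigma2[o]
  weights <- run$weights[o]
  gamma <- run$gamma[, o, drop = FALSE]
  rownames(gamma) <- gd$track_id
  tE <- gd$protocol$exposure_s
  p <- if (shared_noise) 2L * K else 3L * K - 1L
  bic <- -2 * run$loglik + p * log(gd$n_disp)
  structure(list(K = K, weights = weights, D = D, sigma2 = sigma2,
                 eps2 = sigma2 - D * tE / 3,
                 shared_noise = shared_noise, posteriors = gamma,
                 track_id = gd$track_id, loglik = run$loglik, bic = bic,
                 n_disp = gd$n_disp, n_tracks = gd$n_tracks,
                 trace = run$trace, converged = run$converged,
                 iterations = run$iterations,
                 sigma2_floored = run$sigma2_floored,
                 protocol = gd$protocol, seed = seed, data = gd),
            class = "pem_fit")
}

# Quantile initialization from per-track apparent diffusivities.
pem_init <- function(gd, K, jitter = FALSE) {
  dt <- gd$protocol$frame_interval_s
  tE <- gd$protocol$exposure_s
  s0 <- unlist(lapply(gd$groups, `[[`, "s0"))[order(unlist(
    lapply(gd$groups, `[[`, "idx")))]
  d_app <- s0 / (4 * gd$n_m * dt)    # mean per-axis sq. disp / (2 dt)
  grp <- if (K == 1L) rep(1L, length(d_app)) else
    cut(rank(d_app, ties.method = "first"), breaks = K, labels = FALSE)
  D <- vapply(seq_len(K), function(k) stats::median(d_app[grp == k]),
              numeric(1))
  D <- pmax(D, 1e-8 * max(max(D), 1e-8))
  if (jitter) D <- D * exp(rnorm(K, 0, 0.3))
  s1 <- unlist(lapply(gd$groups, `[[`, "s1"))
  n1 <- sum(2 * pmax(gd$n_m - 1L, 0L))
  cov1 <- sum(s1) / max(n1, 1L)
  sigma2 <- max(0, -cov1 + mean(D) * tE / 3)
  list(D = sort(D), sigma2 = sigma2, weights = rep(1 / K, K))
}

# One safeguarded EM run from the given starting parameters.
run_em <- function(gd, par, shared_noise, max_iter, tol) {
  dt <- gd$protocol$frame_interval_s
  tE <- gd$protocol$exposure_s
  K <- length(par$D)
  D <- par$D; sigma2 <- par$sigma2; weights <- par$weights
  if (shared_noise) sigma2 <- sigma2[1L]
  e <- em_estep(gd, D, sigma2, weights, dt, tE)
  trace <- e$loglik
  converged <- FALSE
  sigma2_floored <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    m <- em_mstep(gd, e$gamma, dt, tE, shared_noise)
    if (m$collapsed)
      stop("state ", m$which_collapsed, " collapsed (no tracks support it); ",
           "K = ", K, " exceeds the distinguishable states in the data",
           call. = FALSE)
    sigma2_floored <- sigma2_floored || m$sigma2_floored
    # backtracking safeguard: accept only non-decreasing likelihood steps
    step <- 1
    accepted <- FALSE
    for (half in 1:30) {
      Dn <- (1 - step) * D + step * m$D
      sn <- (1 - step) * sigma2 + step * m$sigma2
      wn <- (1 - step) * weights + step * m$weights
      e_new <- em_estep(gd, Dn, sn, wn, dt, tE)
      if (e_new$loglik >= e$loglik - 1e-12 * abs(e$loglik)) {
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) {           # no improving step: at a stationary point
      converged <- TRUE
      break
    }
    improved <- e_new$loglik - e$loglik
    D <- Dn; sigma2 <- sn; weights <- wn
    e <- e_new
    trace <- c(trace, e$loglik)
    if (abs(improved) < tol * abs(e$loglik)) {
      converged <- TRUE
      break
    }
  }
  list(D = D, sigma2 = sigma2, weights = weights, gamma = e$gamma,
       loglik = e$loglik, trace = trace, converged = converged,
       iterations = iter, sigma2_floored = sigma2_floored)
}

em_estep <- function(gd, D, sigma2, weights, dt, tE) {
  eps2 <- sigma2 - D * tE / 3
  ll <- state_loglik_matrix(gd, D, eps2, dt)
  lw <- sweep(ll, 2L, log(pmax(weights, 1e-300)), `+`)
  mx <- apply(lw, 1L, max)
  lse <- mx + log(rowSums(exp(lw - mx)))
  gamma <- exp(lw - lse)
  list(gamma = gamma, loglik = sum(lse))
}

em_mstep <- function(gd, gamma, dt, tE, shared_noise) {
  K <- ncol(gamma)
  M <- nrow(gamma)
  s0 <- numeric(M); s1 <- numeric(M)
  for (g in gd$groups) { s0[g$idx] <- g$s0; s1[g$idx] <- g$s1 }
  n_m <- gd$n_m
  wsum <- colSums(gamma)
  if (any(wsum < 1e-10 * M)) {
    return(list(collapsed = TRUE, which_collapsed = which.min(wsum)))
  }
  S0 <- drop(crossprod(gamma, s0))
  N0 <- drop(crossprod(gamma, 2 * n_m))
  S1 <- drop(crossprod(gamma, s1))
  N1 <- drop(crossprod(gamma, 2 * pmax(n_m - 1L, 0L)))
  var_k <- S0 / N0
  cov_k <- ifelse(N1 > 0, S1 / N1, 0)
  D <- pmax((var_k + 2 * cov_k) / (2 * dt), 0)
  sig2_k <- -cov_k + D * tE / 3
  if (shared_noise) {
    sigma2_raw <- if (sum(N1) > 0) sum(N1 * sig2_k) / sum(N1) else 0
  } else {
    sigma2_raw <- sig2_k
  }
  sigma2 <- pmax(sigma2_raw, 0)
  list(D = D, sigma2 = sigma2, weights = wsum / M,
       collapsed = FALSE, sigma2_floored = any(sigma2_raw < -1e-12))
}

#' @export
print.pem_fit <- function(x, ...) {
  cat(sprintf(
    "<pem_fit> K = %d states, %d tracks, %d displacements\n",
    x$K, x$n_tracks, x$n_disp))
  cat(sprintf("  logLik = %.2f, BIC = %.2f, %s after %d iterations\n",
              x$loglik, x$bic,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  tbl <- data.frame(state = seq_len(x$K),
                    D_um2_s = signif(x$D, 4),
                    weight = signif(x$weights, 4),
                    eps2_um2 = signif(x$eps2, 4))
  print(tbl, row.names = FALSE)
  cat(sprintf("  static localization variance sigma^2 = %s um^2%s\n",
              paste(signif(x$sigma2, 4), collapse = ", "),
              if (x$sigma2_floored) " (floored at 0)" else ""))
  invisible(x)
}
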