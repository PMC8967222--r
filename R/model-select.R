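#' Choose the number of diffusive states by BIC
#'
#' Fits [fit_pem()] for each candidate K and selects the model minimizing
#' \eqn{BIC = -2 \ln L + p \ln n}, where n is the total number of
#' displacements (the likelihood's observation unit) and p = 2K for the
#' shared-noise model (K - 1 free weights, K diffusivities, one shared
#' noise). Fit failures for individual K (e.g. collapsed states when K
#' exceeds the distinguishable support) are recorded and skipped, and the
#' best feasible model is returned as long as at least one K succeeds.
#'
#' @inheritParams fit_pem
#' @param K_range Candidate state counts (e.g. `1:4`).
#' @return An object of class `pem_selection`: a list with `best` (the
#'   winning `pem_fit`), `bic_table` (tibble with one row per K) and `fits`
#'   (all successful fits, named by K).
#' @export
select_model <- function(tracks, K_range = 1:4, n_restarts = 5L,
                         n_perturbations = 10L, seed = 1L,
                         shared_noise = TRUE, max_iter = 500L, tol = 1e-7) {
  stopifnot(length(K_range) >= 1L, all(K_range >= 1L))
  gd <- disp_groups(tracks)
  fits <- list()
  rows <- list()
  for (K in sort(unique(as.integer(K_range)))) {
    res <- tryCatch(
      fit_pem_gd(gd, K, n_restarts, n_perturbations, seed, shared_noise,
                 max_iter, tol),
      error = function(e) e)
    if (inherits(res, "error")) {
      rows[[as.character(K)]] <- tibble::tibble(
        K = K, loglik = NA_real_, bic = NA_real_, converged = NA,
        error = conditionMessage(res))
    } else {
      fits[[as.character(K)]] <- res
      rows[[as.character(K)]] <- tibble::tibble(
        K = K, loglik = res$loglik, bic = res$bic,
        converged = res$converged, error = NA_character_)
    }
  }
  bic_table <- dplyr::bind_rows(rows)
  if (!length(fits))
    stop("no candidate K could be fitted; smallest error: ",
         bic_table$error[1])
  best_K <- bic_table$K[which.min(bic_table$bic)]
  structure(list(best = fits[[as.character(best_K)]],
                 bic_table = bic_table, fits = fits),
            class = "pem_selection")
}

#' @export
print.pem_selection <- function(x, ...) {
  cat("<pem_selection> BIC over candidate state counts\n")
  print(as.data.frame(x$bic_table), row.names = FALSE)
  cat("selected K =", x$best$K, "\n")
  invisible(x)
}

#' Discard minor diffusive states
#'
#' Applies the population filter used in SMT state classification: a
#' state's population is the fraction of tracks whose posterior probability
#' for that state exceeds `posterior_threshold`; states below
#' `min_population` are removed, the remaining weights renormalized, and
#' the posteriors recomputed under the reduced model (the diffusivities and
#' noise of the surviving states are kept; set `refit = TRUE` to re-run EM
#' on the reduced state set instead).
#'
#' @param model A `pem_fit`.
#' @param min_population Minimum population a state needs to survive
#'   (default 0.05).
#' @param posterior_threshold Posterior probability a track must exceed to
#'   count towards a state's population (default 0.6).
#' @param refit Re-run EM after removal instead of renormalizing.
#' @return A `pem_fit` with the surviving states.
#' @export
filter_states <- function(model, min_population = 0.05,
                          posterior_threshold = 0.6, refit = FALSE) {
  stopifnot(inherits(model, "pem_fit"))
  pop <- state_populations(model, posterior_threshold)
  keep <- which(pop >= min_population)
  if (!length(keep))
    stop("the population filter would remove all ", model$K, " states; ",
         "lower min_population or posterior_threshold")
  if (length(keep) == model$K) return(model)
  gd <- model$data
  if (refit) {
    return(fit_pem_gd(gd, length(keep), n_restarts = 1L,
                      n_perturbations = 0L, seed = model$seed,
                      shared_noise = model$shared_noise,
                      max_iter = 500L, tol = 1e-7))
  }
  D <- model$D[keep]
  sigma2 <- if (model$shared_noise) model$sigma2 else model$sigma2[keep]
  weights <- model$weights[keep] / sum(model$weights[keep])
  e <- em_estep(gd, D, sigma2, weights, gd$protocol$frame_interval_s,
                gd$protocol$exposure_s)
  out <- new_pem_fit(list(D = D, sigma2 = sigma2, weights = weights,
                          gamma = e$gamma, loglik = e$loglik,
                          trace = e$loglik, converged = model$converged,
                          iterations = 0L,
                          sigma2_floored = model$sigma2_floored),
                     gd, length(keep), model$shared_noise, model$seed)
  out$filtered <- list(min_population = min_population,
                       posterior_threshold = posterior_threshold,
                       removed_states = setdiff(seq_len(model$K), keep),
                       populations_before = pop)
  out
}

#' Per-state track populations by posterior threshold
#'
#' @param model A `pem_fit`.
#' @param posterior_threshold Threshold a track's posterior must exceed.
#' @return Numeric vector: fraction of tracks exceeding the threshold per
#'   state.
#' @export
state_populations <- function(model, posterior_threshold = 0.6) {
  stopifnot(inherits(model, "pem_fit"))
  colMeans(model$posteriors > posterior_threshold)
}
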