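#' Run the full SMT analysis pipeline from a configuration
#'
#' Executes the requested stages in order — `simulate` (fast-acquisition
#' trajectories), `states` (pEM + BIC classification, population filter,
#' posterior-weighted MSDs, bound/confined/free fractions), `dwell`
#' (slow-acquisition residence analysis with an H2B-like bleaching control)
#' and `report` — writing each stage's artifacts (CSV/JSON) into
#' `out_dir`. A stage failure leaves a `<stage>.failed` marker file and
#' halts with the stage name. Identical configuration and seed give
#' identical numeric outputs.
#'
#' @param config An `smt_config` from [read_run_config()], or a path to a
#'   YAML configuration file.
#' @return A run report (list of class `smt_run_report`): per-stage
#'   outputs, package version, seed, wall times and warnings; also written
#'   to `out_dir/run_report.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "smt_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(package = "tidysmt",
                 version = as.character(utils::packageVersion("tidysmt")),
                 r_version = R.version.string,
                 seed = config$seed,
                 config = unclass(config),
                 stages = list(), warnings = character())
  state <- new.env(parent = emptyenv())
  for (stage in config$stages) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(
      withCallingHandlers(
        run_stage(stage, config, state, out_dir),
        warning = function(w) {
          report$warnings <<- c(report$warnings,
                                paste0(stage, ": ", conditionMessage(w)))
          invokeRestart("muffleWarning")
        }),
      error = function(e) e)
    if (inherits(res, "error")) {
      writeLines(conditionMessage(res),
                 file.path(out_dir, paste0(stage, ".failed")))
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(res),
           call. = FALSE)
    }
    report$stages[[stage]] <- c(res,
                                list(elapsed_s = round(
                                  proc.time()[["elapsed"]] - t0, 3)))
  }
  class(report) <- "smt_run_report"
  jsonlite::write_json(unclass(report),
                       file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report
}

run_stage <- function(stage, config, state, out_dir) {
  switch(stage,
         simulate = stage_simulate(config, state, out_dir),
         states = stage_states(config, state, out_dir),
         dwell = stage_dwell(config, state, out_dir),
         report = list(note = "report assembled"),
         stop("unknown stage: ", stage))
}

stage_simulate <- function(config, state, out_dir) {
  sc <- config$simulate %||% list()
  protocol <- as_protocol(sc$protocol %||% "fast")
  if (!is.null(sc$n_frames))
    protocol <- acquisition_protocol(protocol$frame_interval_s,
                                     protocol$exposure_s,
                                     protocol$pixel_size_um,
                                     sc$n_frames, protocol$label)
  blocks <- sc$states %||% list(
    list(label = "bound", diffusivity_um2_s = 0.005, mean_dwell_s = Inf),
    list(label = "free", diffusivity_um2_s = 0.5, mean_dwell_s = Inf))
  states <- purrr::map(blocks, function(b) {
    motion_state(b$label, b$diffusivity_um2_s,
                 b$confinement_radius_um %||% NULL,
                 b$mean_dwell_s %||% Inf)
  })
  model <- simulation_model(
    states,
    initial_weights = sc$initial_weights %||% NULL,
    localization_sigma_um = sc$localization_sigma_um %||% 0.03,
    bleach_rate_s = sc$bleach_rate_s %||% 0,
    seed = substream_seed(config$seed, "pipeline_sim", 0L))
  sim <- simulate_tracks(model, protocol, sc$n_tracks %||% 500L,
                         region_um = sc$region_um %||% NULL)
  write_tracks(sim$tracks, file.path(out_dir, "tracks_fast.csv"))
  readr::write_csv(sim$truth$displacements,
                   file.path(out_dir, "ground_truth.csv"))
  state$sim <- sim
  list(n_tracks = dplyr::n_distinct(sim$tracks$track_id),
       outputs = c("tracks_fast.csv", "ground_truth.csv"))
}

stage_states <- function(config, state, out_dir) {
  if (is.null(state$sim))
    stop("the 'states' stage needs tracks from the 'simulate' stage")
  pc <- config$states %||% list()
  sel <- select_model(state$sim$tracks,
                      K_range = pc$k_range %||% 1:4,
                      n_restarts = pc$n_restarts %||% 2L,
                      n_perturbations = pc$n_perturbations %||% 3L,
                      seed = substream_seed(config$seed, "pipeline_pem", 0L))
  filt <- filter_states(sel$best,
                        min_population = pc$min_population %||% 0.05,
                        posterior_threshold = pc$posterior_threshold %||% 0.6)
  msd <- state_msd(filt, max_lag = pc$max_lag %||% 5L)
  fr <- summarize_fractions(filt, bound_D_max = pc$bound_D_max %||% 0.03)
  jsonlite::write_json(
    list(K = filt$K, weights = filt$weights, D_um2_s = filt$D,
         sigma2_um2 = filt$sigma2, eps2_um2 = filt$eps2,
         loglik = filt$loglik, bic = filt$bic,
         bic_table = sel$bic_table, converged = filt$converged),
    file.path(out_dir, "state_model.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  readr::write_csv(posterior_table(filt),
                   file.path(out_dir, "posteriors.csv"))
  readr::write_csv(tibble::as_tibble(msd), file.path(out_dir, "msd.csv"))
  jsonlite::write_json(as.list(tibble::as_tibble(fr)),
                       file.path(out_dir, "fractions.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  state$model <- filt
  list(selected_K = filt$K,
       outputs = c("state_model.json", "posteriors.csv", "msd.csv",
                   "fractions.json"))
}

stage_dwell <- function(config, state, out_dir) {
  dc <- config$dwell %||% list()
  protocol <- as_protocol(dc$protocol %||% "slow")
  if (!is.null(dc$n_frames))
    protocol <- acquisition_protocol(protocol$frame_interval_s,
                                     protocol$exposure_s,
                                     protocol$pixel_size_um,
                                     dc$n_frames, protocol$label)
  rs <- dc$residence %||% list(type = "power_law", alpha = 2,
                               t_min_s = 0.2)
  law <- switch(rs$type %||% "power_law",
                power_law = residence_power_law(rs$alpha %||% 2,
                                                rs$t_min_s %||% 0.2),
                exponential = residence_exponential(rs$mean_s %||% 2),
                stop("unknown residence type: ", rs$type))
  bl <- dc$bleach %||% list(amplitudes = c(0.5, 0.3, 0.2),
                            timescales_s = c(0.5, 2, 10))
  bleach_true <- bleach_model(bl$amplitudes, bl$timescales_s)
  sigma <- dc$localization_sigma_um %||% 0.03

  target <- simulate_residence_tracks(
    protocol, dc$n_tracks %||% 3000L, law, bleach = bleach_true,
    localization_sigma_um = sigma, n_cells = 5L,
    seed = substream_seed(config$seed, "pipeline_dwell", 1L))
  control <- simulate_residence_tracks(
    protocol, dc$control_n_tracks %||% 3000L, residence_stable(),
    bleach = bleach_true, localization_sigma_um = sigma, n_cells = 5L,
    seed = substream_seed(config$seed, "pipeline_dwell", 2L))

  br <- dc$bound_radius_um %||% 0.2
  mbf <- dc$min_bound_frames %||% 2L
  dw_t <- pool_weighted(extract_dwell_times(target$tracks, br, mbf))
  dw_c <- pool_weighted(extract_dwell_times(control$tracks, br, mbf))
  bleach_fit <- fit_triple_exponential(
    dw_c, seed = substream_seed(config$seed, "pipeline_dwell", 3L))
  corr <- correct_photobleach(dw_t, bleach_fit)
  pl <- fit_power_law(corr, t_min = dc$t_min_fit_s %||% NULL)

  readr::write_csv(dw_t$support, file.path(out_dir, "survival_raw.csv"))
  readr::write_csv(corr$support,
                   file.path(out_dir, "survival_corrected.csv"))
  jsonlite::write_json(
    list(amplitudes = bleach_fit$amplitudes,
         timescales_s = bleach_fit$timescales_s,
         diagnostics = bleach_fit$diagnostics),
    file.path(out_dir, "bleach_model.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(as.list(tibble::as_tibble(pl)),
                       file.path(out_dir, "power_law.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  state$power_law <- pl
  list(alpha = pl$alpha, n_dwells = dw_t$n_obs,
       outputs = c("survival_raw.csv", "survival_corrected.csv",
                   "bleach_model.json", "power_law.json"))
}

#' Posterior probabilities as a tidy table
#'
#' @param model A `pem_fit`.
#' @return A tibble with `track_id`, `state`, `posterior`.
#' @export
posterior_table <- function(model) {
  stopifnot(inherits(model, "pem_fit"))
  g <- model$posteriors
  tibble::tibble(track_id = rep(model$track_id, times = ncol(g)),
                 state = rep(seq_len(ncol(g)), each = nrow(g)),
                 posterior = as.vector(g))
}

#' @export
print.smt_run_report <- function(x, ...) {
  cat("<smt_run_report> seed", x$seed, "\n")
  for (nm in names(x$stages)) {
    cat(sprintf("  %-9s %6.2f s  %s\n", nm, x$stages[[nm]]$elapsed_s,
                paste(x$stages[[nm]]$outputs, collapse = ", ")))
  }
  if (length(x$warnings)) cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}
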