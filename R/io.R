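#' Read and write track tables
#'
#' Tracks are stored as plain CSV with header
#' `track_id,frame,x_um,y_um[,cell_id]`. Coordinates are serialized at full
#' precision, so a write/read round trip reproduces the track set exactly.
#' `read_tracks()` validates the table: missing columns, non-consecutive
#' frames within a track and non-finite coordinates each produce a distinct
#' error naming the offender.
#'
#' @param tracks An [track_set()].
#' @param path CSV file path.
#' @param protocol Protocol to attach on read (object or `"fast"`/`"slow"`).
#' @return `read_tracks()` returns an [track_set()]; `write_tracks()`
#'   returns `path` invisibly.
#' @export
write_tracks <- function(tracks, path) {
  stopifnot(inherits(tracks, "smt_tracks"))
  cols <- intersect(c("track_id", "frame", "x_um", "y_um", "cell_id"),
                    names(tracks))
  readr::write_csv(tibble::as_tibble(tracks)[cols], path)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path, protocol) {
  protocol <- as_protocol(protocol)
  # base read.csv: correctly rounded double parsing, so the write/read
  # round trip is bit-exact
  tbl <- tibble::as_tibble(utils::read.csv(path))
  required <- c("track_id", "frame", "x_um", "y_um")
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols))
    stop("track file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (any(!is.finite(tbl$x_um)) || any(!is.finite(tbl$y_um)))
    stop("track file ", path, " contains non-finite coordinates")
  track_set(tbl, protocol, provenance = list(source = path))
}

#' Read a localization table
#'
#' Plain CSV with header `frame,x_px,y_px[,intensity]`.
#' @param path CSV file path.
#' @return A tibble of localizations in pixels.
#' @export
read_localizations <- function(path) {
  tbl <- tibble::as_tibble(utils::read.csv(path))
  missing_cols <- setdiff(c("frame", "x_px", "y_px"), names(tbl))
  if (length(missing_cols))
    stop("localization file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  tbl
}

#' Read and validate a pipeline run configuration
#'
#' Reads a YAML configuration for [run_pipeline()] and rejects unknown keys
#' anywhere in the hierarchy before any computation happens.
#'
#' @param path YAML file path.
#' @return A validated config list of class `smt_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
}

config_schema <- function() {
  list(
    seed = NULL, out_dir = NULL, stages = NULL,
    simulate = list(
      protocol = NULL, n_frames = NULL, n_tracks = NULL,
      states = list(label = NULL, diffusivity_um2_s = NULL,
                    confinement_radius_um = NULL, mean_dwell_s = NULL),
      initial_weights = NULL, localization_sigma_um = NULL,
      bleach_rate_s = NULL, region_um = NULL),
    states = list(k_range = NULL, n_restarts = NULL, n_perturbations = NULL,
                  bound_D_max = NULL, min_population = NULL,
                  posterior_threshold = NULL, max_lag = NULL),
    dwell = list(
      protocol = NULL, n_frames = NULL, n_tracks = NULL,
      control_n_tracks = NULL,
      residence = list(type = NULL, alpha = NULL, t_min_s = NULL,
                       mean_s = NULL),
      bleach = list(amplitudes = NULL, timescales_s = NULL),
      bound_radius_um = NULL, min_bound_frames = NULL, t_min_fit_s = NULL,
      localization_sigma_um = NULL))
}

validate_config <- function(cfg) {
  check_keys <- function(x, schema, where) {
    unknown <- setdiff(names(x), names(schema))
    if (length(unknown))
      stop("unknown configuration key(s) ", where,
           paste(unknown, collapse = ", "))
    for (nm in names(x)) {
      if (is.list(schema[[nm]]) && is.list(x[[nm]]) &&
          !is.null(names(schema[[nm]]))) {
        # 'states' under simulate is a list of state blocks
        if (nm == "states" && is.null(names(x[[nm]]))) {
          for (blk in x[[nm]]) check_keys(blk, schema[[nm]],
                                          paste0("in simulate.states: "))
        } else {
          check_keys(x[[nm]], schema[[nm]], paste0("in ", nm, ": "))
        }
      }
    }
  }
  check_keys(cfg, config_schema(), "at top level: ")
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$out_dir)) stop("configuration must set out_dir")
  if (is.null(cfg$stages))
    cfg$stages <- c("simulate", "states", "dwell", "report")
  bad <- setdiff(cfg$stages, c("simulate", "states", "dwell", "report"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  structure(cfg, class = "smt_config")
}
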