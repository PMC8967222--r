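#' Bundle trajectories with their acquisition protocol
#'
#' A track set is a tibble of localizations — one row per (track, frame) with
#' columns `track_id`, `frame`, `x_um`, `y_um` and optionally `cell_id` —
#' carrying the acquisition protocol as an attribute. It is the exchange
#' object between simulation, linking, state classification and residence
#' analysis. All coordinates are in micrometers; `frame` is 1-based and
#' strictly increasing with no gaps within a track.
#'
#' @param data A data frame with columns `track_id`, `frame`, `x_um`, `y_um`
#'   (and optionally `cell_id`).
#' @param protocol An [acquisition_protocol()] (or `"fast"`/`"slow"`).
#' @param provenance Optional named list recording how the tracks were made
#'   (source, seed, parameters).
#' @param min_track_len Minimum track length to enforce (default 2).
#' @return A tibble of class `smt_tracks`.
#' @export
track_set <- function(data, protocol, provenance = list(),
                      min_track_len = 2L) {
  protocol <- as_protocol(protocol)
  data <- tibble::as_tibble(data)
  required <- c("track_id", "frame", "x_um", "y_um")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols))
    stop("track table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  if (any(!is.finite(data$x_um)) || any(!is.finite(data$y_um)))
    stop("track table contains non-finite coordinates")
  data <- dplyr::arrange(data, .data$track_id, .data$frame)
  validate_track_frames(data)
  len <- dplyr::count(data, .data$track_id)
  if (any(len$n < min_track_len))
    stop("tracks shorter than min_track_len present: ",
         paste(utils::head(len$track_id[len$n < min_track_len], 5),
               collapse = ", "))
  structure(data,
            class = c("smt_tracks", class(tibble::tibble())),
            protocol = protocol,
            provenance = provenance)
}

validate_track_frames <- function(data) {
  bad <- data |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(ok = all(diff(.data$frame) == 1L), .groups = "drop") |>
    dplyr::filter(!.data$ok)
  if (nrow(bad))
    stop("track(s) with non-consecutive frames (gap closing is not ",
         "performed): ", paste(utils::head(bad$track_id, 5), collapse = ", "))
  invisible(TRUE)
}

#' Extract the protocol attached to a track set
#' @param x An `smt_tracks` object.
#' @return The `smt_protocol`.
#' @export
protocol_of <- function(x) {
  p <- attr(x, "protocol", exact = TRUE)
  if (is.null(p)) stop("object carries no acquisition protocol")
  p
}

#' @export
print.smt_tracks <- function(x, ...) {
  p <- attr(x, "protocol", exact = TRUE)
  n_tracks <- dplyr::n_distinct(x$track_id)
  cat(sprintf("<smt_tracks> %d tracks, %d localizations", n_tracks, nrow(x)))
  if (!is.null(p)) cat(sprintf(" [%s protocol, dt = %g ms]",
                               p$label, 1e3 * p$frame_interval_s))
  cat("\n")
  NextMethod()
}

# Track lengths (positions per track), as a tibble.
track_lengths <- function(tracks) {
  dplyr::count(tibble::as_tibble(tracks), .data$track_id, name = "n_pos")
}
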