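#' Link per-frame localizations into trajectories
#'
#' Frame-to-frame linking with the standard SMT rules: between consecutive
#' frames an optimal bipartite assignment minimizes the total squared
#' displacement among candidate pairs closer than `max_disp_px` pixels;
#' unmatched detections start new tracks; a track ends as soon as it is
#' unmatched (no gap closing); tracks shorter than `min_track_len` frames
#' are discarded. The default gates follow common practice for nuclear SMT:
#' 4 pixels for slow (5 Hz) movies and 6 pixels for fast (83 Hz) movies,
#' with a minimum length of 2 frames. Among equal-cost assignments the
#' pairing reachable first in input row order is kept (deterministic
#' tie-break).
#'
#' @param locs A data frame of localizations with columns `frame` and either
#'   `x_px`, `y_px` (pixels) or `x_um`, `y_um` (micrometers, converted with
#'   the protocol); optional `intensity`.
#' @param protocol Acquisition protocol (or `"fast"`/`"slow"`); supplies the
#'   pixel size and the default gate.
#' @param max_disp_px Maximum frame-to-frame displacement in pixels; default
#'   4 when the frame interval is >= 100 ms, 6 otherwise.
#' @param min_track_len Minimum track length in frames (>= 2).
#' @return An [track_set()] with coordinates in micrometers.
#' @export
link_tracks <- function(locs, protocol, max_disp_px = NULL,
                        min_track_len = 2L) {
  protocol <- as_protocol(protocol)
  locs <- tibble::as_tibble(locs)
  if (!"frame" %in% names(locs)) stop("locs must have a 'frame' column")
  if (all(c("x_px", "y_px") %in% names(locs))) {
    x <- locs$x_px; y <- locs$y_px
  } else if (all(c("x_um", "y_um") %in% names(locs))) {
    x <- um_to_px(protocol, locs$x_um)
    y <- um_to_px(protocol, locs$y_um)
  } else {
    stop("locs must have columns x_px,y_px or x_um,y_um")
  }
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("localizations contain non-finite coordinates")
  max_disp_px <- max_disp_px %||%
    (if (protocol$frame_interval_s >= 0.1) 4 else 6)
  stopifnot(is_scalar(max_disp_px), max_disp_px > 0,
            is_count(min_track_len, 2))

  dup <- duplicated(data.frame(f = locs$frame, x = x, y = y))
  if (any(dup))
    stop("duplicate (frame, position) localization rows in frame(s) ",
         paste(unique(locs$frame[dup]), collapse = ", "))

  ord <- order(locs$frame, seq_len(nrow(locs)))   # stable: keep input order
  frame <- as.integer(locs$frame[ord]); x <- x[ord]; y <- y[ord]

  frames <- sort(unique(frame))
  idx_by_frame <- split(seq_along(frame), frame)[as.character(frames)]

  track_of <- integer(length(frame))
  next_id <- 0L
  # tracks active at the previous frame: localization indices of their ends
  prev_ends <- integer(0)
  prev_frame <- NA_integer_
  for (fi in seq_along(frames)) {
    cur <- idx_by_frame[[fi]]
    consecutive <- !is.na(prev_frame) && frames[fi] == prev_frame + 1L
    links <- if (consecutive && length(prev_ends)) {
      assign_frame_pair(x[prev_ends], y[prev_ends], x[cur], y[cur],
                        max_disp_px)
    } else {
      rep(NA_integer_, length(cur))
    }
    for (k in seq_along(cur)) {
      if (!is.na(links[k])) {
        track_of[cur[k]] <- track_of[prev_ends[links[k]]]
      } else {
        next_id <- next_id + 1L
        track_of[cur[k]] <- next_id
      }
    }
    prev_ends <- cur
    prev_frame <- frames[fi]
  }

  px <- protocol$pixel_size_um
  tbl <- tibble::tibble(track_id = track_of, frame = frame,
                        x_um = x * px, y_um = y * px)
  keep <- dplyr::count(tbl, .data$track_id) |>
    dplyr::filter(.data$n >= min_track_len)
  tbl <- dplyr::semi_join(tbl, keep, by = "track_id") |>
    dplyr::arrange(.data$track_id, .data$frame)
  if (nrow(tbl) == 0L)
    stop("no track reached min_track_len = ", min_track_len)
  # relabel track ids consecutively in order of first appearance
  tbl$track_id <- match(tbl$track_id, unique(tbl$track_id))
  track_set(tbl, protocol,
            provenance = list(source = "link_tracks",
                              max_disp_px = max_disp_px,
                              min_track_len = as.integer(min_track_len)),
            min_track_len = min_track_len)
}

# Optimal gated assignment between the ends of live tracks (1..n1) and the
# detections of the next frame (1..n2). Returns, for each detection, the
# index of the matched track end or NA. Uses a square Hungarian problem with
# birth/death dummies priced at gate^2, so cardinality-maximal gated
# matchings always win and ties resolve by input order.
assign_frame_pair <- function(x1, y1, x2, y2, gate) {
  n1 <- length(x1); n2 <- length(x2)
  d2 <- outer(x1, x2, `-`)^2 + outer(y1, y2, `-`)^2
  big <- 4 * gate^2 + 1
  d2[d2 > gate^2] <- big
  p <- gate^2
  n <- n1 + n2
  cost <- matrix(big, n, n)
  cost[seq_len(n1), seq_len(n2)] <- d2
  if (n1) cost[cbind(seq_len(n1), n2 + seq_len(n1))] <- p      # track death
  if (n2) cost[cbind(n1 + seq_len(n2), seq_len(n2))] <- p      # track birth
  cost[n1 + seq_len(n2), n2 + seq_len(n1)] <- 0                # dummy-dummy
  asg <- solve_assignment(cost)                                # row -> col
  out <- rep(NA_integer_, n2)
  for (i in seq_len(n1)) {
    j <- asg[i]
    if (j <= n2 && d2[i, j] < big) out[j] <- i
  }
  out
}

# Hungarian algorithm (shortest augmenting path formulation) for a square
# cost matrix; returns the column assigned to each row. O(n^3).
solve_assignment <- function(a) {
  n <- nrow(a)
  stopifnot(ncol(a) == n)
  INF <- Inf
  u <- numeric(n + 1L)
  v <- numeric(n + 1L)          # v[1] is the virtual column
  p <- integer(n + 1L)          # p[j+1] = row matched to column j (0 = none)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(INF, n)
    way <- integer(n)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      free_j <- which(!used[-1L])
      cur <- a[i0, free_j] - u[i0 + 1L] - v[free_j + 1L]
      upd <- cur < minv[free_j]
      if (any(upd)) {
        minv[free_j[upd]] <- cur[upd]
        way[free_j[upd]] <- j0
      }
      j1 <- free_j[which.min(minv[free_j])]
      delta <- minv[j1]
      used_j <- which(used) - 1L               # columns 0..n already used
      u[p[used_j + 1L] + 1L] <- u[p[used_j + 1L] + 1L] + delta
      v[used_j + 1L] <- v[used_j + 1L] - delta
      minv[free_j] <- minv[free_j] - delta
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  asg <- integer(n)
  for (j in seq_len(n)) if (p[j + 1L] > 0L) asg[p[j + 1L]] <- j
  asg
}
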