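#' Render trajectories into a synthetic image stack
#'
#' Draws every live emitter of every frame as a 2D Gaussian point-spread
#' function integrated over the pixel grid, adds a constant background, and
#' applies Poisson shot noise. Positions are converted from micrometers to
#' pixels with the track set's protocol; pixel centers sit at integer
#' coordinates starting at 1.
#'
#' @param tracks An [track_set()].
#' @param psf_sigma_px PSF standard deviation in pixels (> 0).
#' @param photons_per_spot Expected photon count per emitter per frame.
#' @param background Expected background photons per pixel.
#' @param image_shape `c(n_row, n_col)` in pixels.
#' @param n_frames Number of frames to render (default: last frame present).
#' @param seed Integer seed for the shot noise.
#' @return A numeric array `[n_row, n_col, n_frames]` of photon counts.
#' @export
render_frames <- function(tracks, psf_sigma_px, photons_per_spot = 500,
                          background = 5, image_shape = c(64L, 64L),
                          n_frames = NULL, seed = 1L) {
  stopifnot(inherits(tracks, "smt_tracks"), is_scalar(psf_sigma_px),
            psf_sigma_px > 0, is_scalar(photons_per_spot),
            photons_per_spot >= 0, is_scalar(background), background >= 0,
            length(image_shape) == 2L)
  protocol <- protocol_of(tracks)
  tbl <- tibble::as_tibble(tracks) |>
    dplyr::mutate(x_px = um_to_px(protocol, .data$x_um),
                  y_px = um_to_px(protocol, .data$y_um))
  nr <- as.integer(image_shape[1]); nc <- as.integer(image_shape[2])
  if (nrow(tbl)) {
    oob <- tbl$x_px < 0.5 | tbl$x_px > nc + 0.5 |
      tbl$y_px < 0.5 | tbl$y_px > nr + 0.5
    if (any(oob))
      stop(sum(oob), " localization(s) fall outside the image after pixel ",
           "conversion; enlarge image_shape or shift the tracks")
  }
  n_frames <- as.integer(n_frames %||% max(tbl$frame, 1L))
  withr::with_seed(substream_seed(seed, "render", 0L), {
    stack <- array(0, dim = c(nr, nc, n_frames))
    for (f in seq_len(n_frames)) {
      img <- matrix(background, nr, nc)
      spots <- tbl[tbl$frame == f, ]
      for (i in seq_len(nrow(spots))) {
        img <- img + photons_per_spot *
          gauss_spot(nr, nc, spots$x_px[i], spots$y_px[i], psf_sigma_px)
      }
      stack[, , f] <- matrix(rpois(nr * nc, img), nr, nc)
    }
    stack
  })
}

# Unit-mass Gaussian integrated over the pixel grid (rows = y, cols = x).
gauss_spot <- function(nr, nc, x, y, s) {
  px <- diff(stats::pnorm(seq(0.5, nc + 0.5), mean = x, sd = s))
  py <- diff(stats::pnorm(seq(0.5, nr + 0.5), mean = y, sd = s))
  outer(py, px)
}

#' Write / read an image stack as multi-page TIFF
#'
#' Stores photon-count stacks as 16-bit multi-page TIFF. Counts are clipped
#' to the 16-bit range on write.
#'
#' @param stack Numeric array `[n_row, n_col, n_frames]`.
#' @param path Output path.
#' @return `write_frames_tiff()` returns `path` invisibly;
#'   `read_frames_tiff()` returns the stack as a numeric array of counts.
#' @export
write_frames_tiff <- function(stack, path) {
  stopifnot(is.array(stack), length(dim(stack)) == 3L)
  pages <- purrr::map(seq_len(dim(stack)[3]), function(f) {
    pmin(pmax(stack[, , f], 0), 65535) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_frames_tiff
#' @export
read_frames_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  stack <- array(0, dim = c(dim(pages[[1]])[1:2], length(pages)))
  for (f in seq_along(pages)) stack[, , f] <- round(pages[[f]] * 65535)
  stack
}
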