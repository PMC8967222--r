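#' Detect diffraction-limited spots in an image stack
#'
#' Convolves each frame with a PSF-matched Gaussian kernel (a matched
#' filter, which suppresses pixel noise), finds local maxima of the
#' filtered image that rise above the frame background by `threshold_sd`
#' robust noise standard deviations of the raw image, then refines each
#' candidate to sub-pixel precision by least-squares fitting a 2D Gaussian
#' (fixed width `psf_sigma_px`) with free position, amplitude and offset in
#' a raw-image window around the maximum. Candidates closer than one PSF
#' sigma are merged, keeping the brighter one.
#'
#' @param stack Numeric array `[n_row, n_col, n_frames]` (or a single
#'   matrix) of photon counts.
#' @param threshold_sd Detection threshold in units of the robust noise s.d.
#'   above the frame median.
#' @param psf_sigma_px PSF standard deviation in pixels (> 0).
#' @return A tibble with columns `frame`, `x_px`, `y_px`, `intensity`
#'   (fitted amplitude above offset, photons).
#' @export
detect_spots <- function(stack, threshold_sd = 3, psf_sigma_px = 1.3) {
  if (is.matrix(stack)) stack <- array(stack, dim = c(dim(stack), 1L))
  stopifnot(is.array(stack), length(dim(stack)) == 3L)
  if (prod(dim(stack)) == 0L) stop("empty image stack")
  if (!is_scalar(psf_sigma_px) || psf_sigma_px <= 0)
    stop("psf_sigma_px must be > 0")
  w <- max(2L, ceiling(2 * psf_sigma_px))
  out <- purrr::map(seq_len(dim(stack)[3]), function(f) {
    detect_frame(stack[, , f], f, threshold_sd, psf_sigma_px, w)
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0L)
    out <- tibble::tibble(frame = integer(0), x_px = numeric(0),
                          y_px = numeric(0), intensity = numeric(0))
  out
}

detect_frame <- function(img, f, threshold_sd, s, w) {
  bg <- stats::median(img)
  noise <- stats::mad(img)
  sm <- gaussian_smooth(img, s)
  thr <- bg + threshold_sd * max(noise, .Machine$double.eps)
  nr <- nrow(img); nc <- ncol(img)
  cand <- which(sm > thr, arr.ind = TRUE)
  # strict local maxima of the filtered image over the 8-neighborhood,
  # away from the border
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, 1]; c <- cand[i, 2]
    if (r <= w || r > nr - w || c <= w || c > nc - w) next
    nb <- sm[(r - 1):(r + 1), (c - 1):(c + 1)]
    keep[i] <- sm[r, c] >= max(nb) &&
      sum(nb == sm[r, c]) == 1L   # unique max avoids plateau duplicates
  }
  cand <- cand[keep, , drop = FALSE]
  if (!nrow(cand)) return(NULL)
  fits <- purrr::map(seq_len(nrow(cand)), function(i) {
    fit_gaussian_spot(img, cand[i, 1], cand[i, 2], s, w)
  })
  res <- dplyr::bind_rows(fits)
  res <- res[is.finite(res$x_px) & is.finite(res$y_px), , drop = FALSE]
  if (!nrow(res)) return(NULL)
  res <- merge_close_spots(res, s)
  tibble::tibble(frame = f, x_px = res$x_px, y_px = res$y_px,
                 intensity = res$intensity)
}

# Separable Gaussian convolution (matched filter), normalized so a flat
# background stays at its level.
gaussian_smooth <- function(img, s) {
  half <- max(2L, ceiling(3 * s))
  k <- stats::dnorm(-half:half, sd = s)
  k <- k / sum(k)
  pad <- function(m, n) m[c(rep(1L, n), seq_len(nrow(m)),
                            rep(nrow(m), n)), , drop = FALSE]
  conv1 <- function(m) {
    mp <- pad(m, half)
    out <- matrix(0, nrow(m), ncol(m))
    for (j in seq_along(k)) {
      out <- out + k[j] * mp[j:(j + nrow(m) - 1L), , drop = FALSE]
    }
    out
  }
  t(conv1(t(conv1(img))))
}

# Least-squares 2D Gaussian (fixed sigma) on a (2w+1)^2 window.
fit_gaussian_spot <- function(img, r0, c0, s, w) {
  rows <- (r0 - w):(r0 + w); cols <- (c0 - w):(c0 + w)
  z <- img[rows, cols]
  obj <- function(par) {
    mdl <- par[4] + par[3] *
      exp(-((outer(rows, rep(1, length(cols))) - par[2])^2 +
            (outer(rep(1, length(rows)), cols) - par[1])^2) / (2 * s^2))
    sum((z - mdl)^2)
  }
  start <- c(c0, r0, max(img[r0, c0] - stats::median(z), 1e-6),
             stats::median(z))
  fit <- stats::optim(start, obj, method = "L-BFGS-B",
                      lower = c(c0 - w, r0 - w, 0, 0),
                      upper = c(c0 + w, r0 + w, Inf, Inf))
  tibble::tibble(x_px = fit$par[1], y_px = fit$par[2],
                 intensity = fit$par[3] * 2 * pi * s^2)
}

merge_close_spots <- function(res, s) {
  res <- res[order(-res$intensity), , drop = FALSE]
  kept <- rep(TRUE, nrow(res))
  for (i in seq_len(nrow(res))) {
    if (!kept[i]) next
    if (i < nrow(res)) {
      j <- (i + 1):nrow(res)
      d <- sqrt((res$x_px[j] - res$x_px[i])^2 +
                (res$y_px[j] - res$y_px[i])^2)
      kept[j][d < s] <- FALSE
    }
  }
  res[kept, , drop = FALSE]
}
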