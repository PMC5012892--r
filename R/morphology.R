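# Grayscale flat-disk morphology.
#
# Erosion/dilation are computed as running min/max over the disk offsets via
# vectorised shifted-submatrix pmin/pmax; pixels near the border use the
# in-bounds part of the structuring element only. With a symmetric flat
# element this border convention keeps opening(x) <= x pointwise, so the
# top-hat residual is always non-negative.

#' Disk structuring-element offsets
#'
#' Integer offsets `(di, dj)` with `di^2 + dj^2 <= r^2` — a flat disk of
#' pixel radius `r` (always includes the centre).
#'
#' @param r_px Non-negative integer pixel radius.
#' @return A two-column integer matrix of offsets.
#' @export
disc_offsets <- function(r_px) {
  r_px <- as.integer(r_px)
  g <- expand.grid(di = -r_px:r_px, dj = -r_px:r_px)
  as.matrix(g[g$di^2 + g$dj^2 <= r_px^2, , drop = FALSE])
}

shift_reduce <- function(x, offsets, init, fun) {
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(init, nr, nc)
  for (k in seq_len(nrow(offsets))) {
    di <- offsets[k, 1]; dj <- offsets[k, 2]
    rs <- max(1L, 1L - di):min(nr, nr - di)
    cs <- max(1L, 1L - dj):min(nc, nc - dj)
    out[rs, cs] <- fun(out[rs, cs], x[rs + di, cs + dj])
  }
  out
}

#' Grayscale erosion by a flat disk
#' @param x Numeric matrix.
#' @param r_px Disk pixel radius.
#' @return Matrix of local minima over the disk neighbourhood.
#' @export
erode_disc <- function(x, r_px) shift_reduce(x, disc_offsets(r_px), Inf, pmin)

#' Grayscale dilation by a flat disk
#' @inheritParams erode_disc
#' @return Matrix of local maxima over the disk neighbourhood.
#' @export
dilate_disc <- function(x, r_px) shift_reduce(x, disc_offsets(r_px), -Inf, pmax)

#' Grayscale opening by a flat disk
#' @inheritParams erode_disc
#' @return Erosion followed by dilation with the same disk.
#' @export
open_disc <- function(x, r_px) dilate_disc(erode_disc(x, r_px), r_px)

#' White top-hat background non-uniformity correction
#'
#' Subtracts the grayscale morphological opening of the image by a flat disk,
#' removing any background structure wider than the disk while preserving
#' objects smaller than it. The disk radius is given in micrometres and
#' converted to pixels as `round(radius_um / pixel_size_um)`; a radius that
#' converts to less than one pixel is clamped to 1 px with a warning.
#'
#' @param pixels Numeric intensity matrix.
#' @param radius_um Structuring-element radius in micrometres (default 20).
#' @param pixel_size_um Micrometres per pixel edge.
#' @return Corrected intensity matrix, pointwise in `[0, pixels]`.
#' @examples
#' tophat_correct(matrix(7, 8, 8), 20, 2)  # flat image -> all zero
#' @export
tophat_correct <- function(pixels, radius_um = 20, pixel_size_um = 2) {
  stopifnot(is.matrix(pixels), radius_um > 0, pixel_size_um > 0)
  r_px <- round(radius_um / pixel_size_um)
  if (r_px < 1) {
    warning(sprintf(
      "top-hat radius %g um is below one pixel (%g um); clamped to 1 px",
      radius_um, pixel_size_um))
    r_px <- 1L
  }
  pixels - open_disc(pixels, r_px)
}

#' Separable Gaussian smoothing
#'
#' Convolution with a truncated Gaussian kernel (radius `ceiling(3*sigma)`),
#' applied along rows then columns; near the border the kernel is
#' renormalised over its in-bounds support so flat images stay flat.
#' `sigma = 0` returns the input unchanged.
#'
#' @param x Numeric matrix.
#' @param sigma Gaussian standard deviation in pixels.
#' @return Smoothed matrix of the same shape.
#' @export
gaussian_smooth <- function(x, sigma) {
  stopifnot(is.matrix(x), sigma >= 0)
  if (sigma == 0) return(x)
  r <- as.integer(ceiling(3 * sigma))
  w <- exp(-(-r:r)^2 / (2 * sigma^2))
  ones <- matrix(1, nrow(x), ncol(x))
  conv1 <- function(m, byrow) {
    nr <- nrow(m); nc <- ncol(m)
    num <- matrix(0, nr, nc); den <- matrix(0, nr, nc)
    for (k in seq_along(w)) {
      d <- k - r - 1L
      if (byrow) {
        rs <- max(1L, 1L - d):min(nr, nr - d)
        num[rs, ] <- num[rs, ] + w[k] * m[rs + d, , drop = FALSE]
        den[rs, ] <- den[rs, ] + w[k]
      } else {
        cs <- max(1L, 1L - d):min(nc, nc - d)
        num[, cs] <- num[, cs] + w[k] * m[, cs + d, drop = FALSE]
        den[, cs] <- den[, cs] + w[k]
      }
    }
    num / den
  }
  conv1(conv1(x, TRUE), FALSE)
}
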