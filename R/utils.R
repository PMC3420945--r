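# Shared geometry and image helpers.
#
# Coordinate convention used throughout: images are R matrices indexed
# [row, col]; a pixel's centre sits at x = col - 1, y = row - 1 (0-based,
# pixel-centre). Arc lengths are in px; conversion to um happens only when
# reporting.

#' Bilinear interpolation of an image at continuous coordinates
#'
#' @param image numeric matrix.
#' @param x,y numeric vectors of 0-based pixel-centre coordinates.
#' @return numeric vector of interpolated values; points outside the image
#'   are clamped to the border.
#' @keywords internal
bilinear <- function(image, x, y) {
  nr <- nrow(image); nc <- ncol(image)
  x <- pmin(pmax(x, 0), nc - 1)
  y <- pmin(pmax(y, 0), nr - 1)
  x0 <- pmin(floor(x), nc - 2); y0 <- pmin(floor(y), nr - 2)
  fx <- x - x0; fy <- y - y0
  i00 <- cbind(y0 + 1, x0 + 1)
  v00 <- image[i00]
  v01 <- image[cbind(y0 + 1, x0 + 2)]
  v10 <- image[cbind(y0 + 2, x0 + 1)]
  v11 <- image[cbind(y0 + 2, x0 + 2)]
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}

# Euclidean distance from points (x, y) to the segment [p1, p2] (each c(x, y)).
dist_to_segment <- function(x, y, p1, p2) {
  dx <- p2[1] - p1[1]; dy <- p2[2] - p1[2]
  len2 <- dx * dx + dy * dy
  if (len2 == 0) return(sqrt((x - p1[1])^2 + (y - p1[2])^2))
  t <- ((x - p1[1]) * dx + (y - p1[2]) * dy) / len2
  t <- pmin(pmax(t, 0), 1)
  sqrt((x - (p1[1] + t * dx))^2 + (y - (p1[2] + t * dy))^2)
}

# Mean of `values[image]` over pixels within radius r of centre (cx, cy),
# optionally restricted to a logical mask of the same shape.
disk_mean <- function(image, cx, cy, r, mask = NULL) {
  nr <- nrow(image); nc <- ncol(image)
  r0 <- max(1L, floor(cy - r) + 1L); r1 <- min(nr, ceiling(cy + r) + 1L)
  c0 <- max(1L, floor(cx - r) + 1L); c1 <- min(nc, ceiling(cx + r) + 1L)
  if (r0 > r1 || c0 > c1) return(NA_real_)
  rows <- r0:r1; cols <- c0:c1
  yy <- matrix(rows - 1, length(rows), length(cols))
  xx <- matrix(cols - 1, length(rows), length(cols), byrow = TRUE)
  inside <- (xx - cx)^2 + (yy - cy)^2 <= r^2
  if (!is.null(mask)) inside <- inside & mask[rows, cols, drop = FALSE]
  if (!any(inside)) return(NA_real_)
  sub <- image[rows, cols, drop = FALSE]
  mean(sub[inside])
}

#' Gaussian blur wrapper
#'
#' Isotropic Gaussian blur; thin wrapper so the PSF is applied in one place.
#' @keywords internal
blur_psf <- function(image, sigma) {
  if (sigma <= 0) return(image)
  EBImage::imageData(EBImage::gblur(image, sigma = sigma))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_rodpol <- function(...) stop(..., call. = FALSE)
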