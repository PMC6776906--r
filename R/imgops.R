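# Low-level image operations shared by the generator and the quantification
# stage. Images are plain numeric matrices indexed (row, col), 0-based
# coordinates at the API surface.

# Banded row-convolution matrix for a Gaussian of standard deviation `sigma`
# (pixels), truncated at `truncate` sigmas and renormalized per row so that
# edges see a unit-sum kernel (replicate-like behaviour without padding).
gaussian_band <- function(n, sigma, truncate = 4) {
  if (sigma <= 0) return(diag(n))
  h <- max(1L, ceiling(truncate * sigma))
  idx <- seq_len(n)
  K <- matrix(0, n, n)
  g <- dnorm(-h:h, sd = sigma)
  for (off in -h:h) {
    i <- idx[idx + off >= 1 & idx + off <= n]
    K[cbind(i, i + off)] <- g[off + h + 1]
  }
  K / rowSums(K)
}

#' Gaussian blur of a 2D image
#'
#' Separable Gaussian convolution with per-row kernel renormalization at the
#' image borders (no dark halo at edges).
#'
#' @param img numeric matrix.
#' @param sigma standard deviation in pixels; 0 returns `img` unchanged.
#' @param truncate kernel support half-width in units of `sigma`.
#' @return blurred matrix of the same shape.
#' @export
gaussian_blur <- function(img, sigma, truncate = 4) {
  stopifnot(is.matrix(img))
  if (sigma <= 0) return(img)
  Kr <- gaussian_band(nrow(img), sigma, truncate)
  Kc <- gaussian_band(ncol(img), sigma, truncate)
  Kr %*% img %*% t(Kc)
}

#' Otsu threshold of an image
#'
#' Classical between-class-variance maximizing threshold on a fixed-bin
#' histogram. Returns the threshold on the intensity scale of the input;
#' pixels strictly above it are foreground.
#'
#' @param img numeric matrix.
#' @param n_bins histogram resolution.
#' @return scalar threshold.
#' @export
otsu_threshold <- function(img, n_bins = 256) {
  v <- as.vector(img)
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(findInterval(v, breaks, all.inside = TRUE), nbins = n_bins)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  w1 <- 1 - w0
  bcv <- (mu_t * w0 - mu)^2 / (w0 * w1)
  bcv[!is.finite(bcv)] <- -Inf
  mids[which.max(bcv)]
}

# Robust noise scale: scaled median absolute deviation about the median.
robust_scale <- function(x) {
  x <- x[is.finite(x)]
  mad(x, constant = 1.4826)
}

# Connected components of a logical matrix; deterministic raster-order labels.
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask))
  .cc_label(mask, as.integer(connectivity))
}

# Exact Euclidean distance (pixels) to the nearest background pixel.
distance_transform <- function(mask) {
  sqrt(.edt_sq(mask))
}

# Local maxima of `img` within `mask`: pixels >= all 8 neighbours and
# > at least one (plateau interiors excluded by the strict condition against
# the raster-shifted copy), then greedily thinned to a minimum separation.
# Returns a data.frame of 0-based (row, col) sorted by decreasing value.
local_maxima <- function(img, mask = NULL, min_distance = 1) {
  nr <- nrow(img)
  nc <- ncol(img)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- img
  is_max <- matrix(TRUE, nr, nc)
  strictly_gt <- matrix(FALSE, nr, nc)
  for (dr in -1:1) {
    for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      nb <- pad[(2:(nr + 1)) + dr, (2:(nc + 1)) + dc]
      is_max <- is_max & (img >= nb)
      strictly_gt <- strictly_gt | (img > nb)
    }
  }
  is_max <- is_max & strictly_gt
  if (!is.null(mask)) is_max <- is_max & mask
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(data.frame(row = numeric(0), col = numeric(0), value = numeric(0)))
  }
  vals <- img[is_max]
  ord <- order(-vals, idx[, 1], idx[, 2])
  idx <- idx[ord, , drop = FALSE]
  vals <- vals[ord]
  if (min_distance > 1 && nrow(idx) > 1) {
    keep <- rep(TRUE, nrow(idx))
    for (i in seq_len(nrow(idx))) {
      if (!keep[i]) next
      if (i < nrow(idx)) {
        j <- (i + 1):nrow(idx)
        d2 <- (idx[j, 1] - idx[i, 1])^2 + (idx[j, 2] - idx[i, 2])^2
        keep[j[d2 < min_distance^2]] <- FALSE
      }
    }
    idx <- idx[keep, , drop = FALSE]
    vals <- vals[keep]
  }
  data.frame(row = idx[, 1] - 1, col = idx[, 2] - 1, value = vals)
}

# Render an anti-aliased uniform disk onto `img` (modified in place by
# value, returned). Center is 0-based (row, col); edge pixels get the
# sub-pixel covered fraction approximated from the center distance.
render_disk <- function(img, center, radius, amplitude) {
  nr <- nrow(img)
  nc <- ncol(img)
  r0 <- max(1L, floor(center[1] + 1 - radius - 1))
  r1 <- min(nr, ceiling(center[1] + 1 + radius + 1))
  c0 <- max(1L, floor(center[2] + 1 - radius - 1))
  c1 <- min(nc, ceiling(center[2] + 1 + radius + 1))
  if (r0 > r1 || c0 > c1) return(img)
  rows <- r0:r1
  cols <- c0:c1
  d <- sqrt(outer((rows - 1 - center[1])^2, (cols - 1 - center[2])^2, "+"))
  cov <- pmin(1, pmax(0, radius - d + 0.5))
  img[rows, cols] <- img[rows, cols] + amplitude * cov
  img
}

# Camera noise model: Poisson shot noise on expected photon counts
# (intensity / gain), scaled back, plus Gaussian read noise, clipped to the
# sensor range.
apply_camera_noise <- function(img, gaussian_sd, poisson_gain, bit_depth = 16) {
  out <- img
  if (poisson_gain > 0) {
    out <- rpois(length(img), lambda = pmax(0, img / poisson_gain)) * poisson_gain
    out <- matrix(out, nrow(img), ncol(img))
  }
  if (gaussian_sd > 0) {
    out <- out + matrix(rnorm(length(img), 0, gaussian_sd), nrow(img), ncol(img))
  }
  matrix(pmin(2^bit_depth - 1, pmax(0, out)), nrow(img), ncol(img))
}
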