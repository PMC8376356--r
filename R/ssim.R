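# Structural similarity (SSIM) between AFM height images.
#
# Standard local-window SSIM: with local means mu, variances sigma^2 and
# covariance sigma_xy computed under a Gaussian window,
#   SSIM = (2 mu_x mu_y + C1)(2 sigma_xy + C2) /
#          ((mu_x^2 + mu_y^2 + C1)(sigma_x^2 + sigma_y^2 + C2)),
# C1 = (k1 L)^2, C2 = (k2 L)^2.  The dynamic range L is the joint maximum
# height of the two images (heights are already on a common physical scale in
# Angstrom, with the substrate at 0).  Window smoothing is renormalized at
# the borders so identical images score exactly 1 everywhere.

gaussian_taps <- function(window = 11, sigma = 1.5) {
  half <- (window - 1) / 2
  g <- exp(-((-half):half)^2 / (2 * sigma^2))
  g / sum(g)
}

# separable, border-renormalized smoothing of a matrix
smooth_mat <- function(M, taps) {
  ny <- nrow(M); nx <- ncol(M)
  conv1 <- function(n) {
    # n x n banded smoothing matrix with renormalized truncated rows
    half <- (length(taps) - 1) / 2
    A <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- (i - half):(i + half)
      ok <- j >= 1 & j <= n
      A[i, j[ok]] <- taps[ok] / sum(taps[ok])
    }
    A
  }
  key <- as.character(ny * 1e6 + nx)
  ops <- .smooth_cache[[key]]
  if (is.null(ops)) {
    ops <- list(row = conv1(ny), col = conv1(nx))
    .smooth_cache[[key]] <- ops
  }
  ops$row %*% M %*% t(ops$col)
}

.smooth_cache <- new.env(parent = emptyenv())

#' Structural similarity between two AFM images
#'
#' Mean local SSIM over the mask (or the whole frame). Returns exactly 1 for
#' identical images and is symmetric in its arguments.
#'
#' @param a,b `afm_image` objects of equal shape.
#' @param mask Optional `afm_mask`; the SSIM map is averaged over its pixels.
#' @param window Window width in pixels (odd; default 11).
#' @param sigma Gaussian window standard deviation in pixels (default 1.5).
#' @param k1,k2 SSIM stabilisation constants (defaults 0.01, 0.03).
#' @return SSIM value <= 1.
#' @export
ssim <- function(a, b, mask = NULL, window = 11, sigma = 1.5,
                 k1 = 0.01, k2 = 0.03) {
  stopifnot(inherits(a, "afm_image"), inherits(b, "afm_image"))
  if (!all(dim(a$heights) == dim(b$heights))) stop("image shapes differ")
  X <- a$heights; Y <- b$heights
  L <- max(X, Y)
  if (L <= 0) {
    # both images are flat zero; identical by definition
    if (identical(dim(X), dim(Y)) && max(abs(X - Y)) == 0) return(1)
    L <- 1
  }
  C1 <- (k1 * L)^2; C2 <- (k2 * L)^2
  taps <- gaussian_taps(window, sigma)
  mx <- smooth_mat(X, taps); my <- smooth_mat(Y, taps)
  sxx <- smooth_mat(X * X, taps) - mx^2
  syy <- smooth_mat(Y * Y, taps) - my^2
  sxy <- smooth_mat(X * Y, taps) - mx * my
  map <- ((2 * mx * my + C1) * (2 * sxy + C2)) /
    ((mx^2 + my^2 + C1) * (sxx + syy + C2))
  if (!is.null(mask)) {
    check_same_shape(a, mask)
    mean(map[mask$values])
  } else {
    mean(map)
  }
}
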