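# Pseudo-AFM rendering: rasterize a mixture model into a height map.
#
# Each kernel is drawn as its Mahalanobis-level ellipsoid
#   (r - mu)^T Sigma^-1 (r - mu) = m^2.
# For a pixel center (x, y) this is a quadratic in z; the pixel height under
# one kernel is the larger real root (the top surface of the ellipsoid), and
# the image height is the maximum over kernels, clipped at the substrate
# plane z = 0.  This hard-surface model is deterministic and cheap enough to
# evaluate once per Monte-Carlo proposal.

#' Rasterize a pseudo-AFM image from a mixture model
#'
#' @param model A `gmm_model`.
#' @param grid An `afm_image` supplying the pixel geometry (its heights are
#'   ignored); see [default_afm_grid()].
#' @param level Mahalanobis level `m` of the rendered ellipsoid surface
#'   (default 2.0, i.e. the two-sigma surface).
#' @param isovalue Alternative soft rendering: if not `NULL`, the height is
#'   instead the largest z at which the full mixture density crosses
#'   `isovalue` (bisection per pixel; slower, exposed for sensitivity
#'   checks).
#' @return An `afm_image` with the rendered heights (Angstrom, >= 0).
#' @export
render_pseudo_afm <- function(model, grid = default_afm_grid(), level = 2,
                              isovalue = NULL) {
  stopifnot(inherits(model, "gmm_model"), inherits(grid, "afm_image"),
            level > 0)
  ny <- nrow(grid$heights); nx <- ncol(grid$heights)
  xs <- grid$origin[1] + (seq_len(nx) - 1) * grid$dx
  ys <- grid$origin[2] + (seq_len(ny) - 1) * grid$dy
  if (!is.null(isovalue)) {
    return(render_isovalue(model, grid, xs, ys, isovalue))
  }
  X <- matrix(xs, ny, nx, byrow = TRUE)
  Y <- matrix(ys, ny, nx)
  H <- matrix(0, ny, nx)
  m2 <- level^2
  for (i in seq_along(model$kernels)) {
    k <- model$kernels[[i]]
    dt <- det(k$cov)
    if (!is.finite(dt) || dt <= 0) {
      stop(sprintf("kernel %d has a singular covariance", i))
    }
    P <- solve(k$cov)
    dx <- X - k$center[1]
    dy <- Y - k$center[2]
    # P33 u^2 + 2 (P13 dx + P23 dy) u + quad(dx, dy) - m^2 = 0,  u = z - mu_z
    a <- P[3, 3]
    b <- 2 * (P[1, 3] * dx + P[2, 3] * dy)
    cc <- P[1, 1] * dx^2 + 2 * P[1, 2] * dx * dy + P[2, 2] * dy^2 - m2
    disc <- b^2 - 4 * a * cc
    hit <- disc >= 0
    if (any(hit)) {
      z <- k$center[3] + (-b[hit] + sqrt(disc[hit])) / (2 * a)
      Hk <- matrix(-Inf, ny, nx)
      Hk[hit] <- z
      H <- pmax(H, Hk)
    }
  }
  grid$heights <- pmax(H, 0)
  grid
}

# mixture-isovalue variant: highest z where density >= isovalue
render_isovalue <- function(model, grid, xs, ys, isovalue) {
  zmax <- max(vapply(model$kernels, function(k) {
    k$center[3] + 6 * sqrt(max(eigen(k$cov, only.values = TRUE)$values))
  }, numeric(1)))
  H <- matrix(0, nrow(grid$heights), ncol(grid$heights))
  for (i in seq_along(ys)) {
    for (j in seq_along(xs)) {
      f <- function(z) density_at(model, c(xs[j], ys[i], z)) - isovalue
      zs <- seq(0, zmax, length.out = 64)
      vals <- vapply(zs, f, numeric(1))
      above <- which(vals >= 0)
      if (length(above)) {
        hi <- zs[max(above)]
        lo <- if (max(above) < length(zs)) zs[max(above) + 1] else zmax
        H[i, j] <- tryCatch(
          stats::uniroot(f, c(hi, lo))$root,
          error = function(e) hi)
      }
    }
  }
  grid$heights <- H
  grid
}
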