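# Independent brute-force oracles used to validate the analytic paths.
# These deliberately share no code with the package internals: plain grid
# quadrature and per-pixel loops.

# unnormalized Gaussian density on a grid of points
.gauss_on_grid <- function(pts, mu, S) {
  P <- solve(S)
  d <- sweep(pts, 2, mu)
  exp(-rowSums((d %*% P) * d) / 2) / sqrt((2 * pi)^3 * det(S))
}

# grid for a set of kernels: centers +/- 6 max-sd, given spacing
.kernel_grid <- function(kernels, spacing) {
  centers <- do.call(rbind, lapply(kernels, `[[`, "center"))
  pad <- 6 * max(vapply(kernels, function(k) {
    sqrt(max(eigen(k$cov, only.values = TRUE)$values))
  }, numeric(1)))
  lo <- apply(centers, 2, min) - pad
  hi <- apply(centers, 2, max) + pad
  lapply(1:3, function(i) seq(lo[i], hi[i], by = spacing))
}

# numeric normalized overlap of two kernels by grid quadrature
grid_overlap <- function(a, b, spacing = 0.35) {
  ax <- .kernel_grid(list(a, b), spacing)
  pts <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  ga <- .gauss_on_grid(pts, a$center, a$cov)
  gb <- .gauss_on_grid(pts, b$center, b$cov)
  sum(ga * gb) / sqrt(sum(ga^2) * sum(gb^2))
}

# numeric density cross-correlation of two models by grid quadrature
grid_cc3d <- function(ma, mb, spacing = 0.7) {
  ax <- .kernel_grid(c(ma$kernels, mb$kernels), spacing)
  pts <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  dens <- function(m) {
    v <- 0
    for (k in m$kernels) v <- v + k$weight * .gauss_on_grid(pts, k$center, k$cov)
    v
  }
  ra <- dens(ma); rb <- dens(mb)
  sum(ra * rb) / sqrt(sum(ra^2) * sum(rb^2))
}

# direct per-pixel SSIM with Gaussian window and border renormalization,
# written as explicit loops
naive_ssim <- function(a, b, mask = NULL, window = 11, sigma = 1.5,
                       k1 = 0.01, k2 = 0.03) {
  X <- a$heights; Y <- b$heights
  L <- max(X, Y)
  if (L <= 0) {
    if (max(abs(X - Y)) == 0) return(1)
    L <- 1
  }
  C1 <- (k1 * L)^2; C2 <- (k2 * L)^2
  half <- (window - 1) / 2
  g1 <- exp(-((-half):half)^2 / (2 * sigma^2))
  ny <- nrow(X); nx <- ncol(X)
  out <- matrix(NA_real_, ny, nx)
  for (i in seq_len(ny)) {
    for (j in seq_len(nx)) {
      ii <- max(1, i - half):min(ny, i + half)
      jj <- max(1, j - half):min(nx, j + half)
      w <- outer(g1[ii - i + half + 1], g1[jj - j + half + 1])
      w <- w / sum(w)
      x <- X[ii, jj]; y <- Y[ii, jj]
      mx <- sum(w * x); my <- sum(w * y)
      sxx <- sum(w * x^2) - mx^2
      syy <- sum(w * y^2) - my^2
      sxy <- sum(w * x * y) - mx * my
      out[i, j] <- ((2 * mx * my + C1) * (2 * sxy + C2)) /
        ((mx^2 + my^2 + C1) * (sxx + syy + C2))
    }
  }
  if (is.null(mask)) mean(out) else mean(out[mask$values])
}

# random SPD covariance with eigenvalues in [lo, hi]
random_cov <- function(lo = 1, hi = 9) {
  A <- matrix(stats::rnorm(9), 3)
  Q <- qr.Q(qr(A))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q %*% diag(stats::runif(3, lo, hi)) %*% t(Q)
}

random_kernel <- function(center_spread = 5, lo = 1, hi = 9) {
  gmm_kernel(stats::runif(1, 0.5, 2),
             stats::rnorm(3, 0, center_spread),
             random_cov(lo, hi))
}

random_model <- function(n_kern, center_spread = 5) {
  gmm_model(lapply(seq_len(n_kern), function(i) random_kernel(center_spread)))
}
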