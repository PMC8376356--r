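# Analytic Gaussian overlap and density cross-correlation.
#
# Both measures come from the closed form for products of Gaussians:
#   integral N(x; m1, S1) N(x; m2, S2) dx = N(m1 - m2; 0, S1 + S2)
# so every pairwise integral reduces to one 3x3 solve and determinant.

# integral of N(.;m1,S1) * N(.;m2,S2) over R^3
gauss_product_integral <- function(m1, S1, m2, S2) {
  S <- S1 + S2
  dt <- det(S)
  if (!is.finite(dt) || dt <= 0) stop("singular sum covariance in overlap")
  d <- m1 - m2
  exp(-sum(d * solve(S, d)) / 2) / sqrt((2 * pi)^3 * dt)
}

#' Normalized overlap between two Gaussian kernels
#'
#' The cross-correlation of the two (unit-mass) kernel densities,
#' \deqn{o_{ab} = \frac{\int g_a g_b}{\sqrt{\int g_a^2 \int g_b^2}},}
#' evaluated in closed form. It is symmetric, lies in (0, 1], and equals 1
#' exactly when the kernels coincide. Kernel weights cancel and are ignored.
#' For two spherical kernels of standard deviation sigma whose centers are d
#' apart this reduces to `exp(-d^2 / (4 sigma^2))`.
#'
#' @param a,b `gmm_kernel` objects.
#' @return Overlap value in (0, 1].
#' @export
kernel_overlap <- function(a, b) {
  stopifnot(inherits(a, "gmm_kernel"), inherits(b, "gmm_kernel"))
  num <- gauss_product_integral(a$center, a$cov, b$center, b$cov)
  den <- sqrt(gauss_product_integral(a$center, a$cov, a$center, a$cov) *
                gauss_product_integral(b$center, b$cov, b$center, b$cov))
  min(num / den, 1)
}

# Sum over all kernel pairs of w_i w_j * integral(N_i N_j): the inner product
# <rho_a, rho_b> of two mixture densities.
density_inner_product <- function(a, b) {
  total <- 0
  for (ka in a$kernels) {
    for (kb in b$kernels) {
      total <- total + ka$weight * kb$weight *
        gauss_product_integral(ka$center, ka$cov, kb$center, kb$cov)
    }
  }
  total
}

#' Density cross-correlation between two mixture models
#'
#' Normalized cross-correlation of the full mixture densities,
#' \deqn{CC = \frac{\int \rho_a \rho_b}{\sqrt{\int \rho_a^2 \int \rho_b^2}},}
#' computed analytically over all kernel pairs (no voxelization). This is the
#' correlation reported as CC3D_density once the models have been rigidly
#' superposed; see [kernelcenter_fit()] and [cc3d_refined()].
#'
#' @param a,b `gmm_model` objects.
#' @return Correlation in [0, 1]; 1 for a model against itself.
#' @export
cc3d_density <- function(a, b) {
  stopifnot(inherits(a, "gmm_model"), inherits(b, "gmm_model"))
  num <- density_inner_product(a, b)
  den <- sqrt(density_inner_product(a, a) * density_inner_product(b, b))
  min(num / den, 1)
}
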