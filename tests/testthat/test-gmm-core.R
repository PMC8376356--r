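# Gaussian mixture core: density, overlap, correlation, voxelization,
# transforms, EM fitting, serialization.

test_that("density_at matches the closed form and is linear in kernels", {
  k1 <- gmm_kernel(1, c(0, 0, 0), diag(3))
  m1 <- gmm_model(list(k1))
  expect_equal(density_at(m1, c(0, 0, 0)), (2 * pi)^(-3 / 2))
  expect_equal(density_at(m1, c(1e6, 0, 0)), 0)

  k2 <- gmm_kernel(2.5, c(3, -1, 2), random_cov())
  m2 <- gmm_model(list(k2))
  both <- gmm_model(list(k1, k2))
  p <- c(1.2, -0.3, 0.5)
  expect_equal(density_at(both, p), density_at(m1, p) + density_at(m2, p))
})

test_that("density_at reports the singular kernel by index", {
  m <- gmm_model(list(gmm_kernel(1, c(0, 0, 0), diag(3)),
                      gmm_kernel(1, c(5, 0, 0), diag(3))))
  m$kernels[[2]]$cov <- matrix(0, 3, 3)  # corrupt after construction
  expect_error(density_at(m, c(0, 0, 0)), "kernel 2")
})

test_that("kernel overlap: identity, spherical closed form, symmetry", {
  withr::local_seed(1)
  k <- random_kernel()
  expect_equal(kernel_overlap(k, k), 1)

  a <- gmm_kernel(1, c(0, 0, 0), diag(3))
  b <- gmm_kernel(1, c(2, 0, 0), diag(3))
  expect_equal(kernel_overlap(a, b), exp(-1), tolerance = 1e-12)

  k2 <- random_kernel()
  expect_equal(kernel_overlap(k, k2), kernel_overlap(k2, k))
})

test_that("analytic overlap matches grid quadrature on anisotropic pairs", {
  withr::local_seed(7)
  for (rep in 1:5) {
    a <- random_kernel(center_spread = 2, lo = 1.5, hi = 6)
    b <- random_kernel(center_spread = 2, lo = 1.5, hi = 6)
    expect_equal(kernel_overlap(a, b), grid_overlap(a, b), tolerance = 1e-3)
  }
})

test_that("cc3d_density: self = 1, distant models ~ 0, grid oracle agrees", {
  withr::local_seed(11)
  m <- random_model(3)
  expect_equal(cc3d_density(m, m), 1)

  far <- transform_model(m, diag(3), c(1e4, 0, 0))
  expect_lt(cc3d_density(m, far), 1e-6)

  for (rep in 1:3) {
    a <- random_model(sample(2:5, 1), center_spread = 4)
    b <- random_model(sample(2:5, 1), center_spread = 4)
    expect_equal(cc3d_density(a, b), grid_cc3d(a, b), tolerance = 1e-3)
  }
})

test_that("cc3d_density is symmetric and rigid-transform invariant", {
  withr::local_seed(3)
  a <- random_model(4); b <- random_model(4)
  expect_equal(cc3d_density(a, b), cc3d_density(b, a), tolerance = 1e-12)
  R <- rotation_matrix(c(1, 2, 0.5), 0.9)
  t_ <- c(5, -3, 2)
  expect_equal(cc3d_density(transform_model(a, R, t_),
                            transform_model(b, R, t_)),
               cc3d_density(a, b), tolerance = 1e-6)
})

test_that("voxelize conserves mass, peaks at the center, scales linearly", {
  withr::local_seed(5)
  m <- gmm_model(list(gmm_kernel(2, c(0, 0, 0), 4 * diag(3))))
  grid <- density_grid(origin = c(-15, -15, -15), dim = c(31, 31, 31),
                       voxel = 1)
  map <- voxelize(m, grid)
  expect_equal(sum(map$values) * prod(map$voxel), 2, tolerance = 0.01)
  peak <- which(map$values == max(map$values), arr.ind = TRUE)
  expect_equal(as.integer(peak[1, ]), c(16L, 16L, 16L))

  m2 <- m; m2$kernels[[1]]$weight <- 4
  expect_equal(voxelize(m2, grid)$values, 2 * map$values)

  small <- density_grid(origin = c(-1, -1, -1), dim = c(3, 3, 3), voxel = 1)
  expect_warning(voxelize(m, small), "mass outside")
})

test_that("transform_kernel rotates covariance and preserves eigenvalues", {
  k <- gmm_kernel(1, c(1, 0, 0), diag(c(4, 1, 1)))
  expect_equal(transform_kernel(k, diag(3), c(0, 0, 0)), k)

  k90 <- transform_kernel(k, rotation_matrix(c(0, 0, 1), pi / 2))
  expect_equal(diag(k90$cov), c(1, 4, 1), tolerance = 1e-12)

  withr::local_seed(9)
  R <- rotation_matrix(rnorm(3), runif(1, 0, pi))
  k2 <- gmm_kernel(1, c(0, 1, 2), random_cov())
  expect_equal(sort(eigen(transform_kernel(k2, R)$cov, only.values = TRUE)$values),
               sort(eigen(k2$cov, only.values = TRUE)$values),
               tolerance = 1e-10)
  expect_error(transform_kernel(k, 2 * diag(3)), "orthonormal")
})

test_that("EM with k = 1 reproduces the weighted centroid and covariance", {
  withr::local_seed(21)
  X <- matrix(rnorm(300), ncol = 3)
  w <- runif(100, 1, 16)
  fit <- fit_gmm_em(X, weights = w, k = 1)
  mu_ref <- colSums(X * w) / sum(w)
  d <- sweep(X, 2, mu_ref)
  cov_ref <- crossprod(d * w, d) / sum(w)
  expect_equal(fit$kernels[[1]]$center, mu_ref, tolerance = 1e-10)
  expect_equal(fit$kernels[[1]]$cov, cov_ref, tolerance = 1e-10)
  expect_equal(fit$kernels[[1]]$weight, 1)
})

test_that("EM recovers two well-separated spherical clusters", {
  withr::local_seed(22)
  X <- rbind(matrix(rnorm(1500, 0, 3), ncol = 3),
             sweep(matrix(rnorm(1500, 0, 3), ncol = 3), 2, c(50, 0, 0), "+"))
  fit <- fit_gmm_em(X, k = 2, seed = 4)
  centers <- kernel_centers(fit)
  centers <- centers[order(centers[, 1]), ]
  expect_lt(sqrt(sum((centers[1, ] - c(0, 0, 0))^2)), 1)
  expect_lt(sqrt(sum((centers[2, ] - c(50, 0, 0))^2)), 1)
  expect_equal(sum(vapply(fit$kernels, `[[`, numeric(1), "weight")), 1)
})

test_that("EM log-likelihood is monotone non-decreasing and seed-stable", {
  withr::local_seed(23)
  X <- rbind(matrix(rnorm(900, 0, 2), ncol = 3),
             sweep(matrix(rnorm(900, 0, 4), ncol = 3), 2, c(12, 5, 0), "+"),
             sweep(matrix(rnorm(900, 0, 3), ncol = 3), 2, c(-8, 14, 6), "+"))
  fit <- fit_gmm_em(X, k = 3, seed = 11)
  ll <- attr(fit, "loglik")
  expect_true(all(diff(ll) >= -1e-7 * abs(ll[-length(ll)])))

  fit2 <- fit_gmm_em(X, k = 3, seed = 11)
  expect_equal(kernel_centers(fit), kernel_centers(fit2))
  expect_error(fit_gmm_em(matrix(numeric(0), ncol = 3), k = 1), "no points")
})

test_that("EM agrees with an independent unweighted mixture fit", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  withr::local_seed(24)
  X <- rbind(matrix(rnorm(1200, 0, 2), ncol = 3),
             sweep(matrix(rnorm(1200, 0, 2), ncol = 3), 2, c(20, 0, 0), "+"))
  fit <- fit_gmm_em(X, k = 2, seed = 2)
  mc <- mclust::Mclust(X, G = 2, modelNames = "VVV", verbose = FALSE)
  ours <- kernel_centers(fit); ours <- ours[order(ours[, 1]), ]
  theirs <- t(mc$parameters$mean); theirs <- theirs[order(theirs[, 1]), ]
  expect_lt(max(abs(ours - theirs)), 0.2)
})

test_that("gmm text and JSON round trips are lossless", {
  withr::local_seed(31)
  m <- make_toy_hexamer()
  for (ext in c(".gmm", ".json")) {
    path <- tempfile(fileext = ext)
    write_gmm(m, path)
    back <- read_gmm(path)
    expect_equal(length(back$kernels), 18)
    for (i in seq_along(m$kernels)) {
      expect_equal(back$kernels[[i]]$weight, m$kernels[[i]]$weight,
                   tolerance = 1e-6)
      expect_equal(back$kernels[[i]]$center, m$kernels[[i]]$center,
                   tolerance = 1e-6)
      expect_equal(back$kernels[[i]]$cov, m$kernels[[i]]$cov,
                   tolerance = 1e-6)
      expect_identical(back$kernels[[i]]$chain, m$kernels[[i]]$chain)
      expect_identical(back$kernels[[i]]$role, m$kernels[[i]]$role)
    }
  }
})

test_that("gmm reader reports malformed and truncated files by line", {
  m <- random_model(3)
  path <- tempfile(fileext = ".gmm")
  write_gmm(m, path)
  lines <- readLines(path)
  writeLines(lines[1:3], path)  # drop the last kernel
  expect_error(read_gmm(path), "truncated")
  bad <- lines; bad[2] <- "not a kernel line"
  writeLines(bad, path)
  expect_error(read_gmm(path), "line 2")
})
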