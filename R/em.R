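# Mass-weighted expectation-maximization for fitting Gaussian mixtures to
# atomic point clouds.

log_gauss <- function(X, mu, S) {
  dt <- det(S)
  P <- solve(S)
  d <- sweep(X, 2, mu)
  -0.5 * rowSums((d %*% P) * d) - 0.5 * log((2 * pi)^3 * dt)
}

# deterministic k-means++-style center seeding from an integer seed
seed_centers <- function(X, w, k, seed) {
  with_seed(seed, {
    n <- nrow(X)
    idx <- sample.int(n, 1, prob = w)
    centers <- X[idx, , drop = FALSE]
    while (nrow(centers) < k) {
      d2 <- apply(centers, 1, function(c0) rowSums(sweep(X, 2, c0)^2))
      mind2 <- if (is.matrix(d2)) apply(d2, 1, min) else d2
      p <- w * mind2
      if (sum(p) <= 0) p <- w
      idx <- sample.int(n, 1, prob = p)
      centers <- rbind(centers, X[idx, , drop = FALSE])
    }
    centers
  })
}

floor_cov <- function(S, floor = 1e-2) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  if (all(e$values >= floor)) return((S + t(S)) / 2)
  warning("covariance eigenvalue below floor; regularized at ", floor,
          " A^2", call. = FALSE)
  e$vectors %*% diag(pmax(e$values, floor)) %*% t(e$vectors)
}

#' Fit a Gaussian mixture to weighted points by EM
#'
#' Mass-weighted EM: each point contributes to the sufficient statistics in
#' proportion to its weight (e.g. atomic mass), so the fitted mixture
#' approximates the mass density rather than the atom-count density. Kernel
#' weights sum to 1. Initialisation is a deterministic k-means++-style seeding
#' driven by `seed`, so results are reproducible. Covariance eigenvalues are
#' floored at 0.01 Angstrom^2 to prevent collapse (a warning is issued when
#' the floor engages).
#'
#' @param points n x 3 numeric matrix of coordinates (Angstrom).
#' @param weights Positive per-point weights; default all 1.
#' @param k Number of kernels.
#' @param seed Integer seed for initialisation.
#' @param tol Convergence tolerance on the weighted log-likelihood.
#' @param max_iter Maximum EM iterations.
#' @return A `gmm_model` with `k` kernels; attribute `"loglik"` holds the
#'   per-iteration weighted log-likelihood trace (non-decreasing).
#' @export
fit_gmm_em <- function(points, weights = NULL, k, seed = 1L, tol = 1e-8,
                       max_iter = 200L) {
  points <- as.matrix(points)
  if (nrow(points) == 0) stop("no points to fit")
  stopifnot(ncol(points) == 3, k >= 1, nrow(points) >= k)
  w <- if (is.null(weights)) rep(1, nrow(points)) else as.numeric(weights)
  stopifnot(length(w) == nrow(points), all(w > 0))
  wsum <- sum(w)

  # closed-form k = 1: one M step is exact
  wmean <- function(X, w) colSums(X * w) / sum(w)
  wcov <- function(X, w, mu) {
    d <- sweep(X, 2, mu)
    crossprod(d * w, d) / sum(w)
  }
  if (k == 1) {
    mu <- wmean(points, w)
    S <- floor_cov(wcov(points, w, mu))
    mod <- gmm_model(list(gmm_kernel(1, mu, S)), name = "em_fit")
    attr(mod, "loglik") <- sum(w * log_gauss(points, mu, S))
    return(mod)
  }

  mu <- seed_centers(points, w, k, seed)
  # initial responsibilities from nearest seeded center
  d2 <- vapply(seq_len(k), function(j) rowSums(sweep(points, 2, mu[j, ])^2),
               numeric(nrow(points)))
  assign0 <- max.col(-d2)
  pi_k <- vapply(seq_len(k), function(j) sum(w[assign0 == j]), numeric(1))
  pi_k <- pmax(pi_k, 1e-12); pi_k <- pi_k / sum(pi_k)
  S <- lapply(seq_len(k), function(j) {
    sel <- assign0 == j
    if (sum(sel) >= 2) floor_cov(wcov(points[sel, , drop = FALSE], w[sel],
                                      wmean(points[sel, , drop = FALSE], w[sel])))
    else diag(3)
  })
  mu <- lapply(seq_len(k), function(j) {
    sel <- assign0 == j
    if (any(sel)) wmean(points[sel, , drop = FALSE], w[sel]) else mu[j, ]
  })

  ll_trace <- numeric(0)
  prev <- -Inf
  for (it in seq_len(max_iter)) {
    lg <- vapply(seq_len(k),
                 function(j) log(pi_k[j]) + log_gauss(points, mu[[j]], S[[j]]),
                 numeric(nrow(points)))
    m <- apply(lg, 1, max)
    lse <- m + log(rowSums(exp(lg - m)))
    ll <- sum(w * lse)
    ll_trace <- c(ll_trace, ll)
    r <- exp(lg - lse)           # responsibilities, rows sum to 1
    rw <- r * w
    Nk <- colSums(rw)
    pi_k <- Nk / wsum
    for (j in seq_len(k)) {
      mu[[j]] <- colSums(points * rw[, j]) / Nk[j]
      d <- sweep(points, 2, mu[[j]])
      S[[j]] <- floor_cov(crossprod(d * rw[, j], d) / Nk[j])
    }
    if (is.finite(prev) && ll - prev < tol * abs(ll)) break
    prev <- ll
  }

  kernels <- lapply(seq_len(k), function(j) gmm_kernel(pi_k[j], mu[[j]], S[[j]]))
  mod <- gmm_model(kernels, name = "em_fit")
  attr(mod, "loglik") <- ll_trace
  attr(mod, "responsibilities") <- r
  mod
}
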