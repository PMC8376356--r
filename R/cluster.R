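# Conformational clustering of candidate models.
#
# Models are voxelized on one common grid, the flattened maps are projected
# onto their first two principal components, and the 2D embedding is
# clustered with DBSCAN (min_samples = 4 by default; eps chosen by the
# k-distance knee when not given).  Each cluster is summarised by its median
# member — the model closest, in PC space, to the coordinate-wise median of
# the cluster — and clusters are ranked by size.

# plain O(n^2) DBSCAN on a coordinate matrix; labels 0 = noise
dbscan_labels <- function(X, eps, min_pts) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  labels <- rep(NA_integer_, n)   # NA = unvisited
  cluster <- 0L
  for (p in seq_len(n)) {
    if (!is.na(labels[p])) next
    nb <- which(D[p, ] <= eps)
    if (length(nb) < min_pts) { labels[p] <- 0L; next }
    cluster <- cluster + 1L
    labels[p] <- cluster
    queue <- setdiff(nb, p)
    while (length(queue)) {
      q <- queue[1]; queue <- queue[-1]
      if (!is.na(labels[q]) && labels[q] == 0L) labels[q] <- cluster
      if (!is.na(labels[q])) next
      labels[q] <- cluster
      nb_q <- which(D[q, ] <= eps)
      if (length(nb_q) >= min_pts) queue <- c(queue, setdiff(nb_q, q))
    }
  }
  labels
}

# automatic eps from the k-distance curve: the radius that makes ~90% of
# points core points (distance to the k-th nearest neighbor, counting the
# point itself -- the same convention as the core-point test).  The upper
# decile is left out so isolated outliers become noise rather than inflating
# eps.
auto_eps <- function(X, k) {
  D <- as.matrix(stats::dist(X))
  kd <- apply(D, 1, function(r) sort(r)[min(k, length(r))])
  eps <- 1.1 * stats::quantile(kd, 0.9, names = FALSE)
  if (eps <= 0) eps <- max(kd, 1e-8)
  eps
}

#' Cluster an ensemble of models by voxel PCA + DBSCAN
#'
#' @param models List of `gmm_model`s (>= `min_samples`).
#' @param voxel Voxel edge for the common grid (Angstrom; default 3).
#' @param margin Grid padding around the joint bounding box (Angstrom).
#' @param min_samples DBSCAN core-point threshold (default 4).
#' @param eps DBSCAN radius in PC space; `NULL` selects it from the
#'   k-distance knee with `k = min_samples`.
#' @return A `cluster_report`: data frame `assignments` (model, cluster
#'   [0 = noise], PC1, PC2), data frame `clusters` (cluster, size, rank,
#'   median_model index), and the `eps` used. Cluster ranks order
#'   non-increasing size.
#' @export
cluster_models <- function(models, voxel = 3, margin = 10, min_samples = 4,
                           eps = NULL) {
  stopifnot(length(models) >= min_samples)
  grid <- enclosing_grid(models, voxel = voxel, margin = margin)
  flat <- t(vapply(models, function(m) as.numeric(voxelize(m, grid)$values),
                   numeric(prod(grid$dim))))
  pc <- stats::prcomp(flat, center = TRUE, scale. = FALSE, rank. = 2)
  emb <- pc$x[, 1:2, drop = FALSE]
  if (ncol(emb) < 2) emb <- cbind(emb, 0)
  if (is.null(eps)) eps <- auto_eps(emb, min_samples)
  labels <- dbscan_labels(emb, eps, min_samples)

  ids <- sort(setdiff(unique(labels), 0L))
  if (!length(ids)) warning("all models labeled as noise; zero clusters")
  clusters <- do.call(rbind, lapply(ids, function(cl) {
    members <- which(labels == cl)
    med <- apply(emb[members, , drop = FALSE], 2, stats::median)
    d <- sqrt(rowSums(sweep(emb[members, , drop = FALSE], 2, med)^2))
    data.frame(cluster = cl, size = length(members),
               median_model = members[which.min(d)])
  })) %||% data.frame(cluster = integer(), size = integer(),
                      median_model = integer())
  if (nrow(clusters)) {
    clusters <- clusters[order(-clusters$size, clusters$cluster), ]
    clusters$rank <- seq_len(nrow(clusters))
  } else {
    clusters$rank <- integer(0)
  }
  structure(list(
    assignments = data.frame(model = seq_along(models), cluster = labels,
                             PC1 = emb[, 1], PC2 = emb[, 2]),
    clusters = clusters, eps = eps, voxel = voxel),
    class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf("Cluster report: %d models, %d clusters (eps = %.4g), %d noise\n",
              nrow(x$assignments), nrow(x$clusters),
              x$eps, sum(x$assignments$cluster == 0)))
  if (nrow(x$clusters)) print(x$clusters, row.names = FALSE)
  invisible(x)
}
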