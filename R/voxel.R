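# Voxelization of mixture models and MRC export.

#' Construct a density-map grid specification
#'
#' @param origin 3-vector, position of the center of voxel (1,1,1) (Angstrom).
#' @param dim integer 3-vector, number of voxels along x, y, z.
#' @param voxel 3-vector (or scalar) voxel edge lengths (Angstrom).
#' @return A `density_grid` object.
#' @export
density_grid <- function(origin, dim, voxel) {
  if (length(voxel) == 1) voxel <- rep(voxel, 3)
  stopifnot(length(origin) == 3, length(dim) == 3, length(voxel) == 3,
            all(dim >= 1), all(voxel > 0))
  structure(list(origin = as.numeric(origin), dim = as.integer(dim),
                 voxel = as.numeric(voxel)), class = "density_grid")
}

#' Grid that encloses a set of models
#'
#' Bounding box of all kernel centers expanded by `margin`, discretized at
#' `voxel` Angstrom.
#' @param models list of `gmm_model`.
#' @param voxel voxel edge (Angstrom).
#' @param margin padding added on every side (Angstrom).
#' @export
enclosing_grid <- function(models, voxel = 3, margin = 10) {
  ext <- do.call(rbind, lapply(models, function(m) {
    do.call(rbind, lapply(m$kernels, function(k) {
      r <- 3 * sqrt(max(eigen(k$cov, symmetric = TRUE,
                              only.values = TRUE)$values))
      rbind(k$center - r, k$center + r)
    }))
  }))
  lo <- apply(ext, 2, min) - margin
  hi <- apply(ext, 2, max) + margin
  dim <- pmax(1L, as.integer(ceiling((hi - lo) / voxel)) + 1L)
  density_grid(origin = lo, dim = dim, voxel = voxel)
}

#' Rasterize a mixture model onto a voxel grid
#'
#' Each voxel holds the mixture density evaluated at the voxel center, so
#' `sum(map) * prod(voxel)` approximates the total kernel weight when the grid
#' encloses the model. A warning reports the mass fraction lost when it does
#' not (threshold 1%).
#'
#' @param model A `gmm_model`.
#' @param grid A [density_grid()].
#' @return A `density_map`: list with `values` (3D array), `voxel`, `origin`.
#' @export
voxelize <- function(model, grid) {
  stopifnot(inherits(model, "gmm_model"), inherits(grid, "density_grid"))
  xs <- grid$origin[1] + (seq_len(grid$dim[1]) - 1) * grid$voxel[1]
  ys <- grid$origin[2] + (seq_len(grid$dim[2]) - 1) * grid$voxel[2]
  zs <- grid$origin[3] + (seq_len(grid$dim[3]) - 1) * grid$voxel[3]
  vals <- array(0, dim = grid$dim)
  # per-kernel vectorized evaluation over the full grid
  pts <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  for (i in seq_along(model$kernels)) {
    k <- model$kernels[[i]]
    dt <- det(k$cov)
    if (!is.finite(dt) || dt <= 0) {
      stop(sprintf("kernel %d has a singular covariance", i))
    }
    P <- solve(k$cov)
    d <- sweep(pts, 2, k$center)
    q <- rowSums((d %*% P) * d)
    vals <- vals + array(k$weight * exp(-q / 2) / sqrt((2 * pi)^3 * dt),
                         dim = grid$dim)
  }
  total_w <- sum(vapply(model$kernels, `[[`, numeric(1), "weight"))
  captured <- sum(vals) * prod(grid$voxel)
  if (captured < 0.99 * total_w) {
    warning(sprintf("grid too small: %.1f%% of model mass outside the map",
                    100 * (1 - captured / total_w)))
  }
  structure(list(values = vals, voxel = grid$voxel, origin = grid$origin),
            class = "density_map")
}

#' Write a density map as an MRC/CCP4 volume
#'
#' Minimal mode-2 (float32) MRC writer so that maps and representative models
#' can be inspected in molecular graphics software.
#'
#' @param map A `density_map` from [voxelize()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(map, path) {
  stopifnot(inherits(map, "density_map"))
  dm <- dim(map$values)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(dm)                       # NX NY NZ
  wi(2)                        # MODE 2 = float32
  wi(c(0, 0, 0))               # NXSTART..
  wi(dm)                       # MX MY MZ
  wf(dm * map$voxel)           # CELLA (A)
  wf(c(90, 90, 90))            # CELLB
  wi(c(1, 2, 3))               # MAPC MAPR MAPS
  wf(c(min(map$values), max(map$values), mean(map$values)))
  wi(c(1, 0))                  # ISPG, NSYMBT
  writeBin(raw(25 * 4), con)   # EXTRA (25 words)
  wf(map$origin)               # ORIGIN (words 50-52)
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(as.numeric(map$values)))
  wi(0)                        # NLABL
  writeBin(raw(800), con)      # labels
  wf(as.numeric(map$values))   # x fastest, matching R array order
  invisible(path)
}
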