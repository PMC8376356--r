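# Synthetic hexamer fixtures.
#
# Parameter-driven toy hexamers emulating the four conformational classes
# seen for hexameric disaggregases in AFM (closed ring, spiral, open,
# half-spiral), plus perturbation and noisy-target-image generators, so that
# every pipeline stage can be exercised without any external data.  Default
# dimensions fill most of the 300-Angstrom image width, mirroring how the
# experimental molecules fill the frame, and -- critically -- pack adjacent
# chains into contact so that the neighboring body/tail/head kernels of the
# ring genuinely overlap: the inter-chain overlap restraints are only
# meaningful on a hexamer whose chains touch, as in the real oligomer.

#' Specification of a toy hexamer
#'
#' @param class One of `"closed"`, `"spiral"`, `"open"`, `"half-spiral"`.
#' @param ring_radius Radius of the ring of body kernels (Angstrom).
#' @param z_rise Cumulative per-chain vertical rise for the spiral classes
#'   (Angstrom; applied when `class` is `"spiral"`).
#' @param seam_gap Extra separation opened at each seam for the `"open"` and
#'   `"half-spiral"` classes (Angstrom).
#' @param sizes Named list of per-role covariance standard deviations,
#'   3-vectors (radial, tangential, vertical; Angstrom).
#' @param z_levels Named vector of role center heights above the substrate
#'   (Angstrom).
#' @param weights Named vector of per-role mass fractions (sum to 1 within a
#'   chain).
#' @return A `toy_spec` list.
#' @export
toy_spec <- function(class = "closed", ring_radius = 55, z_rise = 7,
                     seam_gap = 30,
                     sizes = list(head = c(9, 16, 7), body = c(18, 22, 16),
                                  tail = c(10, 13, 7)),
                     z_levels = c(head = 50, body = 30, tail = 10),
                     weights = c(head = 0.2, body = 0.6, tail = 0.2)) {
  class <- match.arg(class, c("closed", "spiral", "open", "half-spiral"))
  stopifnot(ring_radius > 0, all(unlist(sizes) > 0))
  structure(list(class = class, ring_radius = ring_radius, z_rise = z_rise,
                 seam_gap = seam_gap, sizes = sizes, z_levels = z_levels,
                 weights = weights), class = "toy_spec")
}

#' Build a toy labeled 18-kernel hexamer
#'
#' Places three labeled kernels (head/body/tail) per chain on a ring; chain
#' `c` sits at angle `60 (c - 1)` degrees. The `"spiral"` class adds a
#' cumulative vertical rise per chain; `"open"` displaces chain F radially
#' outward by the seam gap (opening the A-F interface); `"half-spiral"`
#' translates the trimer D-E-F away from A-B-C, opening both the A-F and C-D
#' interfaces. Covariances are anisotropic and oriented along the ring
#' tangent.
#'
#' @param spec A [toy_spec()].
#' @param center Lateral position of the ring center (Angstrom); the default
#'   centers the assembly in the default 66 x 42 image.
#' @return An 18-kernel labeled `gmm_model`.
#' @export
make_toy_hexamer <- function(spec = toy_spec(),
                             center = c(65 * 4.545 / 2, 41 * 5.477 / 2)) {
  stopifnot(inherits(spec, "toy_spec"))
  kernels <- list()
  for (ci in 1:6) {
    theta <- (ci - 1) * pi / 3
    Rz <- rotation_matrix(c(0, 0, 1), theta)
    radial <- c(cos(theta), sin(theta), 0)
    dz <- if (spec$class == "spiral") spec$z_rise * (ci - 1) else 0
    shift <- c(0, 0, 0)
    if (spec$class == "open" && ci == 6) {
      shift <- spec$seam_gap * radial
    }
    if (spec$class == "half-spiral" && ci %in% 4:6) {
      # translate trimer D-E-F away from the A-B-C centroid (at 60 deg):
      # opens both the A-F and C-D interfaces
      shift <- spec$seam_gap * c(cos(4 * pi / 3), sin(4 * pi / 3), 0)
    }
    for (role in c("head", "body", "tail")) {
      s <- spec$sizes[[role]]
      cov_local <- diag(s^2)
      cov <- Rz %*% cov_local %*% t(Rz)
      pos <- c(center, 0) + spec$ring_radius * radial +
        c(0, 0, spec$z_levels[[role]] + dz) + shift
      kernels[[length(kernels) + 1]] <-
        gmm_kernel(spec$weights[[role]] / 6, pos, cov,
                   chain = LETTERS[ci], role = role)
    }
  }
  gmm_model(kernels, name = paste0("toy_", spec$class),
            provenance = "synthetic hexamer")
}

#' Randomly perturb the kernels of a model
#'
#' Independent Gaussian center displacements (`sigma_t` per axis) and
#' covariance rotations by Gaussian angles (`sigma_r`) about random axes,
#' per kernel. Deterministic given `seed`.
#'
#' @param model A `gmm_model`.
#' @param sigma_t Center displacement standard deviation (Angstrom).
#' @param sigma_r Rotation angle standard deviation (degrees).
#' @param seed Integer seed.
#' @return The perturbed model.
#' @export
perturb_model <- function(model, sigma_t = 4, sigma_r = 15, seed = 1L) {
  if (sigma_t == 0 && sigma_r == 0) return(model)
  with_seed(seed, {
    model$kernels <- lapply(model$kernels, function(k) {
      if (sigma_t > 0) k$center <- k$center + stats::rnorm(3, 0, sigma_t)
      if (sigma_r > 0) {
        R <- rotation_matrix(stats::rnorm(3),
                             stats::rnorm(1, 0, sigma_r * pi / 180))
        k$cov <- (R %*% k$cov %*% t(R) + t(R %*% k$cov %*% t(R))) / 2
      }
      k
    })
    model$provenance <- sprintf("%s + perturbation (%.3g A, %.3g deg, seed %d)",
                                model$provenance, sigma_t, sigma_r, seed)
    model
  })
}

# one-pixel binary dilation (4 + diagonal neighborhood)
dilate1 <- function(M) {
  ny <- nrow(M); nx <- ncol(M)
  out <- M
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    src_i <- pmin(pmax(seq_len(ny) + di, 1), ny)
    src_j <- pmin(pmax(seq_len(nx) + dj, 1), nx)
    out <- out | M[src_i, src_j]
  }
  out
}

#' Render a synthetic target image with noise and background tilt
#'
#' Renders the model on `grid`, adds a planar background tilt
#' `tilt[1] x + tilt[2] y` and i.i.d. Gaussian pixel noise, and derives the
#' molecule mask from the noiseless rendering (pixels with height > 0,
#' dilated by one pixel). With zero noise and tilt the image equals the
#' plain rendering.
#'
#' @param model A `gmm_model`.
#' @param grid An `afm_image` geometry (default [default_afm_grid()]).
#' @param noise_sd Pixel noise standard deviation (Angstrom).
#' @param tilt Length-2 plane coefficients (Angstrom per Angstrom).
#' @param seed Integer seed for the noise.
#' @param level Rendering level (see [render_pseudo_afm()]).
#' @return List with `image` (`afm_image`) and `mask` (`afm_mask`).
#' @export
make_target_image <- function(model, grid = default_afm_grid(), noise_sd = 0,
                              tilt = c(0, 0), seed = 1L, level = 2) {
  clean <- render_pseudo_afm(model, grid, level = level)
  mask <- afm_mask(dilate1(clean$heights > 0))
  img <- clean
  if (any(tilt != 0)) {
    ny <- nrow(img$heights); nx <- ncol(img$heights)
    xs <- img$origin[1] + (seq_len(nx) - 1) * img$dx
    ys <- img$origin[2] + (seq_len(ny) - 1) * img$dy
    img$heights <- img$heights + tilt[1] * matrix(xs, ny, nx, byrow = TRUE) +
      tilt[2] * matrix(ys, ny, nx)
  }
  if (noise_sd > 0) {
    img$heights <- img$heights +
      with_seed(seed, matrix(stats::rnorm(length(img$heights), 0, noise_sd),
                             nrow(img$heights)))
  }
  list(image = img, mask = mask)
}
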