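# Core Gaussian-mixture representation.
#
# A protein chain is coarse-grained into a handful of anisotropic 3D Gaussian
# kernels (for the hexamers modeled here: one "head" kernel for the coiled-coil
# domain, one "body" kernel for the AAA1+/AAA2+ core and one "tail" kernel for
# the C-terminal domain, per chain).  A model is an ordered list of such
# kernels; kernel order is stable and defines the correspondence between
# models, which every pairwise measure in the package relies on.

#' Construct a single Gaussian kernel
#'
#' @param weight Positive scalar weight (unitless; mass fraction by
#'   convention).
#' @param center Numeric 3-vector, kernel center in Angstrom.
#' @param cov 3x3 symmetric positive-definite covariance matrix (Angstrom^2).
#' @param chain Optional chain label, one of `"A"`..`"F"` (or `NA`).
#' @param role Optional role label: `"head"`, `"body"` or `"tail"` (or `NA`).
#' @return An object of class `gmm_kernel`.
#' @examples
#' k <- gmm_kernel(1, c(0, 0, 0), diag(3))
#' @export
gmm_kernel <- function(weight, center, cov, chain = NA_character_,
                       role = NA_character_) {
  stopifnot(is.numeric(weight), length(weight) == 1, weight > 0,
            is.numeric(center), length(center) == 3, all(is.finite(center)))
  cov <- check_spd(cov)
  if (!is.na(chain)) stopifnot(chain %in% LETTERS[1:6])
  if (!is.na(role)) stopifnot(role %in% c("head", "body", "tail"))
  structure(list(weight = as.numeric(weight),
                 center = as.numeric(center),
                 cov = cov,
                 chain = as.character(chain),
                 role = as.character(role)),
            class = "gmm_kernel")
}

#' Construct a Gaussian mixture model
#'
#' @param kernels List of [gmm_kernel()] objects. Order matters: it defines
#'   kernel correspondence between models.
#' @param name Model name.
#' @param provenance Free-text provenance (source structure, trajectory step).
#' @return An object of class `gmm_model`.
#' @export
gmm_model <- function(kernels, name = "model", provenance = "") {
  stopifnot(is.list(kernels), length(kernels) >= 1,
            all(vapply(kernels, inherits, logical(1), "gmm_kernel")))
  structure(list(kernels = kernels, name = name, provenance = provenance),
            class = "gmm_model")
}

#' @export
print.gmm_model <- function(x, ...) {
  cat(sprintf("Gaussian mixture model '%s': %d kernels\n", x$name,
              length(x$kernels)))
  ch <- vapply(x$kernels, `[[`, character(1), "chain")
  if (!all(is.na(ch))) {
    cat("  chains:", paste(names(table(ch)), table(ch), sep = ":",
                           collapse = " "), "\n")
  }
  invisible(x)
}

n_kernels <- function(model) length(model$kernels)

#' Kernel centers of a model as a matrix
#'
#' @param model A `gmm_model`.
#' @return n x 3 numeric matrix of centers (Angstrom).
#' @export
kernel_centers <- function(model) {
  do.call(rbind, lapply(model$kernels, `[[`, "center"))
}

#' Evaluate the mixture density at a point
#'
#' Returns the weighted sum of the kernel Gaussian densities at `point`,
#' \eqn{\sum_i w_i N(x; \mu_i, \Sigma_i)}.
#'
#' @param model A `gmm_model`.
#' @param point Numeric 3-vector (Angstrom).
#' @return Non-negative density value.
#' @export
density_at <- function(model, point) {
  stopifnot(inherits(model, "gmm_model"), length(point) == 3)
  total <- 0
  for (i in seq_along(model$kernels)) {
    k <- model$kernels[[i]]
    dt <- det(k$cov)
    if (!is.finite(dt) || dt <= 0) {
      stop(sprintf("kernel %d has a singular covariance", i))
    }
    d <- point - k$center
    q <- sum(d * solve(k$cov, d))
    total <- total + k$weight * exp(-q / 2) / sqrt((2 * pi)^3 * dt)
  }
  total
}

#' Rigidly transform a kernel
#'
#' Applies `center' = R center + t`, `cov' = R cov R^T`. Weight and labels are
#' unchanged; covariance eigenvalues are preserved.
#'
#' @param k A `gmm_kernel`.
#' @param rotation 3x3 rotation matrix with determinant +1.
#' @param translation Numeric 3-vector (Angstrom).
#' @return The transformed kernel.
#' @export
transform_kernel <- function(k, rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(inherits(k, "gmm_kernel"), length(translation) == 3)
  if (!is_rotation(rotation)) {
    stop("rotation must be a proper orthonormal matrix (det = +1)")
  }
  k$center <- as.numeric(rotation %*% k$center + translation)
  k$cov <- (rotation %*% k$cov %*% t(rotation) +
              t(rotation %*% k$cov %*% t(rotation))) / 2
  k
}

#' Rigidly transform a whole model
#'
#' @inheritParams transform_kernel
#' @param model A `gmm_model`.
#' @export
transform_model <- function(model, rotation = diag(3),
                            translation = c(0, 0, 0)) {
  model$kernels <- lapply(model$kernels, transform_kernel, rotation = rotation,
                          translation = translation)
  model
}
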