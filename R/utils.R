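# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded internals (EM
#' initialisation, Monte-Carlo trajectories) do not disturb the caller's
#' random stream.
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Rotation matrix about an arbitrary axis (Rodrigues' formula)
#'
#' @param axis 3-vector, need not be normalized.
#' @param angle rotation angle in radians.
#' @return 3x3 rotation matrix.
#' @keywords internal
#' @export
rotation_matrix <- function(axis, angle) {
  stopifnot(length(axis) == 3, is.finite(angle))
  n <- sqrt(sum(axis^2))
  if (n < .Machine$double.eps) stop("rotation axis has zero length")
  a <- axis / n
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Rotation about the z axis by an angle in degrees
#' @noRd
rot_z <- function(deg) rotation_matrix(c(0, 0, 1), deg * pi / 180)

is_rotation <- function(R, tol = 1e-8) {
  is.matrix(R) && all(dim(R) == c(3, 3)) &&
    max(abs(crossprod(R) - diag(3))) < tol && abs(det(R) - 1) < tol
}

#' Symmetrize and check a covariance matrix
#' @noRd
check_spd <- function(S, what = "covariance") {
  S <- (S + t(S)) / 2
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop(sprintf("%s matrix is not positive definite", what))
  S
}

# Standard atomic masses (Da) used for mass-weighted GMM fitting.
.atomic_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, SE = 78.971, FE = 55.845, ZN = 65.38, MG = 24.305
)

#' Look up atomic masses by element symbol
#'
#' Unknown elements fall back to carbon mass with a warning.
#' @noRd
element_masses <- function(elements) {
  el <- toupper(trimws(elements))
  m <- .atomic_masses[el]
  if (anyNA(m)) {
    warning("unknown element(s) ", paste(unique(el[is.na(m)]), collapse = ", "),
            "; using carbon mass")
    m[is.na(m)] <- .atomic_masses[["C"]]
  }
  unname(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
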