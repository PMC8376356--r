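# Preparation of reference hexamer mixture models from atomic structures.
#
# The workflow mirrors how reference conformations are built for AFM-guided
# modeling of a hexameric disaggregase: superpose one monomer onto each chain
# of a reference hexamer (closed-ring and spiral analogues), trim flexible
# N-terminal regions, orient the complex so the C-terminal face points to the
# substrate plane, optionally rotate about z to match the seam seen in the
# image, and fit three mass-weighted Gaussian kernels per chain.

#' Load an atomic structure as a flat atom table
#'
#' Parses PDB or mmCIF via bio3d and returns an `atom_cloud`: a data frame
#' with columns `x, y, z, mass, chain, resno, elety`. Hetero atoms are
#' excluded by default.
#'
#' @param path PDB (`.pdb`/`.ent`) or mmCIF (`.cif`) file.
#' @param chains Optional character vector of chain IDs to keep.
#' @param resno_keep Optional integer vector of residue numbers to keep.
#' @param resno_drop Optional integer vector of residue numbers to drop
#'   (applied after `resno_keep`), e.g. `1:165` to delete an N-terminal
#'   region.
#' @param het Keep hetero atoms? Default `FALSE`.
#' @return An `atom_cloud` data frame.
#' @export
load_atoms <- function(path, chains = NULL, resno_keep = NULL,
                       resno_drop = NULL, het = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- if (grepl("\\.cif$", path, ignore.case = TRUE)) {
    bio3d::read.cif(path)
  } else {
    bio3d::read.pdb(path)
  }
  at <- pdb$atom
  if (!het) at <- at[at$type == "ATOM", , drop = FALSE]
  if (!is.null(chains)) {
    missing <- setdiff(chains, unique(at$chain))
    if (length(missing)) {
      stop("chain(s) ", paste(missing, collapse = ", "),
           " not in structure; available: ",
           paste(sort(unique(at$chain)), collapse = ", "))
    }
    at <- at[at$chain %in% chains, , drop = FALSE]
  }
  if (!is.null(resno_keep)) at <- at[at$resno %in% resno_keep, , drop = FALSE]
  if (!is.null(resno_drop)) at <- at[!at$resno %in% resno_drop, , drop = FALSE]
  if (nrow(at) == 0) stop("no atoms left after filtering")
  el <- at$elesy
  if (is.null(el) || all(is.na(el)) || all(el == "")) {
    el <- substr(trimws(at$elety), 1, 1)
  }
  cloud <- data.frame(x = at$x, y = at$y, z = at$z,
                      mass = element_masses(el),
                      chain = at$chain, resno = at$resno, elety = at$elety,
                      stringsAsFactors = FALSE)
  class(cloud) <- c("atom_cloud", "data.frame")
  cloud
}

atom_xyz <- function(cloud) as.matrix(cloud[, c("x", "y", "z")])

#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Least-squares rotation + translation mapping `mobile` onto `reference`,
#' with the SVD determinant correction so the returned rotation is proper
#' (det = +1).
#'
#' @param mobile,reference n x 3 coordinate matrices, paired row by row,
#'   n >= 3.
#' @return List with `rotation` (3x3), `translation` (3-vector) such that
#'   `mobile %*% t(rotation) + translation` superposes onto `reference`, and
#'   `rmsd` (Angstrom).
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  stopifnot(ncol(mobile) == 3, ncol(reference) == 3)
  if (nrow(mobile) != nrow(reference)) stop("point counts differ")
  if (nrow(mobile) < 3) stop("need at least 3 paired points")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  H <- crossprod(A, B)
  sv <- svd(H)
  if (sv$d[2] < 1e-10) stop("rank-deficient point sets; superposition undefined")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_vec <- cr - as.numeric(R %*% cm)
  fitted <- sweep(A %*% t(R), 2, cr, "+")
  rmsd <- sqrt(mean(rowSums((fitted - reference)^2)))
  list(rotation = R, translation = t_vec, rmsd = rmsd)
}

apply_rigid <- function(cloud, rotation, translation) {
  xyz <- atom_xyz(cloud) %*% t(rotation)
  xyz <- sweep(xyz, 2, translation, "+")
  cloud$x <- xyz[, 1]; cloud$y <- xyz[, 2]; cloud$z <- xyz[, 3]
  cloud
}

#' Assemble a hexamer by superposing one monomer onto each reference chain
#'
#' For each of the six chains of `reference_hexamer`, the C-alpha atoms of
#' `monomer` named in `correspondence` are superposed (Kabsch) onto the
#' corresponding reference C-alphas, and the whole monomer is transformed
#' accordingly. Output chains are relabeled A..F in the order of the sorted
#' reference chain IDs.
#'
#' @param monomer `atom_cloud` of a single chain.
#' @param reference_hexamer `atom_cloud` with exactly six chains.
#' @param correspondence Either a two-column data frame
#'   (`mono_resno`, `ref_resno`) used for every chain, or a named list of such
#'   data frames keyed by reference chain ID.
#' @return `atom_cloud` of the assembled hexamer (chains A..F); attribute
#'   `"rmsd"` holds the per-chain superposition RMSDs.
#' @export
assemble_hexamer <- function(monomer, reference_hexamer, correspondence) {
  ref_chains <- sort(unique(reference_hexamer$chain))
  if (length(ref_chains) != 6) {
    stop("reference must have exactly 6 chains, found ", length(ref_chains))
  }
  ca_of <- function(cloud, resnos) {
    ca <- cloud[cloud$elety == "CA", , drop = FALSE]
    ca <- ca[match(resnos, ca$resno), , drop = FALSE]
    if (anyNA(ca$x)) stop("correspondence names residues without CA atoms")
    atom_xyz(ca)
  }
  out <- vector("list", 6)
  rmsds <- numeric(6)
  for (i in seq_along(ref_chains)) {
    rc <- ref_chains[i]
    map <- if (is.data.frame(correspondence)) correspondence else {
      correspondence[[rc]] %||% stop("no correspondence for chain ", rc)
    }
    ref_chain <- reference_hexamer[reference_hexamer$chain == rc, ,
                                   drop = FALSE]
    fit <- kabsch_superpose(ca_of(monomer, map[[1]]),
                            ca_of(ref_chain, map[[2]]))
    placed <- apply_rigid(monomer, fit$rotation, fit$translation)
    placed$chain <- LETTERS[i]
    out[[i]] <- placed
    rmsds[i] <- fit$rmsd
  }
  hex <- do.call(rbind, out)
  class(hex) <- c("atom_cloud", "data.frame")
  attr(hex, "rmsd") <- stats::setNames(rmsds, LETTERS[1:6])
  hex
}

#' Rotate a structure about z and optionally flip it face-down
#'
#' Rotates the cloud about the vertical (z) axis through its centroid by
#' `z_angle` degrees; this aligns the seam of the model with the seam visible
#' in the AFM image. If `bottom_resnos` is given and those residues currently
#' sit higher (larger mean z) than the rest, the cloud is flipped 180 degrees
#' about x so that they face the substrate — e.g. C-terminal regions facing
#' the bottom, as adsorbed molecules present them.
#'
#' @param cloud An `atom_cloud`.
#' @param z_angle Rotation about z in degrees.
#' @param bottom_resnos Optional residue numbers that must end up at the
#'   bottom.
#' @return The transformed `atom_cloud`.
#' @export
orient_and_zrotate <- function(cloud, z_angle = 0, bottom_resnos = NULL) {
  ctr <- colMeans(atom_xyz(cloud))
  rot_about <- function(cl, R) {
    apply_rigid(cl, R, ctr - as.numeric(R %*% ctr))
  }
  if (!is.null(bottom_resnos)) {
    sel <- cloud$resno %in% bottom_resnos
    if (any(sel) && any(!sel) &&
        mean(cloud$z[sel]) > mean(cloud$z[!sel])) {
      cloud <- rot_about(cloud, rotation_matrix(c(1, 0, 0), pi))
    }
  }
  cloud <- rot_about(cloud, rot_z(z_angle))
  cloud
}

#' Fit three labeled kernels per chain of a hexamer
#'
#' Runs mass-weighted EM ([fit_gmm_em()]) independently on each chain and
#' assigns each kernel the role (`head`/`body`/`tail`) whose residue range
#' contributes the plurality of its responsibility-weighted mass. Per-chain
#' kernel weights are rescaled so they sum to the chain's mass fraction;
#' model weights therefore sum to 1 overall.
#'
#' @param cloud `atom_cloud` with six chains.
#' @param kernels_per_chain Kernels per chain; 3 for the head/body/tail
#'   scheme.
#' @param domain_ranges Named list mapping each role to an integer vector of
#'   residue numbers, e.g.
#'   `list(head = 400:550, body = c(166:399, 551:770), tail = 771:860)`.
#' @param seed Integer seed for the EM initialisation.
#' @return A `gmm_model` with `6 * kernels_per_chain` labeled kernels,
#'   ordered by chain (A..F) and, within a chain, head, body, tail.
#' @export
chainwise_gmm <- function(cloud, kernels_per_chain = 3, domain_ranges, seed = 1L) {
  chains <- sort(unique(cloud$chain))
  if (length(chains) != 6) stop("expected 6 chains, found ", length(chains))
  total_mass <- sum(cloud$mass)
  role_order <- c("head", "body", "tail")
  kernels <- list()
  for (ci in seq_along(chains)) {
    cc <- cloud[cloud$chain == chains[ci], , drop = FALSE]
    if (nrow(cc) < kernels_per_chain) {
      stop("chain ", chains[ci], " has fewer atoms than kernels")
    }
    fit <- fit_gmm_em(atom_xyz(cc), weights = cc$mass, k = kernels_per_chain,
                      seed = seed + ci)
    resp <- attr(fit, "responsibilities")
    if (is.null(resp)) resp <- matrix(1, nrow(cc), 1)
    roles <- vapply(seq_len(kernels_per_chain), function(j) {
      mass_by_role <- vapply(names(domain_ranges), function(rl) {
        sel <- cc$resno %in% domain_ranges[[rl]]
        sum(resp[sel, j] * cc$mass[sel])
      }, numeric(1))
      names(domain_ranges)[which.max(mass_by_role)]
    }, character(1))
    frac <- sum(cc$mass) / total_mass
    ks <- lapply(seq_len(kernels_per_chain), function(j) {
      k <- fit$kernels[[j]]
      gmm_kernel(k$weight * frac, k$center, k$cov,
                 chain = LETTERS[ci], role = roles[j])
    })
    ord <- order(match(roles, role_order))
    kernels <- c(kernels, ks[ord])
  }
  gmm_model(kernels, name = "hexamer_gmm",
            provenance = sprintf("chainwise EM, %d kernels/chain",
                                 kernels_per_chain))
}
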