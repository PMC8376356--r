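# Multi-trajectory orchestration: candidate selection, cross-start
# convergence pairing, rigid fitting and the two-phase protocol.
#
# The full-scale protocol runs twenty 1.5e6-step trajectories per phase (ten
# from each reference start); all counts and lengths scale down for testing.

#' Select the best models from a set of trajectories by SSIM quantile
#'
#' Pools every snapshot of the given trajectories and retains the models in
#' the top fraction `q` by SSIM, i.e. those at or above the empirical
#' `1 - q` quantile (default q = 0.2: the best 20%).
#'
#' @param trajectories List of `gmm_trajectory` objects.
#' @param q Retained fraction, in (0, 1); default 0.2.
#' @return A `candidate_set`: data frame-like list with `models`, `ssim`,
#'   `source` (trajectory index).
#' @export
select_candidates <- function(trajectories, q = 0.2) {
  stopifnot(q > 0, q < 1)
  if (length(trajectories) == 0) stop("no trajectories given")
  models <- list(); ssims <- numeric(0); src <- integer(0)
  for (ti in seq_along(trajectories)) {
    for (sn in trajectories[[ti]]$snapshots) {
      models[[length(models) + 1]] <- sn$model
      ssims <- c(ssims, sn$ssim)
      src <- c(src, ti)
    }
  }
  thr <- stats::quantile(ssims, 1 - q, names = FALSE)
  keep <- ssims >= thr
  structure(list(models = models[keep], ssim = ssims[keep],
                 source = src[keep]),
            class = "candidate_set")
}

#' Rigid fit on kernel centers, then density correlation
#'
#' Kabsch-superposes the kernel centers of `a` onto those of `b` (index
#' correspondence), applies the transform to `a` and returns the density
#' cross-correlation of the superposed pair.
#'
#' @param a,b `gmm_model`s with equal kernel counts.
#' @return List with `rotation`, `translation`, `rmsd` (of the centers) and
#'   `cc` ([cc3d_density()] after fitting).
#' @export
kernelcenter_fit <- function(a, b) {
  if (n_kernels(a) != n_kernels(b)) stop("kernel counts differ")
  fit <- kabsch_superpose(kernel_centers(a), kernel_centers(b))
  a2 <- transform_model(a, fit$rotation, fit$translation)
  list(rotation = fit$rotation, translation = fit$translation,
       rmsd = fit$rmsd, cc = cc3d_density(a2, b))
}

# pack/unpack a rigid transform as 6 parameters (rotation vector + shift)
rigid_from_par <- function(par) {
  ang <- sqrt(sum(par[1:3]^2))
  R <- if (ang < 1e-12) diag(3) else rotation_matrix(par[1:3], ang)
  list(R = R, t = par[4:6])
}

#' Refined density correlation after local rigid optimization
#'
#' Starts from the kernel-center fit and locally maximizes
#' [cc3d_density()] over the six rigid degrees of freedom (Nelder-Mead on a
#' rotation-vector + translation parameterization, applied about the center
#' of the pre-fitted model). The result is never below the center-fit
#' correlation. This is the reported CC3D_density between two conformations.
#'
#' @param a,b `gmm_model`s with equal kernel counts.
#' @return Refined correlation coefficient.
#' @export
cc3d_refined <- function(a, b) {
  base <- kernelcenter_fit(a, b)
  a0 <- transform_model(a, base$rotation, base$translation)
  ctr <- colMeans(kernel_centers(a0))
  objective <- function(par) {
    tr <- rigid_from_par(par)
    shifted <- transform_model(a0, tr$R, ctr - as.numeric(tr$R %*% ctr) + tr$t)
    -cc3d_density(shifted, b)
  }
  opt <- stats::optim(rep(0, 6), objective, method = "Nelder-Mead",
                      control = list(maxit = 400, reltol = 1e-10))
  max(-opt$value, base$cc)
}

#' Most similar cross-start pair of candidate models
#'
#' Exhaustively compares every model of `setR` with every model of `setS`
#' using [kernelcenter_fit()] and returns the pair with the highest density
#' correlation — the most converged solutions from the two different starts.
#'
#' @param setR,setS `candidate_set`s (from trajectories started at R and S).
#' @return List with `modelR`, `modelS`, `cc`, and the winning indices.
#' @export
convergence_pairing <- function(setR, setS) {
  if (!length(setR$models) || !length(setS$models)) {
    stop("both candidate sets must be nonempty")
  }
  best <- list(cc = -Inf)
  for (i in seq_along(setR$models)) {
    for (j in seq_along(setS$models)) {
      cc <- kernelcenter_fit(setR$models[[i]], setS$models[[j]])$cc
      if (cc > best$cc) {
        best <- list(modelR = setR$models[[i]], modelS = setS$models[[j]],
                     cc = cc, i = i, j = j,
                     ssimR = setR$ssim[i], ssimS = setS$ssim[j])
      }
    }
  }
  best
}

run_phase <- function(startR, startS, image, restraints, config, n_traj,
                      refsR, refsS, q, seed_base) {
  half <- n_traj %/% 2
  run_from <- function(start, refA, refB, offset) {
    lapply(seq_len(half), function(i) {
      cfg <- config
      cfg$seed <- as.integer(seed_base + offset + i)
      rs <- build_restraints(refA, refB, anchor_model = start,
                             config = attr(restraints, "config") %||%
                               default_restraint_config())
      run_trajectory(start, image, rs, cfg)
    })
  }
  trajR <- run_from(startR, refsR, refsS, 0L)
  trajS <- run_from(startS, refsR, refsS, 1000L)
  list(trajR = trajR, trajS = trajS,
       candR = select_candidates(trajR, q),
       candS = select_candidates(trajS, q))
}

#' Two-phase multi-trajectory reconstruction protocol
#'
#' Phase 1 runs `n_traj` trajectories (half from `startR`, half from
#' `startS`), selects the top SSIM quantile from each half and picks the most
#' similar cross-start pair. Phase 2 restarts the same number of trajectories
#' from the two phase-1 winners and repeats the selection and pairing,
#' returning the final converged pair. Defaults at full scale are 20
#' trajectories of 1.5e6 steps each; scale down via `n_traj` and
#' `config$steps`.
#'
#' @param startR,startS Reference starting `gmm_model`s (closed-ring and
#'   spiral analogues).
#' @param image Target `afm_image`.
#' @param restraints A `restraint_set` built from `startR` and `startS`
#'   (phantoms are re-anchored to each phase's starting model internally).
#' @param config An `mc_config` (per-trajectory steps etc.).
#' @param n_traj Total trajectories per phase (even; default 20).
#' @param q SSIM selection quantile (default 0.2).
#' @return List with `modelR`, `modelS`, `cc` (final pair), `cc_start`
#'   (correlation of the two starts), `phase1` pair info, and the candidate
#'   SSIMs.
#' @export
two_phase_protocol <- function(startR, startS, image, restraints, config,
                               n_traj = 20, q = 0.2) {
  stopifnot(n_traj >= 2, n_traj %% 2 == 0)
  cc_start <- kernelcenter_fit(startR, startS)$cc
  p1 <- run_phase(startR, startS, image, restraints, config, n_traj,
                  startR, startS, q, config$seed)
  pair1 <- convergence_pairing(p1$candR, p1$candS)
  p2 <- run_phase(pair1$modelR, pair1$modelS, image, restraints, config,
                  n_traj, startR, startS, q, config$seed + 2000L)
  pair2 <- convergence_pairing(p2$candR, p2$candS)
  list(modelR = pair2$modelR, modelS = pair2$modelS, cc = pair2$cc,
       cc_start = cc_start, phase1 = pair1,
       ssimR = pair2$ssimR, ssimS = pair2$ssimS)
}
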