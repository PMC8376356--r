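# Two-step annealed Metropolis Monte-Carlo sampling against one AFM image.
#
# Each proposal randomly moves one kernel.  Acceptance is gated twice with a
# shared annealed temperature:
#   stage 1 - hard rejection if phantom connectivity is violated, else
#             Metropolis on the change in the restraint score;
#   stage 2 - only if stage 1 accepted: render the candidate pseudo-AFM
#             image and Metropolis on -scale * delta(SSIM).  SSIM is scaled
#             (x 10000 by default) so one annealing scheme serves both
#             stages.
# Rejection at either stage restores the previous model.

#' Monte-Carlo configuration
#'
#' @param steps Number of MC proposals.
#' @param sigma_t Translation move standard deviation (Angstrom).
#' @param sigma_r Covariance-rotation move standard deviation (degrees).
#' @param ssim_scale Scale applied to SSIM so the image term shares the
#'   restraint-score temperature (default 10000).
#' @param t_min,t_max Annealing temperature bounds (defaults 0.2 and 1.0).
#' @param anneal_period Period of the cosine annealing schedule, in
#'   proposals.
#' @param snapshot_interval Steps between stored snapshots.
#' @param seed Integer RNG seed; trajectories are bit-reproducible given the
#'   seed.
#' @param level Rendering level passed to [render_pseudo_afm()].
#' @param mask Optional `afm_mask` used in the SSIM evaluation.
#' @return An `mc_config` list.
#' @export
mc_config <- function(steps = 10000, sigma_t = 1.5, sigma_r = 5,
                      ssim_scale = 10000, t_min = 0.2, t_max = 1.0,
                      anneal_period = 1e5, snapshot_interval = 1000,
                      seed = 1L, level = 2, mask = NULL) {
  stopifnot(steps >= 0, sigma_t > 0, sigma_r > 0, t_min > 0, t_min <= t_max,
            anneal_period > 0, snapshot_interval >= 1)
  structure(list(steps = as.integer(steps), sigma_t = sigma_t,
                 sigma_r = sigma_r, ssim_scale = ssim_scale, t_min = t_min,
                 t_max = t_max, anneal_period = anneal_period,
                 snapshot_interval = as.integer(snapshot_interval),
                 seed = as.integer(seed), level = level, mask = mask),
            class = "mc_config")
}

#' Annealing temperature at a given step
#'
#' Cosine-periodic schedule
#' `T(t) = t_min + (t_max - t_min) (1 + cos(2 pi t / period)) / 2`;
#' starts at `t_max`, reaches `t_min` at half a period.
#'
#' @param step Step index (0-based).
#' @param config An `mc_config`.
#' @return Temperature in `[t_min, t_max]`.
#' @export
temperature_at <- function(step, config) {
  config$t_min + (config$t_max - config$t_min) *
    (1 + cos(2 * pi * step / config$anneal_period)) / 2
}

#' Metropolis acceptance
#'
#' Accepts with probability `min(1, exp(-delta / temp))`; `delta` is oriented
#' so that an improvement gives `delta <= 0` (always accepted).
#'
#' @param delta Score change (improvement <= 0).
#' @param temp Temperature, > 0.
#' @return Logical: accept the move? (Consumes one uniform draw only when
#'   `delta > 0`.)
#' @export
metropolis_accept <- function(delta, temp) {
  if (temp <= 0) stop("temperature must be positive")
  if (delta <= 0) return(TRUE)
  stats::runif(1) < exp(-delta / temp)
}

# initial sampler state for a model
mc_state <- function(model, image, restraints, config) {
  rendered <- render_pseudo_afm(model, image, level = config$level)
  overlaps <- pair_overlaps(model, restraints)
  list(model = model,
       rotations = rep(list(diag(3)), n_kernels(model)),
       overlaps = overlaps,
       restraint_score = sum(pair_score(overlaps, restraints$pairs$obar,
                                        restraints$pairs$k_att,
                                        restraints$pairs$k_rep)),
       ssim = ssim(rendered, image, mask = config$mask),
       step = 0L)
}

#' Propose a single-kernel random move
#'
#' Picks one kernel uniformly; with probability 1/2 translates its center by
#' an isotropic Gaussian step (`sigma_t`), otherwise rotates its covariance
#' about the kernel center by a Gaussian angle (`sigma_r`) about a uniformly
#' random axis. Covariance eigenvalues are preserved by rotation moves.
#'
#' @param state Sampler state (internal; see [run_trajectory()]).
#' @param config An `mc_config`.
#' @return List with the modified kernel index `k`, new `kernel`, new
#'   accumulated `rotation`, and move type.
#' @export
propose_move <- function(state, config) {
  k_idx <- sample.int(n_kernels(state$model), 1)
  k <- state$model$kernels[[k_idx]]
  rot <- state$rotations[[k_idx]]
  if (stats::runif(1) < 0.5) {
    k$center <- k$center + stats::rnorm(3, 0, config$sigma_t)
    type <- "translate"
  } else {
    ax <- stats::rnorm(3)
    ang <- stats::rnorm(1, 0, config$sigma_r * pi / 180)
    R <- rotation_matrix(ax, ang)
    k$cov <- (R %*% k$cov %*% t(R) + t(R %*% k$cov %*% t(R))) / 2
    rot <- R %*% rot
    type <- "rotate"
  }
  list(k = k_idx, kernel = k, rotation = rot, type = type)
}

#' One two-step Monte-Carlo update
#'
#' @param state Sampler state from the previous step.
#' @param image Target `afm_image`.
#' @param restraints A `restraint_set`.
#' @param config An `mc_config`.
#' @param counters Environment with counters `proposals`, `stage1_accept`,
#'   `renders`, `stage2_accept` (optional).
#' @return Updated state.
#' @export
mc_step <- function(state, image, restraints, config, counters = NULL) {
  temp <- temperature_at(state$step, config)
  mv <- propose_move(state, config)
  if (!is.null(counters)) counters$proposals <- counters$proposals + 1L
  state$step <- state$step + 1L

  cand_model <- state$model
  cand_model$kernels[[mv$k]] <- mv$kernel
  cand_rot <- state$rotations
  cand_rot[[mv$k]] <- mv$rotation

  # stage 1: hard connectivity constraint, then Metropolis on the restraint
  # score change over the affected pairs only
  touched_ph <- which(vapply(restraints$phantoms, function(p) {
    p$i == mv$k || p$j == mv$k
  }, logical(1)))
  if (length(touched_ph)) {
    conn <- connectivity_ok(cand_model, restraints, rotations = cand_rot,
                            which_pairs = touched_ph)
    if (!conn$ok) return(state)
  }
  rows <- which(restraints$pairs$i == mv$k | restraints$pairs$j == mv$k)
  new_o <- pair_overlaps(cand_model, restraints, rows)
  d_restraint <-
    sum(pair_score(new_o, restraints$pairs$obar[rows],
                   restraints$pairs$k_att[rows],
                   restraints$pairs$k_rep[rows])) -
    sum(pair_score(state$overlaps[rows], restraints$pairs$obar[rows],
                   restraints$pairs$k_att[rows],
                   restraints$pairs$k_rep[rows]))
  if (!metropolis_accept(d_restraint, temp)) return(state)
  if (!is.null(counters)) counters$stage1_accept <- counters$stage1_accept + 1L

  # stage 2: render the candidate and Metropolis on the scaled SSIM change
  rendered <- render_pseudo_afm(cand_model, image, level = config$level)
  if (!is.null(counters)) counters$renders <- counters$renders + 1L
  new_ssim <- ssim(rendered, image, mask = config$mask)
  d_image <- -config$ssim_scale * (new_ssim - state$ssim)
  if (!metropolis_accept(d_image, temp)) return(state)
  if (!is.null(counters)) counters$stage2_accept <- counters$stage2_accept + 1L

  state$model <- cand_model
  state$rotations <- cand_rot
  state$overlaps[rows] <- new_o
  state$restraint_score <- state$restraint_score + d_restraint
  state$ssim <- new_ssim
  state
}

#' Run one annealed Monte-Carlo trajectory
#'
#' Executes `config$steps` two-step updates against `image`, snapshotting the
#' model every `config$snapshot_interval` steps (the initial model is always
#' snapshot 0; the final state is always included). Bit-reproducible given
#' `config$seed`.
#'
#' @param model Starting `gmm_model`.
#' @param image Target `afm_image`.
#' @param restraints A `restraint_set` (phantoms should be anchored to
#'   `model`; see [build_restraints()]).
#' @param config An `mc_config`.
#' @return A `gmm_trajectory`: list with `snapshots` (list of records:
#'   `step`, `model`, `restraint_score`, `ssim`, `temperature`), `log`
#'   (data frame of the same scalars), `counters`, and `config`.
#' @export
run_trajectory <- function(model, image, restraints, config) {
  stopifnot(inherits(model, "gmm_model"), inherits(image, "afm_image"),
            inherits(restraints, "restraint_set"),
            inherits(config, "mc_config"))
  with_seed(config$seed, {
    counters <- new.env(parent = emptyenv())
    counters$proposals <- 0L; counters$stage1_accept <- 0L
    counters$renders <- 0L; counters$stage2_accept <- 0L
    state <- mc_state(model, image, restraints, config)
    snap <- function(st) list(step = st$step, model = st$model,
                              restraint_score = st$restraint_score,
                              ssim = st$ssim,
                              temperature = temperature_at(st$step, config))
    snapshots <- list(snap(state))
    if (config$steps > 0) {
      for (t in seq_len(config$steps)) {
        state <- mc_step(state, image, restraints, config, counters)
        if (t %% config$snapshot_interval == 0 || t == config$steps) {
          last <- snapshots[[length(snapshots)]]
          if (last$step < state$step) {
            snapshots[[length(snapshots) + 1]] <- snap(state)
          }
        }
      }
    }
    log <- data.frame(
      step = vapply(snapshots, `[[`, numeric(1), "step"),
      restraint_score = vapply(snapshots, `[[`, numeric(1), "restraint_score"),
      ssim = vapply(snapshots, `[[`, numeric(1), "ssim"),
      temperature = vapply(snapshots, `[[`, numeric(1), "temperature"))
    structure(list(snapshots = snapshots, log = log,
                   counters = as.list(counters), config = config),
              class = "gmm_trajectory")
  })
}

#' @export
print.gmm_trajectory <- function(x, ...) {
  n <- length(x$snapshots)
  cat(sprintf("MC trajectory: %d steps, %d snapshots, final SSIM %.4f, final restraint score %.3f\n",
              x$config$steps, n, x$snapshots[[n]]$ssim,
              x$snapshots[[n]]$restraint_score))
  cat(sprintf("  acceptance: stage1 %d/%d, stage2 %d/%d renders\n",
              x$counters$stage1_accept, x$counters$proposals,
              x$counters$stage2_accept, x$counters$renders))
  invisible(x)
}

#' Write the per-snapshot log of a trajectory as TSV
#' @param traj A `gmm_trajectory`.
#' @param path Output TSV path.
#' @export
write_trajectory_log <- function(traj, path) {
  utils::write.table(traj$log, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
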