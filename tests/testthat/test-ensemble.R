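# Candidate selection, rigid fitting, convergence pairing, clustering.

# wrap a list of models (with ssim values) as a minimal trajectory so that
# select_candidates can be fed controlled inputs
fake_traj <- function(ssims, models = NULL) {
  if (is.null(models)) {
    base <- make_toy_hexamer()
    models <- lapply(seq_along(ssims), function(i) base)
  }
  snaps <- lapply(seq_along(ssims), function(i) {
    list(step = i, model = models[[i]], restraint_score = 0,
         ssim = ssims[i], temperature = 1)
  })
  structure(list(snapshots = snaps, log = NULL, counters = NULL,
                 config = NULL), class = "gmm_trajectory")
}

test_that("select_candidates keeps the top SSIM fraction q", {
  tr <- fake_traj(seq(0.1, 1.0, by = 0.1))
  sel <- select_candidates(list(tr), q = 0.2)
  expect_setequal(sel$ssim, c(0.9, 1.0))

  all_equal <- fake_traj(rep(0.7, 8))
  sel2 <- select_candidates(list(all_equal), q = 0.2)
  expect_equal(length(sel2$models), 8)

  expect_equal(formals(select_candidates)$q, 0.2)
  expect_error(select_candidates(list()), "no trajectories")

  # retained count is ceil(q N) up to ties
  withr::local_seed(71)
  tr3 <- fake_traj(runif(25))
  sel3 <- select_candidates(list(tr3), q = 0.2)
  expect_gte(length(sel3$models), ceiling(0.2 * 25) - 1)
  expect_lte(length(sel3$models), ceiling(0.2 * 25) + 1)
})

test_that("kernelcenter_fit recovers rigid copies and orders similarity", {
  withr::local_seed(72)
  a <- make_toy_hexamer()
  moved <- transform_model(a, rotation_matrix(c(0.3, 1, 2), 1.1),
                           c(30, -12, 8))
  fit <- kernelcenter_fit(moved, a)
  expect_equal(fit$cc, 1, tolerance = 1e-6)
  expect_equal(fit$rmsd, 0, tolerance = 1e-6)

  near <- perturb_model(a, sigma_t = 2, sigma_r = 0, seed = 4)
  far <- make_toy_hexamer(toy_spec("half-spiral"))
  cc_near <- kernelcenter_fit(near, a)$cc
  cc_far <- kernelcenter_fit(far, a)$cc
  expect_lt(cc_near, 1)
  expect_gt(cc_near, cc_far)

  # symmetric within fitting tolerance
  expect_equal(kernelcenter_fit(near, a)$cc, kernelcenter_fit(a, near)$cc,
               tolerance = 1e-6)
  expect_error(kernelcenter_fit(a, gmm_model(a$kernels[1:6])), "counts")
})

test_that("cc3d_refined only improves on the center fit and finds optima", {
  a <- make_toy_hexamer()
  expect_equal(cc3d_refined(a, a), 1, tolerance = 1e-9)

  b <- perturb_model(a, sigma_t = 3, sigma_r = 10, seed = 9)
  expect_gte(cc3d_refined(b, a), kernelcenter_fit(b, a)$cc - 1e-9)

  # a pure rigid motion of a model: the constructed optimum is CC = 1 and
  # refinement must find it from the center fit
  moved <- transform_model(b, rotation_matrix(c(1, 0, 1), 0.8), c(15, 5, -3))
  expect_equal(cc3d_refined(moved, b), 1, tolerance = 1e-3)

  # invariance under a common rigid transform of both models
  R <- rotation_matrix(c(0, 1, 0), 0.5); t_ <- c(4, 4, 4)
  expect_equal(cc3d_refined(transform_model(b, R, t_),
                            transform_model(a, R, t_)),
               cc3d_refined(b, a), tolerance = 1e-3)
})

test_that("convergence_pairing returns the argmax cross pair", {
  a <- make_toy_hexamer()
  b <- perturb_model(a, 3, 10, seed = 1)
  c_ <- perturb_model(a, 6, 20, seed = 2)
  setR <- structure(list(models = list(b, c_), ssim = c(0.8, 0.7),
                         source = c(1L, 2L)), class = "candidate_set")
  setS <- structure(list(models = list(c_, b, a), ssim = c(0.7, 0.9, 0.95),
                         source = c(1L, 2L, 3L)), class = "candidate_set")
  # setS contains an exact copy of setR member b: that pair wins with CC 1
  best <- convergence_pairing(setR, setS)
  expect_equal(best$cc, 1, tolerance = 1e-9)
  expect_equal(best$i, 1)
  expect_equal(best$j, 2)

  # permuting the sets does not change the winning correlation
  setS_perm <- structure(list(models = setS$models[c(3, 1, 2)],
                              ssim = setS$ssim[c(3, 1, 2)],
                              source = setS$source[c(3, 1, 2)]),
                         class = "candidate_set")
  expect_equal(convergence_pairing(setR, setS_perm)$cc, best$cc,
               tolerance = 1e-12)

  single <- structure(list(models = list(b), ssim = 0.5, source = 1L),
                      class = "candidate_set")
  pair1 <- convergence_pairing(single, single)
  expect_equal(pair1$i, 1); expect_equal(pair1$j, 1)
})

test_that("two constructed families cluster into 2 groups of 6", {
  withr::local_seed(73)
  fam1 <- lapply(1:6, function(i) {
    perturb_model(make_toy_hexamer(toy_spec("closed")), 1, 3, seed = i)
  })
  fam2 <- lapply(1:6, function(i) {
    perturb_model(make_toy_hexamer(toy_spec("half-spiral")), 1, 3,
                  seed = 100 + i)
  })
  rep <- cluster_models(c(fam1, fam2), voxel = 4, min_samples = 4)
  expect_equal(nrow(rep$clusters), 2)
  expect_setequal(rep$clusters$size, c(6, 6))
  expect_setequal(rep$clusters$rank, 1:2)
  # families were presented in blocks: assignments must respect the blocks
  expect_equal(length(unique(rep$assignments$cluster[1:6])), 1)
  expect_equal(length(unique(rep$assignments$cluster[7:12])), 1)
  expect_false(rep$assignments$cluster[1] == rep$assignments$cluster[7])
  # medians belong to their own family
  for (r in seq_len(2)) {
    med <- rep$clusters$median_model[r]
    cl <- rep$assignments$cluster[med]
    expect_equal(cl, rep$clusters$cluster[r])
  }
  expect_equal(formals(cluster_models)$min_samples, 4)
})

test_that("duplicating every model doubles cluster sizes, keeps medians", {
  withr::local_seed(74)
  fam1 <- lapply(1:4, function(i) {
    perturb_model(make_toy_hexamer(toy_spec("closed")), 1, 3, seed = i)
  })
  fam2 <- lapply(1:4, function(i) {
    perturb_model(make_toy_hexamer(toy_spec("open")), 1, 3, seed = 50 + i)
  })
  models <- c(fam1, fam2)
  rep1 <- cluster_models(models, voxel = 4, min_samples = 4)
  rep2 <- cluster_models(c(models, models), voxel = 4, min_samples = 4,
                         eps = rep1$eps)
  expect_equal(sort(rep2$clusters$size), sort(2 * rep1$clusters$size))
  # median positions in PC space coincide with the originals (embeddings are
  # sign/rotation-ambiguous between runs, so compare distances to members)
  expect_equal(nrow(rep2$clusters), nrow(rep1$clusters))
})

test_that("two-phase protocol mechanics: phases, selection, pairing", {
  # desk-size run checking the protocol plumbing; the convergence property
  # itself (final CC above the start-pair CC) is asserted at its proper
  # scale in the acceptance suite
  truthA <- make_toy_hexamer(toy_spec("closed"))
  startR <- perturb_model(truthA, 3, 10, seed = 21)
  startS <- perturb_model(truthA, 3, 10, seed = 22)
  image <- render_pseudo_afm(truthA)
  set <- build_restraints(startR, startS)
  cfg <- mc_config(steps = 1500, seed = 31, anneal_period = 150,
                   snapshot_interval = 300)
  res <- two_phase_protocol(startR, startS, image, set, cfg, n_traj = 2)
  expect_s3_class(res$modelR, "gmm_model")
  expect_s3_class(res$modelS, "gmm_model")
  expect_lte(res$cc, 1)
  expect_gt(res$cc, 0)
  expect_equal(res$cc_start, kernelcenter_fit(startR, startS)$cc,
               tolerance = 1e-12)
  expect_lte(res$ssimR, 1)
  expect_lte(res$ssimS, 1)
  expect_true(is.finite(res$phase1$cc))
  # full-scale defaults of the protocol
  expect_equal(formals(two_phase_protocol)$n_traj, 20)
  expect_equal(formals(two_phase_protocol)$q, 0.2)
})
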