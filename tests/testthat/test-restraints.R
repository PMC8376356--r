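# Overlap restraints: construction, asymmetric scoring, connectivity.

ref_pair <- function() {
  R <- make_toy_hexamer(toy_spec("closed"))
  S <- make_toy_hexamer(toy_spec("spiral"))
  list(R = R, S = S, set = build_restraints(R, S))
}

test_that("reference overlaps are the mean of the two initial models", {
  fx <- ref_pair()
  p <- fx$set$pairs
  for (r in sample(nrow(p), 8)) {
    oR <- kernel_overlap(fx$R$kernels[[p$i[r]]], fx$R$kernels[[p$j[r]]])
    oS <- kernel_overlap(fx$S$kernels[[p$i[r]]], fx$S$kernels[[p$j[r]]])
    expect_equal(p$obar[r], (oR + oS) / 2, tolerance = 1e-12)
  }
})

test_that("default hexamer scheme has 36 pairs in the documented classes", {
  fx <- ref_pair()
  p <- fx$set$pairs
  expect_equal(nrow(p), 36)
  counts <- table(p$class)
  expect_equal(counts[["intra"]], 18)
  # one of each interchain class crosses the A-F seam
  expect_equal(counts[["seam"]], 3)
  expect_equal(counts[["body-body"]], 5)
  expect_equal(counts[["tail-tail"]], 5)
  expect_equal(counts[["head-head"]], 5)
  key <- paste(pmin(p$i, p$j), pmax(p$i, p$j))
  expect_false(anyDuplicated(key) > 0)
})

test_that("A-F pairs are seam class with weakened attraction", {
  fx <- ref_pair()
  p <- fx$set$pairs
  ch <- vapply(fx$R$kernels, `[[`, character(1), "chain")
  rl <- vapply(fx$R$kernels, `[[`, character(1), "role")
  seam_bb <- p[ch[p$i] != ch[p$j] &
                 rl[p$i] == "body" & rl[p$j] == "body" &
                 (ch[p$i] == "F" | ch[p$j] == "F") &
                 (ch[p$i] == "A" | ch[p$j] == "A"), ]
  expect_equal(nrow(seam_bb), 1)
  expect_equal(seam_bb$class, "seam")
  cfg <- default_restraint_config()
  expect_lt(seam_bb$k_att, cfg$classes$`body-body`$k_att)
  expect_equal(seam_bb$k_att,
               cfg$classes$`body-body`$k_att * cfg$seam_att_scale)
  expect_equal(seam_bb$k_rep, cfg$classes$`body-body`$k_rep)
})

test_that("pair_score is an asymmetric harmonic with minimum at obar", {
  expect_equal(pair_score(0.5, 0.5, 100, 400), 0)
  expect_equal(pair_score(0.4, 0.5, 100, 400), 1.0)   # attraction side
  expect_equal(pair_score(0.6, 0.5, 100, 400), 4.0)   # repulsion side
})

test_that("total score is zero at the averaged reference and rigid-invariant", {
  # with R = S the averaged overlaps are the model's own: exact zero
  m <- make_toy_hexamer()
  set_self <- build_restraints(m, m)
  expect_equal(total_restraint_score(m, set_self), 0)

  fx <- ref_pair()
  s0 <- total_restraint_score(fx$R, fx$set)
  moved <- transform_model(fx$R, rotation_matrix(c(1, 1, 0), 0.7),
                           c(20, -5, 12))
  expect_equal(total_restraint_score(moved, fx$set), s0, tolerance = 1e-9)
})

test_that("R and S score equally when curvatures are symmetric", {
  R <- make_toy_hexamer(toy_spec("closed"))
  S <- make_toy_hexamer(toy_spec("spiral"))
  cfg <- default_restraint_config()
  for (cl in names(cfg$classes)) {
    cfg$classes[[cl]]$k_att <- cfg$classes[[cl]]$k_rep
  }
  cfg$seam_att_scale <- 1
  set <- build_restraints(R, S, config = cfg)
  expect_equal(total_restraint_score(R, set), total_restraint_score(S, set),
               tolerance = 1e-9)
})

test_that("perturbing one kernel changes only the terms involving it", {
  fx <- ref_pair()
  p <- fx$set$pairs
  per_pair <- function(model) {
    o <- vapply(seq_len(nrow(p)), function(r) {
      kernel_overlap(model$kernels[[p$i[r]]], model$kernels[[p$j[r]]])
    }, numeric(1))
    pair_score(o, p$obar, p$k_att, p$k_rep)
  }
  before <- per_pair(fx$R)
  moved <- fx$R
  moved$kernels[[7]]$center <- moved$kernels[[7]]$center + c(2, 0, 0)
  after <- per_pair(moved)
  involved <- p$i == 7 | p$j == 7
  expect_true(any(abs(after[involved] - before[involved]) > 0))
  expect_equal(after[!involved], before[!involved], tolerance = 1e-14)
  expect_equal(total_restraint_score(moved, fx$set), sum(after),
               tolerance = 1e-10)
})

test_that("connectivity passes untouched models and flags 6 A separations", {
  m <- make_toy_hexamer()
  set <- build_restraints(m, m)
  res <- connectivity_ok(m, set)
  expect_true(res$ok)
  expect_equal(nrow(res$violations), 0)

  # translate one body kernel 6 A: its phantom pairs separate by 6 > 5
  moved <- m
  idx <- set$phantoms[[1]]$i
  moved$kernels[[idx]]$center <- moved$kernels[[idx]]$center + c(6, 0, 0)
  res2 <- connectivity_ok(moved, set)
  expect_false(res2$ok)
  expect_true(all(res2$violations$condition == "separation"))
  expect_equal(max(res2$violations$value), 6, tolerance = 1e-9)
})

test_that("a rotation can break containment while separation stays small", {
  # construct a two-kernel chain-like pair with an off-center anchor, then
  # rotate one kernel so the anchor leaves the partner's ellipsoid
  k1 <- gmm_kernel(1, c(0, 0, 0), diag(c(100, 1, 1)), chain = "A",
                   role = "head")
  k2 <- gmm_kernel(1, c(14, 0, 0), diag(c(100, 1, 1)), chain = "A",
                   role = "body")
  base <- gmm_model(list(k1, k2))
  set <- structure(list(
    pairs = data.frame(i = 1, j = 2, obar = kernel_overlap(k1, k2),
                       k_att = 100, k_rep = 100, class = "intra"),
    phantoms = list(list(i = 1, j = 2,
                         offset_i = c(7, 0, 0), offset_j = c(-7, 0, 0))),
    max_separation = 5, m_contain = 3), class = "restraint_set")
  expect_true(connectivity_ok(base, set)$ok)

  # rotate kernel 1 by 40 degrees about z: its phantom swings to
  # 7 (cos 40, sin 40, 0); separation 14 sin(20 deg) = 4.79 A stays under
  # the 5 A limit, but the 4.5 A lateral excursion leaves the 3-sigma
  # ellipsoids (sd 1 A across the long axis) of both kernels
  rot <- list(rotation_matrix(c(0, 0, 1), 40 * pi / 180), diag(3))
  pos_i <- base$kernels[[1]]$center + as.numeric(rot[[1]] %*% c(7, 0, 0))
  sep <- sqrt(sum((pos_i - (base$kernels[[2]]$center + c(-7, 0, 0)))^2))
  expect_lt(sep, 5)  # geometry sanity: separation below the limit
  res <- connectivity_ok(base, set, rotations = rot)
  expect_false(res$ok)
  expect_equal(res$violations$condition, "containment")
})

test_that("restraint sets round-trip through JSON", {
  fx <- ref_pair()
  path <- tempfile(fileext = ".json")
  write_restraints(fx$set, path)
  back <- read_restraints(path)
  expect_equal(back$pairs$obar, fx$set$pairs$obar, tolerance = 1e-12)
  expect_equal(back$max_separation, 5)
  expect_equal(length(back$phantoms), length(fx$set$phantoms))
  expect_equal(back$phantoms[[3]]$offset_i, fx$set$phantoms[[3]]$offset_i,
               tolerance = 1e-12)
})
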