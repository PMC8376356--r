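# Empirical kernel-position restraints.
#
# Plausibility of a candidate model is scored by asymmetric harmonic
# restraints on pairwise kernel overlaps.  Each restrained pair (i, j) has a
# reference overlap obar equal to the *average* of its overlaps in the two
# reference conformations (closed-ring R and spiral S), so each term is at
# its minimum halfway between the two references:
#   score = k_att (o - obar)^2  if o < obar   (drifted apart: attraction)
#           k_rep (o - obar)^2  if o > obar   (clashing: repulsion)
# Pair classes follow the qualitative scheme: intra-chain pairs strongest,
# neighboring body-body next, tail-tail repulsion like body-body but weaker
# attraction, head-head (coiled-coil) least restricted, and pairs across the
# A-F seam get additionally weakened attraction.  Connectivity of the
# monomer is enforced separately by phantom-particle pairs at intra-chain
# kernel intersections: the two phantoms of a pair ride rigidly with their
# kernels, must stay within 5 Angstrom of each other, and must each remain
# inside the overlap region of both kernels.

#' Default restraint class configuration
#'
#' Curvatures per pair class (`k_att`, `k_rep`), the seam chain pair with its
#' attraction scale, the phantom separation limit (Angstrom) and containment
#' level (Mahalanobis).
#' @return Nested list of parameters; pass (possibly modified) to
#'   [build_restraints()].
#' @export
default_restraint_config <- function() {
  list(
    classes = list(
      intra       = list(k_att = 2000, k_rep = 2000),
      `body-body` = list(k_att = 500,  k_rep = 500),
      `tail-tail` = list(k_att = 250,  k_rep = 500),
      `head-head` = list(k_att = 100,  k_rep = 100)
    ),
    seam_chains = c("A", "F"),
    seam_att_scale = 0.2,
    max_separation = 5,
    m_contain = 3
  )
}

kernel_index <- function(model, chain, role) {
  ch <- vapply(model$kernels, `[[`, character(1), "chain")
  rl <- vapply(model$kernels, `[[`, character(1), "role")
  i <- which(ch == chain & rl == role)
  if (length(i) != 1) {
    stop(sprintf("model must have exactly one %s kernel in chain %s", role,
                 chain))
  }
  i
}

check_labels_match <- function(a, b) {
  la <- lapply(a$kernels, function(k) c(k$chain, k$role))
  lb <- lapply(b$kernels, function(k) c(k$chain, k$role))
  if (!identical(la, lb)) {
    stop("reference models R and S must share kernel order and labels")
  }
}

# product-Gaussian mean: density-weighted midpoint of a kernel pair
product_gauss_mean <- function(k1, k2) {
  P1 <- solve(k1$cov); P2 <- solve(k2$cov)
  as.numeric(solve(P1 + P2, P1 %*% k1$center + P2 %*% k2$center))
}

#' Build the restraint set for a pair of reference hexamer models
#'
#' Produces, for the default hexamer scheme, 36 pair restraints: 3 intra-chain
#' pairs x 6 chains, plus neighboring body-body, tail-tail and head-head
#' pairs (6 each around the ring A-B-...-F-A). The reference overlap of each
#' pair is the mean of its overlaps in `modelR` and `modelS`. Pairs across
#' the seam interface get class `"seam"` with `k_att` scaled down. A phantom
#' pair is placed on every intra-chain pair, anchored at the product-Gaussian
#' mean of the pair in `anchor_model` (the model the trajectory starts from;
#' defaults to `modelR`).
#'
#' @param modelR,modelS Reference `gmm_model`s sharing kernel order and
#'   labels.
#' @param config See [default_restraint_config()].
#' @param anchor_model Model whose geometry anchors the phantom particles.
#' @return A `restraint_set`: list with `pairs` (data frame) and `phantoms`.
#' @export
build_restraints <- function(modelR, modelS,
                             config = default_restraint_config(),
                             anchor_model = modelR) {
  check_labels_match(modelR, modelS)
  check_labels_match(modelR, anchor_model)
  chains <- LETTERS[1:6]
  neighbors <- cbind(chains, c(chains[-1], chains[1]))  # A-B ... F-A
  seam <- sort(config$seam_chains)

  pair_rows <- list()
  add_pair <- function(i, j, class) {
    oR <- kernel_overlap(modelR$kernels[[i]], modelR$kernels[[j]])
    oS <- kernel_overlap(modelS$kernels[[i]], modelS$kernels[[j]])
    cls <- config$classes[[class]]
    k_att <- cls$k_att; k_rep <- cls$k_rep
    ci <- modelR$kernels[[i]]$chain; cj <- modelR$kernels[[j]]$chain
    label <- class
    if (ci != cj && setequal(c(ci, cj), seam)) {
      label <- "seam"
      k_att <- k_att * config$seam_att_scale
    }
    pair_rows[[length(pair_rows) + 1]] <<- data.frame(
      i = i, j = j, obar = (oR + oS) / 2, k_att = k_att, k_rep = k_rep,
      class = label, stringsAsFactors = FALSE)
  }

  roles <- c("head", "body", "tail")
  for (ch in chains) {
    idx <- vapply(roles, function(r) kernel_index(modelR, ch, r), integer(1))
    add_pair(idx["head"], idx["body"], "intra")
    add_pair(idx["body"], idx["tail"], "intra")
    add_pair(idx["head"], idx["tail"], "intra")
  }
  for (r in seq_len(nrow(neighbors))) {
    c1 <- neighbors[r, 1]; c2 <- neighbors[r, 2]
    add_pair(kernel_index(modelR, c1, "body"), kernel_index(modelR, c2, "body"),
             "body-body")
    add_pair(kernel_index(modelR, c1, "tail"), kernel_index(modelR, c2, "tail"),
             "tail-tail")
    add_pair(kernel_index(modelR, c1, "head"), kernel_index(modelR, c2, "head"),
             "head-head")
  }
  pairs <- do.call(rbind, pair_rows)
  key <- paste(pmin(pairs$i, pairs$j), pmax(pairs$i, pairs$j))
  if (anyDuplicated(key)) stop("duplicate restraint pairs")

  # Phantom pairs sit at intra-chain kernel intersections, anchored to the
  # starting geometry.  Only genuinely intersecting pairs get a phantom: the
  # anchor (product-Gaussian mean) must lie inside the m_contain ellipsoid
  # of both kernels in the anchor model, otherwise there is no hinge to
  # preserve (e.g. the head and tail kernels of a chain, which touch only
  # through the body).
  intra <- pairs[pairs$class == "intra", , drop = FALSE]
  phantoms <- list()
  for (r in seq_len(nrow(intra))) {
    i <- intra$i[r]; j <- intra$j[r]
    anchor <- product_gauss_mean(anchor_model$kernels[[i]],
                                 anchor_model$kernels[[j]])
    if (mahalanobis_dist(anchor, anchor_model$kernels[[i]]) > config$m_contain ||
        mahalanobis_dist(anchor, anchor_model$kernels[[j]]) > config$m_contain) {
      next
    }
    phantoms[[length(phantoms) + 1]] <-
      list(i = i, j = j,
           offset_i = anchor - anchor_model$kernels[[i]]$center,
           offset_j = anchor - anchor_model$kernels[[j]]$center)
  }

  structure(list(pairs = pairs, phantoms = phantoms,
                 max_separation = config$max_separation,
                 m_contain = config$m_contain),
            class = "restraint_set", config = config)
}

#' Asymmetric harmonic score of one pair restraint
#'
#' @param o Current overlap of the pair, in (0, 1].
#' @param obar Reference overlap (mean of the two reference conformations).
#' @param k_att Curvature applied when `o < obar` (kernels drifting apart).
#' @param k_rep Curvature applied when `o > obar` (kernels clashing).
#' @return Non-negative score; 0 exactly at `o = obar`.
#' @export
pair_score <- function(o, obar, k_att, k_rep) {
  d <- o - obar
  ifelse(d < 0, k_att * d^2, k_rep * d^2)
}

# overlaps of the restrained pairs in a model (vectorized over the table)
pair_overlaps <- function(model, set, rows = seq_len(nrow(set$pairs))) {
  vapply(rows, function(r) {
    kernel_overlap(model$kernels[[set$pairs$i[r]]],
                   model$kernels[[set$pairs$j[r]]])
  }, numeric(1))
}

#' Total restraint score of a model
#'
#' Sum of [pair_score()] over all pair restraints at the model's current
#' overlaps. Invariant under a global rigid transform (overlaps are
#' relative).
#'
#' @param model A `gmm_model` sharing the kernel ordering of the restrained
#'   references.
#' @param set A `restraint_set` from [build_restraints()].
#' @return Non-negative total score.
#' @export
total_restraint_score <- function(model, set) {
  o <- pair_overlaps(model, set)
  sum(pair_score(o, set$pairs$obar, set$pairs$k_att, set$pairs$k_rep))
}

# world positions of the two phantoms of pair p, given per-kernel accumulated
# rotations (list of 3x3) and the current model
phantom_positions <- function(model, set, p, rotations = NULL) {
  ph <- set$phantoms[[p]]
  Ri <- if (is.null(rotations)) diag(3) else rotations[[ph$i]]
  Rj <- if (is.null(rotations)) diag(3) else rotations[[ph$j]]
  list(pi_ = model$kernels[[ph$i]]$center + as.numeric(Ri %*% ph$offset_i),
       pj_ = model$kernels[[ph$j]]$center + as.numeric(Rj %*% ph$offset_j))
}

mahalanobis_dist <- function(x, k) {
  d <- x - k$center
  sqrt(sum(d * solve(k$cov, d)))
}

#' Check phantom-particle connectivity of a model
#'
#' Every phantom pair must satisfy (a) separation of the two phantoms
#' <= `max_separation` (5 Angstrom by default) and (b) each phantom inside
#' the `m_contain` Mahalanobis ellipsoid of *both* kernels of its pair, i.e.
#' inside the overlap region.
#'
#' @param model A `gmm_model`.
#' @param set A `restraint_set`.
#' @param rotations Optional list of per-kernel accumulated rotation matrices
#'   (identity if omitted); phantoms ride rigidly with their kernel.
#' @param which_pairs Optional subset of phantom pair indices to check.
#' @return List with `ok` (logical) and `violations` (data frame of failing
#'   pairs with the failed condition).
#' @export
connectivity_ok <- function(model, set, rotations = NULL, which_pairs = NULL) {
  idx <- which_pairs %||% seq_along(set$phantoms)
  viol <- list()
  for (p in idx) {
    ph <- set$phantoms[[p]]
    pos <- phantom_positions(model, set, p, rotations)
    sep <- sqrt(sum((pos$pi_ - pos$pj_)^2))
    if (sep > set$max_separation) {
      viol[[length(viol) + 1]] <- data.frame(pair = p, i = ph$i, j = ph$j,
                                             condition = "separation",
                                             value = sep)
      next
    }
    md <- c(mahalanobis_dist(pos$pi_, model$kernels[[ph$i]]),
            mahalanobis_dist(pos$pi_, model$kernels[[ph$j]]),
            mahalanobis_dist(pos$pj_, model$kernels[[ph$i]]),
            mahalanobis_dist(pos$pj_, model$kernels[[ph$j]]))
    if (any(md > set$m_contain)) {
      viol[[length(viol) + 1]] <- data.frame(pair = p, i = ph$i, j = ph$j,
                                             condition = "containment",
                                             value = max(md))
    }
  }
  list(ok = length(viol) == 0,
       violations = if (length(viol)) do.call(rbind, viol) else
         data.frame(pair = integer(), i = integer(), j = integer(),
                    condition = character(), value = numeric()))
}

#' Write / read a restraint set as JSON
#' @param set A `restraint_set`.
#' @param path JSON path.
#' @return `path` (write) or a `restraint_set` (read).
#' @export
write_restraints <- function(set, path) {
  jsonlite::write_json(unclass(set), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_restraints
#' @export
read_restraints <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  phantoms <- lapply(seq_len(nrow(obj$phantoms)), function(r) {
    list(i = obj$phantoms$i[r], j = obj$phantoms$j[r],
         offset_i = unlist(obj$phantoms$offset_i[r]),
         offset_j = unlist(obj$phantoms$offset_j[r]))
  })
  structure(list(pairs = obj$pairs, phantoms = phantoms,
                 max_separation = obj$max_separation,
                 m_contain = obj$m_contain),
            class = "restraint_set")
}
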