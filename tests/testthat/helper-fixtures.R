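# Shared fixtures built in code.

# toy three-blob chain: an artificial "monomer" whose residues fall into
# three well-separated domains (head / body / tail), for role-assignment and
# superposition tests
toy_chain <- function(chain = "A", n_per_domain = 60, seed = 42,
                      centers = rbind(head = c(0, 0, 40),
                                      body = c(0, 0, 20),
                                      tail = c(0, 0, 0)),
                      spread = 3) {
  withr::local_seed(seed)
  dom <- rep(rownames(centers), each = n_per_domain)
  xyz <- do.call(rbind, lapply(rownames(centers), function(d) {
    sweep(matrix(stats::rnorm(3 * n_per_domain, 0, spread), ncol = 3), 2,
          centers[d, ], "+")
  }))
  resno <- seq_len(nrow(xyz))  # head residues first, then body, then tail
  cloud <- data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      mass = rep(12.011, nrow(xyz)),
                      chain = chain, resno = resno, elety = "CA",
                      stringsAsFactors = FALSE)
  class(cloud) <- c("atom_cloud", "data.frame")
  attr(cloud, "domains") <- split(resno, dom)
  cloud
}

toy_domain_ranges <- function(n_per_domain = 60) {
  list(head = 1:n_per_domain,
       body = (n_per_domain + 1):(2 * n_per_domain),
       tail = (2 * n_per_domain + 1):(3 * n_per_domain))
}

# place six rotated copies of a chain cloud on a ring -> toy atomic hexamer
toy_atomic_hexamer <- function(monomer = toy_chain(), radius = 60) {
  out <- lapply(1:6, function(ci) {
    th <- (ci - 1) * pi / 3
    R <- rotation_matrix(c(0, 0, 1), th)
    xyz <- as.matrix(monomer[, c("x", "y", "z")]) %*% t(R)
    xyz[, 1] <- xyz[, 1] + radius * cos(th)
    xyz[, 2] <- xyz[, 2] + radius * sin(th)
    m <- monomer
    m$x <- xyz[, 1]; m$y <- xyz[, 2]; m$z <- xyz[, 3]
    m$chain <- LETTERS[ci]
    m
  })
  hex <- do.call(rbind, out)
  class(hex) <- c("atom_cloud", "data.frame")
  hex
}

# write an atom_cloud as a minimal PDB file; returns the path
write_toy_pdb <- function(cloud, path = tempfile(fileext = ".pdb")) {
  lines <- vapply(seq_len(nrow(cloud)), function(i) {
    sprintf("ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            i %% 100000, cloud$chain[i], cloud$resno[i],
            cloud$x[i], cloud$y[i], cloud$z[i])
  }, character(1))
  writeLines(c(lines, "END"), path)
  path
}

# small labeled hexamer with fatter, overlapping kernels than the defaults
# (keeps restraint fixtures strictly inside (0,1] overlap territory)
small_hexamer <- function(class = "closed") {
  make_toy_hexamer(toy_spec(class = class))
}
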