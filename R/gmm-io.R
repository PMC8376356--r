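# Text and JSON serialisation of mixture models.
#
# Text format: one header line with the kernel count, then one line per
# kernel:
#   weight cx cy cz s11 s12 s13 s22 s23 s33 chain role
# (upper-triangle covariance, Angstrom^2; "-" marks an absent label).
# The JSON dialect carries the same fields and round-trips identically.

#' Write a mixture model to a text or JSON file
#'
#' @param model A `gmm_model`.
#' @param path Output path; a `.json` extension selects the JSON dialect.
#' @return `path`, invisibly.
#' @export
write_gmm <- function(model, path) {
  stopifnot(inherits(model, "gmm_model"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    rec <- lapply(model$kernels, function(k) list(
      weight = k$weight, center = k$center,
      cov_upper = k$cov[upper.tri(k$cov, diag = TRUE)],
      chain = if (is.na(k$chain)) NULL else k$chain,
      role = if (is.na(k$role)) NULL else k$role))
    jsonlite::write_json(list(name = model$name, provenance = model$provenance,
                              kernels = rec),
                         path, auto_unbox = TRUE, digits = NA)
    return(invisible(path))
  }
  lab <- function(x) if (is.na(x)) "-" else x
  lines <- c(as.character(length(model$kernels)),
             vapply(model$kernels, function(k) {
               ut <- k$cov[upper.tri(k$cov, diag = TRUE)]
               # upper.tri order: s11 s12 s22 s13 s23 s33 -> reorder to row-major
               paste(c(format(c(k$weight, k$center,
                                ut[c(1, 2, 4, 3, 5, 6)]), digits = 17),
                       lab(k$chain), lab(k$role)), collapse = " ")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

parse_kernel_fields <- function(weight, center, cov_upper, chain, role, where) {
  S <- matrix(0, 3, 3)
  S[upper.tri(S, diag = TRUE)] <- cov_upper
  S <- S + t(S) - diag(diag(S))
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop(sprintf("non-positive-definite covariance at %s", where))
  gmm_kernel(weight, center, S, chain = chain, role = role)
}

#' Read a mixture model written by [write_gmm()]
#'
#' @param path Path to a `.gmm` text file or `.json` file.
#' @return A `gmm_model`.
#' @export
read_gmm <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    kernels <- lapply(seq_len(nrow(obj$kernels)), function(i) {
      r <- obj$kernels[i, ]
      parse_kernel_fields(r$weight, unlist(r$center), unlist(r$cov_upper),
                          r$chain %||% NA_character_, r$role %||% NA_character_,
                          sprintf("kernel %d", i))
    })
    return(gmm_model(kernels, name = obj$name %||% "model",
                     provenance = obj$provenance %||% ""))
  }
  lines <- readLines(path)
  if (length(lines) < 1) stop("empty model file: ", path)
  n <- suppressWarnings(as.integer(lines[1]))
  if (is.na(n) || n < 1) stop("malformed header at line 1 of ", path)
  if (length(lines) < n + 1) {
    stop(sprintf("truncated file: expected %d kernel lines, found %d (line %d)",
                 n, length(lines) - 1, length(lines) + 1))
  }
  kernels <- vector("list", n)
  for (i in seq_len(n)) {
    ln <- i + 1
    f <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(f) != 12) stop(sprintf("malformed kernel record at line %d", ln))
    num <- suppressWarnings(as.numeric(f[1:10]))
    if (anyNA(num)) stop(sprintf("malformed numeric field at line %d", ln))
    # row-major s11 s12 s13 s22 s23 s33 -> upper.tri order s11 s12 s22 s13 s23 s33
    kernels[[i]] <- parse_kernel_fields(
      num[1], num[2:4], num[5:10][c(1, 2, 4, 3, 5, 6)],
      if (f[11] == "-") NA_character_ else f[11],
      if (f[12] == "-") NA_character_ else f[12],
      sprintf("line %d", ln))
  }
  gmm_model(kernels, name = sub("\\.[^.]*$", "", basename(path)),
            provenance = path)
}
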