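# AFM height images: data model, I/O, masking, background correction.
#
# Heights are stored in a ny x nx matrix in Angstrom, row i = pixel row along
# y, column j = pixel column along x.  Pixel (1,1) is the lower-left pixel
# center at the grid origin; physical pixel centers are
#   x_j = origin[1] + (j-1) * dx,   y_i = origin[2] + (i-1) * dy.

#' Construct an AFM height image
#'
#' @param heights ny x nx numeric matrix of heights (Angstrom).
#' @param dx,dy Pixel pitch along x and y (Angstrom). The imaging geometry
#'   used throughout the examples is 66 x 42 pixels at 4.545 x 5.477
#'   Angstrom.
#' @param origin Physical position of pixel (1,1) center; default (0,0).
#' @return An `afm_image` object.
#' @export
afm_image <- function(heights, dx, dy, origin = c(0, 0)) {
  heights <- as.matrix(heights)
  stopifnot(nrow(heights) >= 1, ncol(heights) >= 1, dx > 0, dy > 0,
            all(is.finite(heights)), length(origin) == 2)
  structure(list(heights = heights, dx = as.numeric(dx), dy = as.numeric(dy),
                 origin = as.numeric(origin)), class = "afm_image")
}

#' Default imaging geometry for the hexamer dataset
#'
#' 66 x 42 pixels (width x height), 4.545 Angstrom pitch in x and 5.477 in y.
#' @param origin Physical position of pixel (1,1).
#' @return An empty `afm_image` carrying only geometry.
#' @export
default_afm_grid <- function(origin = c(0, 0)) {
  afm_image(matrix(0, nrow = 42, ncol = 66), dx = 4.545, dy = 5.477,
            origin = origin)
}

#' @export
print.afm_image <- function(x, ...) {
  cat(sprintf("AFM image: %d x %d px, pitch %.3f x %.3f A, height range [%.2f, %.2f] A\n",
              ncol(x$heights), nrow(x$heights), x$dx, x$dy,
              min(x$heights), max(x$heights)))
  invisible(x)
}

#' Construct a binary image mask
#'
#' @param values Logical or 0/1 matrix, same shape as its image.
#' @return An `afm_mask` object.
#' @export
afm_mask <- function(values) {
  m <- matrix(as.logical(values), nrow = nrow(values))
  if (!any(m)) stop("mask selects no pixels")
  structure(list(values = m), class = "afm_mask")
}

check_same_shape <- function(a, b) {
  if (!all(dim(a$heights %||% a$values) == dim(b$heights %||% b$values))) {
    stop("image/mask shapes differ")
  }
}

#' Subtract a background plane from an AFM image
#'
#' Fits a least-squares plane `a x + b y + c` to the background pixels (the
#' complement of `mask`), subtracts it from the whole image and clips negative
#' heights to zero. After correction the background median is approximately
#' zero.
#'
#' @param image An `afm_image`.
#' @param mask An `afm_mask` marking the molecule region.
#' @return Background-corrected `afm_image`.
#' @export
subtract_background <- function(image, mask) {
  stopifnot(inherits(image, "afm_image"), inherits(mask, "afm_mask"))
  check_same_shape(image, mask)
  bg <- !mask$values
  if (sum(bg) < 3) stop("need at least 3 background pixels to fit a plane")
  ny <- nrow(image$heights); nx <- ncol(image$heights)
  xs <- image$origin[1] + (seq_len(nx) - 1) * image$dx
  ys <- image$origin[2] + (seq_len(ny) - 1) * image$dy
  X <- matrix(xs, ny, nx, byrow = TRUE)
  Y <- matrix(ys, ny, nx)
  fit <- stats::lm.fit(cbind(1, X[bg], Y[bg]), image$heights[bg])
  plane <- fit$coefficients[1] + fit$coefficients[2] * X +
    fit$coefficients[3] * Y
  image$heights <- pmax(image$heights - plane, 0)
  image
}

#' Write an AFM image (or mask) as TSV with a JSON sidecar
#'
#' The height matrix goes to `<path>` as tab-separated values (one row per
#' pixel row); geometry goes to `<path>.json` as
#' `{nx, ny, dx, dy, origin, units}`.
#'
#' @param image `afm_image`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_afm <- function(image, path) {
  stopifnot(inherits(image, "afm_image"))
  utils::write.table(format(image$heights, digits = 17), path, sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(nx = ncol(image$heights), ny = nrow(image$heights),
                            dx = image$dx, dy = image$dy,
                            origin = image$origin, units = "angstrom"),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an AFM image written by [write_afm()]
#'
#' @param path TSV path; the `<path>.json` sidecar must exist.
#' @return An `afm_image`.
#' @export
read_afm <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop("missing sidecar: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  rows <- strsplit(readLines(path), "\t", fixed = TRUE)
  widths <- lengths(rows)
  if (length(unique(widths)) != 1) {
    stop("ragged height matrix: row ", which(widths != widths[1])[1],
         " has ", widths[widths != widths[1]][1], " fields, expected ",
         widths[1])
  }
  h <- do.call(rbind, lapply(rows, as.numeric))
  if (anyNA(h)) stop("non-numeric height entry in ", path)
  if (nrow(h) != meta$ny || ncol(h) != meta$nx) {
    stop(sprintf("matrix is %d x %d but sidecar says %d x %d",
                 nrow(h), ncol(h), meta$ny, meta$nx))
  }
  afm_image(h, dx = meta$dx, dy = meta$dy,
            origin = meta$origin %||% c(0, 0))
}

#' Write / read a binary mask as 0/1 TSV
#' @param mask An `afm_mask`.
#' @param path TSV path.
#' @return `path` (write) or an `afm_mask` (read).
#' @export
write_mask <- function(mask, path) {
  utils::write.table(mask$values * 1L, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t"))
  afm_mask(m != 0)
}
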