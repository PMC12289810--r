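#' Discrete nonnegative measures
#'
#' A `discrete_measure` represents a finite nonnegative measure
#' \eqn{\mu = \sum_i w_i \delta_{x_i}} on \eqn{R^d} as a matrix of support
#' points (one row per atom) plus a vector of nonnegative weights. Zero-weight
#' atoms are dropped and duplicate support points are merged (weights summed)
#' at construction time, so the representation passed to the solvers is always
#' nondegenerate.
#'
#' @param points numeric matrix (n x d) of support coordinates, or a numeric
#'   vector interpreted as a single point when `weights` has length 1 or as
#'   n points in d = 1 otherwise.
#' @param weights numeric vector of nonnegative atom masses, recycled scalar
#'   allowed. Defaults to unit weights (an empirical point cloud).
#' @param label optional character tag carried along for printing/tables.
#' @return An object of class `discrete_measure` with fields `points`,
#'   `weights`, `label`.
#' @examples
#' mu <- discrete_measure(rbind(c(0, 0), c(3, 4)), c(1, 2))
#' tv_norm(mu)
#' @export
discrete_measure <- function(points, weights = NULL, label = NULL) {
  if (is.null(dim(points))) {
    points <- if (!is.null(weights) && length(weights) == 1L && length(points) > 1L) {
      matrix(points, nrow = 1L)
    } else {
      matrix(points, ncol = 1L)
    }
  }
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  dimnames(points) <- NULL
  if (is.null(weights)) weights <- rep(1, nrow(points))
  if (length(weights) == 1L) weights <- rep(weights, nrow(points))
  weights <- as.numeric(weights)
  if (length(weights) != nrow(points)) {
    stop("length(weights) must equal nrow(points)")
  }
  if (anyNA(points) || any(!is.finite(points))) {
    stop("support coordinates must be finite")
  }
  if (anyNA(weights) || any(!is.finite(weights))) {
    stop("weights must be finite")
  }
  if (any(weights < 0)) {
    stop("weights must be nonnegative")
  }
  if (ncol(points) < 1L) stop("dimension must be >= 1")
  keep <- weights > 0
  points <- points[keep, , drop = FALSE]
  weights <- weights[keep]
  if (nrow(points) > 1L) {
    key <- apply(points, 1L, paste, collapse = "\r")
    if (anyDuplicated(key)) {
      first <- !duplicated(key)
      weights <- as.numeric(tapply(weights, factor(key, levels = key[first]), sum))
      points <- points[first, , drop = FALSE]
    }
  }
  structure(list(points = points, weights = weights, label = label),
            class = "discrete_measure")
}

#' @export
print.discrete_measure <- function(x, ...) {
  cat(sprintf("<discrete_measure%s: %d atoms in R^%d, total mass %.6g>\n",
              if (is.null(x$label)) "" else paste0(" '", x$label, "'"),
              n_atoms(x), measure_dim(x), tv_norm(x)))
  invisible(x)
}

#' Number of atoms of a discrete measure
#' @param mu a `discrete_measure`.
#' @return Integer count of (merged, nonzero-weight) support points.
#' @export
n_atoms <- function(mu) nrow(mu$points)

#' Ambient dimension of a discrete measure
#' @param mu a `discrete_measure`.
#' @return Integer dimension d of the support coordinates.
#' @export
measure_dim <- function(mu) ncol(mu$points)

stopifnot_measure <- function(mu) {
  if (!inherits(mu, "discrete_measure")) stop("expected a discrete_measure")
  invisible(mu)
}

check_same_dim <- function(mu, nu) {
  if (measure_dim(mu) != measure_dim(nu)) {
    stop(sprintf("dimension mismatch: %d vs %d", measure_dim(mu), measure_dim(nu)))
  }
  invisible(NULL)
}

#' Dirac measure
#'
#' Single-atom measure `mass * delta_location`. A zero mass yields the empty
#' measure.
#'
#' @param location numeric coordinate vector.
#' @param mass nonnegative scalar mass.
#' @param label optional tag.
#' @return A `discrete_measure` with at most one atom.
#' @examples
#' make_dirac(c(0, 0), 4)
#' @export
make_dirac <- function(location, mass = 1, label = NULL) {
  if (length(mass) != 1L || !is.finite(mass)) stop("mass must be a finite scalar")
  if (mass < 0) stop("mass must be nonnegative")
  discrete_measure(matrix(as.numeric(location), nrow = 1L), mass, label = label)
}

#' Total variation norm of a nonnegative measure
#'
#' For a nonnegative measure this is simply the total mass, the sum of the
#' atom weights.
#'
#' @param mu a `discrete_measure`.
#' @return Nonnegative scalar \eqn{\|\mu\|_{TV}}.
#' @export
tv_norm <- function(mu) {
  stopifnot_measure(mu)
  sum(mu$weights)
}

#' Concatenate (sum) discrete measures
#'
#' The measure-theoretic sum: supports are pooled, duplicate atoms merged.
#'
#' @param ... `discrete_measure` objects of equal dimension.
#' @param label optional tag for the result.
#' @return A `discrete_measure`.
#' @export
measure_sum <- function(..., label = NULL) {
  ms <- list(...)
  lapply(ms, stopifnot_measure)
  d <- unique(vapply(ms, measure_dim, integer(1)))
  if (length(d) != 1L) stop("dimension mismatch across measures")
  discrete_measure(do.call(rbind, lapply(ms, `[[`, "points")),
                   unlist(lapply(ms, `[[`, "weights")), label = label)
}

#' Scale the mass of a measure
#' @param mu a `discrete_measure`.
#' @param c nonnegative scale factor applied to every weight.
#' @return A `discrete_measure` with weights `c * weights`.
#' @export
measure_scale <- function(mu, c) {
  stopifnot_measure(mu)
  if (c < 0) stop("scale factor must be nonnegative")
  discrete_measure(mu$points, mu$weights * c, label = mu$label)
}

#' Convert a grayscale intensity grid to a measure on the unit square
#'
#' Each nonzero pixel becomes one atom at its cell center, with the (binned,
#' integer) intensity as weight. Pixel (row i, col j) of an H x W grid maps to
#' ((j - 0.5)/W, 1 - (i - 0.5)/H), so the image occupies the unit square with
#' the conventional orientation (row 1 at the top). Total mass equals the grid
#' sum exactly.
#'
#' @param intensity_grid numeric matrix of nonnegative intensities; values are
#'   rounded to integers and must land in 0..255.
#' @param label optional tag.
#' @return A `discrete_measure` in d = 2.
#' @examples
#' g <- matrix(0, 2, 2); g[1, 2] <- 255
#' image_to_measure(g)
#' @export
image_to_measure <- function(intensity_grid, label = NULL) {
  g <- as.matrix(intensity_grid)
  if (anyNA(g) || any(!is.finite(g))) stop("intensities must be finite")
  if (any(g < 0)) stop("intensities must be nonnegative")
  g <- round(g)
  if (any(g > 255)) stop("binned intensities must lie in [0, 255]")
  h <- nrow(g); w <- ncol(g)
  idx <- which(g > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(discrete_measure(matrix(numeric(0), 0, 2), numeric(0), label = label))
  }
  pts <- cbind((idx[, "col"] - 0.5) / w, 1 - (idx[, "row"] - 0.5) / h)
  discrete_measure(pts, g[idx], label = label)
}

#' Euclidean pairwise distance matrix
#'
#' @param points_a numeric matrix (n x d).
#' @param points_b numeric matrix (m x d); defaults to `points_a`.
#' @return n x m matrix of Euclidean distances.
#' @export
pairwise_distances <- function(points_a, points_b = points_a) {
  a <- as.matrix(points_a); b <- as.matrix(points_b)
  if (ncol(a) != ncol(b)) stop("dimension mismatch")
  sq <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  if (identical(a, b) && nrow(a) == nrow(b)) diag(sq) <- 0 # exact zero diagonal
  sqrt(pmax(sq, 0))
}

#' Read / write a discrete measure as delimited text
#'
#' The on-disk format is a delimited text file with a header row: columns
#' `x1..xd` followed by `weight`. Writing then reading reproduces points and
#' weights to full double precision.
#'
#' @param path file path.
#' @param sep field separator, `","` (default) or `"\t"`.
#' @param label optional tag attached to the measure read.
#' @return `read_measure` returns a `discrete_measure`; `write_measure`
#'   returns `path` invisibly.
#' @export
read_measure <- function(path, sep = ",", label = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = sep, fill = TRUE)
  nc <- ncol(df)
  if (nc < 2L || !identical(names(df)[nc], "weight")) {
    stop("expected columns x1..xd followed by 'weight'")
  }
  bad <- which(!stats::complete.cases(df) |
                 vapply(seq_len(nrow(df)),
                        function(i) any(!is.finite(as.numeric(df[i, ]))),
                        logical(1)))
  if (length(bad)) {
    stop(sprintf("malformed row(s) in %s: %s", path,
                 paste(utils::head(bad, 5L), collapse = ", ")))
  }
  w <- df[[nc]]
  if (any(w < 0)) {
    stop(sprintf("negative weight at row(s): %s",
                 paste(utils::head(which(w < 0), 5L), collapse = ", ")))
  }
  discrete_measure(as.matrix(df[, -nc, drop = FALSE]), w, label = label)
}

#' @rdname read_measure
#' @param measure a `discrete_measure` to write.
#' @export
write_measure <- function(measure, path, sep = ",") {
  stopifnot_measure(measure)
  df <- as.data.frame(measure$points)
  names(df) <- paste0("x", seq_len(ncol(df)))
  df$weight <- measure$weights
  utils::write.table(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                     path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a grayscale image file as an intensity grid
#'
#' Supports PNG (via the png package; gray or RGB, converted to gray by
#' averaging channels) and plain-text PGM (`P2`). Intensities are rescaled to
#' integers in 0..255.
#'
#' @param path image file path.
#' @return Integer intensity matrix (H x W) with values in 0..255.
#' @export
read_image_grid <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    a <- png::readPNG(path)
    if (length(dim(a)) == 3L) a <- apply(a[, , 1:min(3, dim(a)[3]), drop = FALSE], c(1, 2), mean)
    return(round(a * 255))
  }
  txt <- readLines(path, warn = FALSE)
  txt <- txt[!grepl("^#", txt)]
  if (!identical(txt[1], "P2")) stop("only PNG and plain PGM (P2) images are supported")
  vals <- as.numeric(unlist(strsplit(paste(txt[-1], collapse = " "), "\\s+")))
  vals <- vals[!is.na(vals)]
  w <- vals[1]; h <- vals[2]; maxv <- vals[3]
  px <- vals[-(1:3)]
  if (length(px) != w * h) stop("corrupt PGM: pixel count mismatch")
  round(matrix(px, nrow = h, ncol = w, byrow = TRUE) / maxv * 255)
}

#' Write an intensity grid as plain-text PGM (P2)
#' @param grid integer matrix with values in 0..255.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image_grid <- function(grid, path) {
  g <- round(as.matrix(grid))
  if (any(g < 0 | g > 255)) stop("intensities must lie in [0, 255]")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(g), nrow(g)), "255"), con)
  apply(g, 1L, function(row) writeLines(paste(row, collapse = " "), con))
  invisible(path)
}
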