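#' Landmark tables
#'
#' Throughout the package a set of landmark configurations is an ordinary
#' tibble with one row per digitized configuration.  Coordinate columns are
#' named `x1 ... xk` then `y1 ... yk`; any other columns (identifiers,
#' classifiers, sizes) ride along untouched, so results of every stage can be
#' piped through dplyr verbs.  A single configuration is a plain `k x 2`
#' numeric matrix (column 1 = x, column 2 = y).
#'
#' @name landmark-tables
NULL

coord_names <- function(k) c(paste0("x", seq_len(k)), paste0("y", seq_len(k)))

#' Number of landmarks in a landmark table
#'
#' @param data A landmark table (see [landmark-tables]).
#' @return Integer number of landmarks `k`.
#' @export
landmark_count <- function(data) {
  nm <- names(data)
  kx <- sum(grepl("^x[0-9]+$", nm))
  ky <- sum(grepl("^y[0-9]+$", nm))
  if (kx == 0 || kx != ky) {
    abort("Landmark table must contain matching x1..xk and y1..yk columns.")
  }
  if (!all(coord_names(kx) %in% nm)) {
    abort("Coordinate columns must be consecutively numbered x1..xk, y1..yk.")
  }
  kx
}

#' Extract the n x 2k coordinate matrix of a landmark table
#'
#' Rows follow the table; columns are `x1..xk, y1..yk` (the flattening
#' convention used for all shape vectors in the package).
#'
#' @inheritParams landmark_count
#' @return Numeric matrix, one row per configuration.
#' @export
coord_matrix <- function(data) {
  k <- landmark_count(data)
  m <- as.matrix(data[coord_names(k)])
  if (!is.numeric(m) || any(!is.finite(m))) {
    abort("Landmark coordinates must be finite numbers.")
  }
  m
}

#' Replace the coordinate columns of a landmark table
#'
#' @inheritParams landmark_count
#' @param coords Numeric matrix `n x 2k` in `x1..xk, y1..yk` order.
#' @return The table with coordinates replaced.
#' @export
set_coords <- function(data, coords) {
  k <- landmark_count(data)
  stopifnot(nrow(coords) == nrow(data), ncol(coords) == 2L * k)
  data[coord_names(k)] <- as.data.frame(coords)
  data
}

# k x 2 matrix from a flattened 2k vector (x-block then y-block)
unflatten_config <- function(v) {
  k <- length(v) / 2L
  cbind(v[seq_len(k)], v[k + seq_len(k)])
}

# flattened 2k vector from a k x 2 matrix
flatten_config <- function(m) c(m[, 1L], m[, 2L])

#' Build a landmark table from a list of configuration matrices
#'
#' @param configs List of `k x 2` numeric matrices (equal `k`).
#' @param meta Optional data frame of per-configuration metadata (one row per
#'   configuration), bound in front of the coordinate columns.
#' @return A landmark table (tibble).
#' @export
as_landmark_tbl <- function(configs, meta = NULL) {
  k <- nrow(configs[[1]])
  if (any(vapply(configs, nrow, 0L) != k)) {
    abort("All configurations must have the same number of landmarks.")
  }
  coords <- do.call(rbind, lapply(configs, flatten_config))
  colnames(coords) <- coord_names(k)
  out <- tibble::as_tibble(as.data.frame(coords))
  if (!is.null(meta)) out <- dplyr::bind_cols(tibble::as_tibble(meta), out)
  out
}

#' Split a landmark table into a list of configuration matrices
#'
#' @inheritParams landmark_count
#' @return List of `k x 2` matrices, one per row.
#' @export
config_list <- function(data) {
  m <- coord_matrix(data)
  lapply(seq_len(nrow(m)), function(i) unflatten_config(m[i, ]))
}

#' Reference 17-landmark prosoma outline
#'
#' A fixed 17-point, roughly oval outline of a spider prosoma (dorsal view)
#' used as the default mean shape of the synthetic generator and in examples.
#' Landmarks 1-8 lie on the anterior region (pars cephalica), 9-17 on the
#' posterior region (pars thoracica).  The coordinates are illustrative -- a
#' qualitatively prosoma-like convex outline, centered and scaled to unit
#' centroid size -- not measurements of any specimen.
#'
#' @return A `17 x 2` matrix, centered, centroid size 1.
#' @export
default_mean_shape <- function() {
  m <- matrix(c(
    -0.18, 0.70,   0.18, 0.70,
    -0.38, 0.55,   0.38, 0.55,
    -0.48, 0.33,   0.48, 0.33,
    -0.52, 0.10,   0.52, 0.10,
    -0.60, -0.15,  0.60, -0.15,
    -0.55, -0.45,  0.55, -0.45,
    -0.38, -0.68,  0.38, -0.68,
    -0.15, -0.80,  0.15, -0.80,
    0.00, -0.88
  ), ncol = 2, byrow = TRUE)
  m <- scale(m, scale = FALSE)
  m / centroid_size(m)
}

#' Default wireframe links for the 17-landmark prosoma
#'
#' Perimeter links (odd/left and even/right chains meeting at the posterior
#' tip) plus the chord separating pars cephalica (1-8) from pars thoracica
#' (9-17).  Illustrative, chosen to draw a closed outline of
#' [default_mean_shape()].
#'
#' @return Two-column integer matrix of landmark index pairs.
#' @export
default_wireframe <- function() {
  left <- c(1, 3, 5, 7, 9, 11, 13, 15, 17)
  right <- c(2, 4, 6, 8, 10, 12, 14, 16, 17)
  links <- rbind(
    cbind(left[-length(left)], left[-1]),
    cbind(right[-length(right)], right[-1]),
    c(1, 2), c(7, 8), c(9, 10)
  )
  colnames(links) <- c("from", "to")
  links
}

#' Landmark region map for the 17-landmark prosoma
#'
#' @return Character vector of length 17: `"cephalica"` for landmarks 1-8,
#'   `"thoracica"` for 9-17.
#' @export
default_landmark_regions <- function() {
  rep(c("cephalica", "thoracica"), c(8, 9))
}

#' Orthonormal basis of the similarity directions at a reference shape
#'
#' For a centered reference of unit centroid size the four directions in
#' configuration space that similarity transforms can move a configuration
#' along are: x-translation, y-translation, scaling (the reference itself)
#' and infinitesimal rotation (the reference rotated 90 degrees).  For a
#' centered unit-size reference these are mutually orthonormal.
#'
#' @param reference `k x 2` centered matrix with centroid size 1.
#' @return `2k x 4` matrix with orthonormal columns (tx, ty, scale, rotation).
#' @export
similarity_basis <- function(reference) {
  k <- nrow(reference)
  ref <- scale(reference, scale = FALSE)
  ref <- ref / centroid_size(ref)
  tx <- c(rep(1, k), rep(0, k)) / sqrt(k)
  ty <- c(rep(0, k), rep(1, k)) / sqrt(k)
  sc <- flatten_config(ref)
  rot <- flatten_config(cbind(-ref[, 2], ref[, 1]))
  cbind(tx = tx, ty = ty, scale = sc, rotation = rot)
}

#' Project a shape-change vector into the tangent subspace
#'
#' Removes the components of `v` along the four similarity directions at
#' `reference`, leaving a pure shape change (the tangent space has dimension
#' `2k - 4`).
#'
#' @param v Numeric vector of length `2k` (`x`-block then `y`-block).
#' @param reference `k x 2` reference shape.
#' @return The projected vector, orthogonal to all similarity directions.
#' @export
project_tangent_vector <- function(v, reference) {
  b <- similarity_basis(reference)
  as.numeric(v - b %*% crossprod(b, v))
}

# TRUE when v is (numerically) orthogonal to the similarity directions
is_tangent_vector <- function(v, reference, tol = 1e-8) {
  b <- similarity_basis(reference)
  all(abs(crossprod(b, v)) < tol)
}
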