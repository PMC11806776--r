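#' Exaggerate a shape difference for display
#'
#' Returns `reference + m * (target - reference)`: the linear extrapolation
#' of the shape change from the reference toward (and past) the target,
#' used to magnify subtle group differences in wireframe figures
#' (`m = 1` reproduces the target, `m = 0` the reference).
#'
#' @param reference,target `k x 2` shapes (typically mean shapes in the
#'   aligned/tangent frame).
#' @param m Magnification factor (>= 0).
#' @return `k x 2` matrix.
#' @export
exaggerate <- function(reference, target, m) {
  reference <- as.matrix(reference); target <- as.matrix(target)
  if (!all(dim(reference) == dim(target))) abort("Shapes must have matching dimensions.")
  reference + m * (target - reference)
}

#' Wireframe line segments for a shape difference display
#'
#' Builds the plot-ready segments of a reference shape and an (optionally
#' magnified) target shape connected by a link list.
#'
#' @param reference,target `k x 2` shapes.
#' @param links Two-column matrix of landmark index pairs (default
#'   [default_wireframe()] when `k = 17`).
#' @param magnification Exaggeration factor applied to the target.
#' @return Tibble with `shape` (`"reference"`/`"target"`), `from`, `to`,
#'   and segment endpoint coordinates `x`, `y`, `xend`, `yend`.
#' @export
wireframe_segments <- function(reference, target = NULL, links = NULL,
                               magnification = 1) {
  reference <- as.matrix(reference)
  k <- nrow(reference)
  if (is.null(links)) {
    if (k != 17L) abort("Supply a link list for k != 17.")
    links <- default_wireframe()
  }
  if (any(links < 1L) || any(links > k)) abort("Link list references invalid landmark indices.")
  seg_of <- function(cfg, label) {
    tibble::tibble(shape = label, from = links[, 1], to = links[, 2],
                   x = cfg[links[, 1], 1], y = cfg[links[, 1], 2],
                   xend = cfg[links[, 2], 1], yend = cfg[links[, 2], 2])
  }
  out <- seg_of(reference, "reference")
  if (!is.null(target)) {
    tgt <- exaggerate(reference, as.matrix(target), magnification)
    out <- dplyr::bind_rows(out, seg_of(tgt, "target"))
  }
  out
}

# thin-plate spline radial kernel U(r) = r^2 log r^2 (0 at r = 0)
tps_kernel <- function(r2) ifelse(r2 == 0, 0, r2 * log(r2))

#' Thin-plate spline warp between two landmark configurations
#'
#' Solves the 2-D thin-plate spline interpolation mapping every source
#' landmark exactly onto its target landmark (kernel `U(r) = r^2 log r^2`),
#' evaluates the warp on a regular grid over the source's bounding box, and
#' reports the bending energy of the non-affine part (zero if and only if
#' the map is affine).  This is the deformation-grid display classically
#' used to visualize mean-shape differences.
#'
#' @param source,target `k x 2` configurations (same `k`; source landmarks
#'   must not be collinear).
#' @param grid_resolution Number of grid lines along the longer side
#'   (default 24).
#' @param padding Bounding-box padding as a fraction of its size.
#' @return Object of class `tps_grid`: `source`, `target`, `grid` (tibble
#'   with grid indices, source position `x0`,`y0` and warped position
#'   `x`,`y`), `bending_energy`, and the spline coefficients.
#' @export
tps_warp <- function(source, target, grid_resolution = 24L, padding = 0.05) {
  source <- as.matrix(source); target <- as.matrix(target)
  k <- nrow(source)
  if (!all(dim(source) == dim(target))) abort("Shapes must have matching dimensions.")
  d2 <- as.matrix(stats::dist(source))^2
  K <- tps_kernel(d2)
  P <- cbind(1, source)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  rhs <- rbind(target, matrix(0, 3, 2))
  coefs <- tryCatch(solve(L, rhs), error = function(e) {
    abort("Singular thin-plate spline system: collinear or duplicated source landmarks.")
  })
  Wc <- coefs[seq_len(k), , drop = FALSE]   # kernel weights
  Ac <- coefs[k + 1:3, , drop = FALSE]      # affine part
  be <- sum(diag(t(Wc) %*% K %*% Wc))
  be <- max(be, 0)

  rng_x <- range(source[, 1]); rng_y <- range(source[, 2])
  pad_x <- diff(rng_x) * padding; pad_y <- diff(rng_y) * padding
  span_x <- diff(rng_x) + 2 * pad_x; span_y <- diff(rng_y) + 2 * pad_y
  if (span_x >= span_y) {
    nx <- as.integer(grid_resolution)
    ny <- max(2L, as.integer(round(grid_resolution * span_y / span_x)))
  } else {
    ny <- as.integer(grid_resolution)
    nx <- max(2L, as.integer(round(grid_resolution * span_x / span_y)))
  }
  gx <- seq(rng_x[1] - pad_x, rng_x[2] + pad_x, length.out = nx)
  gy <- seq(rng_y[1] - pad_y, rng_y[2] + pad_y, length.out = ny)
  grid0 <- as.matrix(expand.grid(x0 = gx, y0 = gy))
  warped <- tps_eval(grid0, source, Wc, Ac)
  grid <- tibble::tibble(
    ix = rep(seq_len(nx), times = ny), iy = rep(seq_len(ny), each = nx),
    x0 = grid0[, 1], y0 = grid0[, 2], x = warped[, 1], y = warped[, 2]
  )
  structure(
    list(source = source, target = target, grid = grid,
         bending_energy = be, weights = Wc, affine = Ac,
         nx = nx, ny = ny),
    class = "tps_grid"
  )
}

# evaluate the fitted spline at arbitrary points (rows of `pts`)
tps_eval <- function(pts, source, Wc, Ac) {
  d2 <- outer(pts[, 1], source[, 1], "-")^2 + outer(pts[, 2], source[, 2], "-")^2
  U <- tps_kernel(d2)
  cbind(1, pts) %*% Ac + U %*% Wc
}

#' Evaluate a thin-plate spline warp at arbitrary points
#'
#' @param warp A [tps_warp()] result.
#' @param points `m x 2` matrix of probe points in the source frame.
#' @return `m x 2` matrix of warped positions.
#' @export
tps_transform <- function(warp, points) {
  stopifnot(inherits(warp, "tps_grid"))
  pts <- as.matrix(points)
  if (is.null(dim(pts)) || ncol(pts) != 2L) pts <- matrix(pts, ncol = 2L)
  tps_eval(pts, warp$source, warp$weights, warp$affine)
}

#' @export
print.tps_grid <- function(x, ...) {
  cat(sprintf("Thin-plate spline warp: %d landmarks, %d x %d grid, bending energy %.4g\n",
              nrow(x$source), x$nx, x$ny, x$bending_energy))
  invisible(x)
}
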