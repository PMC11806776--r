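#' Centroid size
#'
#' The square root of the summed squared distances of the landmarks from
#' their centroid -- the standard size measure of landmark morphometrics.
#'
#' @param x A `k x 2` configuration matrix, or a landmark table (in which
#'   case one size per row is returned).
#' @return Positive numeric (scalar for a matrix, vector for a table).
#' @export
centroid_size <- function(x) {
  if (is.data.frame(x)) {
    m <- coord_matrix(x)
    return(apply(m, 1, function(v) centroid_size(unflatten_config(v))))
  }
  if (!is.matrix(x) || ncol(x) != 2L || nrow(x) < 3L) {
    abort("A configuration must be a k x 2 matrix with k >= 3.")
  }
  if (any(!is.finite(x))) abort("Configuration contains non-finite coordinates.")
  cs <- sqrt(sum(scale(x, scale = FALSE)^2))
  if (cs == 0) abort("Degenerate configuration: all landmarks coincide (centroid size 0).")
  cs
}

# center a k x 2 matrix at the origin
center_config <- function(m) scale(m, scale = FALSE)[, , drop = FALSE]

# optimal rotation angle aligning A onto B (both k x 2), det +1 only:
# rotating (x, y) -> (x cos t - y sin t, x sin t + y cos t) maximizes
# trace(t(A R) B) at t = atan2(Q, P)
rotation_angle <- function(A, B) {
  P <- sum(A[, 1] * B[, 1] + A[, 2] * B[, 2])
  Q <- sum(A[, 1] * B[, 2] - A[, 2] * B[, 1])
  atan2(Q, P)
}

rotate_config <- function(m, theta) {
  ct <- cos(theta); st <- sin(theta)
  cbind(m[, 1] * ct - m[, 2] * st, m[, 1] * st + m[, 2] * ct)
}

#' Full Procrustes superimposition of one configuration onto another
#'
#' Centers both configurations, scales both to unit centroid size, then
#' rotates and rescales the source to minimize the summed squared distance
#' to the target.  Reflections are not allowed (the rotation has determinant
#' +1), so mirror-image shapes keep a positive distance.
#'
#' @param source,target `k x 2` configuration matrices with equal `k`.
#' @return A list with `aligned` (the transformed source), `distance` (the
#'   full Procrustes distance) and `angle` (rotation applied, radians).
#' @export
align_pair <- function(source, target) {
  if (nrow(source) != nrow(target)) abort("Configurations must share the same landmarks.")
  A <- center_config(source); A <- A / centroid_size(A)
  B <- center_config(target); B <- B / centroid_size(B)
  theta <- rotation_angle(A, B)
  P <- sum(A[, 1] * B[, 1] + A[, 2] * B[, 2])
  Q <- sum(A[, 1] * B[, 2] - A[, 2] * B[, 1])
  beta <- sqrt(P^2 + Q^2) # optimal scale, |A| = |B| = 1
  aligned <- beta * rotate_config(A, theta)
  dist2 <- max(0, 1 - beta^2)
  list(aligned = aligned, distance = sqrt(dist2), angle = theta)
}

#' Full Procrustes distance between two configurations
#'
#' @inheritParams align_pair
#' @return Non-negative scalar.
#' @export
procrustes_distance <- function(source, target) align_pair(source, target)$distance

#' Generalized Procrustes analysis
#'
#' Iterative superimposition of all configurations in a landmark table:
#' every configuration is centered and scaled to unit centroid size, rotated
#' to the current consensus, and the consensus (the re-normalized mean of
#' the aligned configurations) is updated until it moves by less than `tol`
#' (root mean square over coordinates).  The first configuration initializes
#' the consensus; after convergence everything is rotated so the consensus
#' lies along its principal axes (major axis on x, deterministic 180-degree
#' convention), which makes the result invariant to input order and to
#' arbitrary similarity transforms of the input rows.
#'
#' Original centroid sizes (before unit-scaling) and their natural logs are
#' recorded per configuration.
#'
#' @param data Landmark table with at least 2 rows.
#' @param tol Convergence tolerance on the consensus RMS change.
#' @param max_iter Maximum number of iterations; if reached the fit is
#'   returned with `converged = FALSE` and a warning.
#' @return An object of class `procrustes_fit`: a list with `consensus`
#'   (`k x 2`, unit centroid size), `aligned` (landmark table of superimposed
#'   coordinates plus `cs` and `log_cs` columns), `k`, `n_iterations`,
#'   `converged`.
#' @export
gpa <- function(data, tol = 1e-10, max_iter = 100L) {
  k <- landmark_count(data)
  X <- coord_matrix(data)
  n <- nrow(X)
  if (n < 2L) abort("GPA needs at least 2 configurations.")

  xs <- X[, seq_len(k), drop = FALSE]
  ys <- X[, k + seq_len(k), drop = FALSE]
  xs <- xs - rowMeans(xs)
  ys <- ys - rowMeans(ys)
  cs <- sqrt(rowSums(xs^2) + rowSums(ys^2))
  if (any(cs == 0)) abort("Degenerate configuration: centroid size 0.")
  xs <- xs / cs
  ys <- ys / cs

  consensus <- cbind(xs[1, ], ys[1, ])
  iter <- 0L
  converged <- FALSE
  repeat {
    iter <- iter + 1L
    # rotate all configurations to the consensus (vectorized over rows)
    P <- xs %*% consensus[, 1] + ys %*% consensus[, 2]
    Q <- xs %*% consensus[, 2] - ys %*% consensus[, 1]
    theta <- atan2(Q, P)
    ct <- as.numeric(cos(theta)); st <- as.numeric(sin(theta))
    xr <- xs * ct - ys * st
    yr <- xs * st + ys * ct
    xs <- xr; ys <- yr
    new_cons <- cbind(colMeans(xs), colMeans(ys))
    new_cons <- center_config(new_cons)
    new_cons <- new_cons / sqrt(sum(new_cons^2))
    delta <- sqrt(mean((new_cons - consensus)^2))
    consensus <- new_cons
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  if (!converged) {
    warn(sprintf("GPA did not converge in %d iterations (last change %.3g).", iter, delta))
  }

  # principal-axis standardization: rotation only (det +1), deterministic sign
  pc <- eigen(crossprod(consensus), symmetric = TRUE)$vectors
  if (det(pc) < 0) pc[, 2] <- -pc[, 2]
  rot_all <- function(R) {
    xr <- xs * R[1, 1] + ys * R[2, 1]
    yr <- xs * R[1, 2] + ys * R[2, 2]
    xs <<- xr; ys <<- yr
    consensus <<- consensus %*% R
  }
  rot_all(pc)
  j <- which.max(abs(consensus[, 1]))
  if (consensus[j, 1] < 0) rot_all(diag(c(-1, -1))) # 180-degree turn

  aligned <- data
  aligned[coord_names(k)] <- as.data.frame(cbind(xs, ys))
  aligned$cs <- cs
  aligned$log_cs <- log(cs)
  structure(
    list(consensus = consensus, aligned = tibble::as_tibble(aligned),
         k = k, n_iterations = iter, converged = converged, tol = tol),
    class = "procrustes_fit"
  )
}

#' @export
print.procrustes_fit <- function(x, ...) {
  cat(sprintf(
    "Generalized Procrustes fit: %d configurations, %d landmarks\n%s after %d iterations (tol %.1e)\n",
    nrow(x$aligned), x$k,
    if (x$converged) "converged" else "NOT converged", x$n_iterations, x$tol
  ))
  invisible(x)
}

#' Tangent-space shape variables from a Procrustes fit
#'
#' Flattens each aligned configuration, subtracts the consensus, and
#' orthogonally projects the residual onto the tangent plane at the consensus
#' (removing any residual components along the four similarity directions).
#' The resulting coordinates span at most `2k - 4` dimensions and are the
#' input to all downstream multivariate statistics.
#'
#' @param fit A [gpa()] fit.
#' @return A landmark table of tangent coordinates (same `x*`/`y*` column
#'   convention, interpreted as deviations from the consensus) with the
#'   original metadata plus `cs` and `log_cs`.
#' @export
shape_variables <- function(fit) {
  stopifnot(inherits(fit, "procrustes_fit"))
  k <- fit$k
  A <- coord_matrix(fit$aligned)
  cvec <- flatten_config(fit$consensus)
  B <- similarity_basis(fit$consensus)
  resid <- sweep(A, 2, cvec)
  tang <- resid - (resid %*% B) %*% t(B)
  out <- fit$aligned
  out[coord_names(k)] <- as.data.frame(tang)
  out
}

#' Flag outlier configurations in a Procrustes fit
#'
#' Flags configurations whose full Procrustes distance to the consensus
#' exceeds the given quantile of the empirical distance distribution --
#' the usual screen for landmarking mistakes (e.g. swapped landmarks).
#'
#' @param fit A [gpa()] fit with at least 2 configurations.
#' @param threshold_quantile Quantile of the distance distribution above
#'   which a configuration is flagged (default 0.999).
#' @return Tibble of the fit's metadata with `distance` and `flagged`
#'   columns.
#' @export
detect_outliers <- function(fit, threshold_quantile = 0.999) {
  stopifnot(inherits(fit, "procrustes_fit"))
  A <- coord_matrix(fit$aligned)
  cvec <- flatten_config(fit$consensus)
  d <- sqrt(rowSums(sweep(A, 2, cvec)^2))
  thr <- quantile(d, threshold_quantile, names = FALSE)
  out <- fit$aligned[setdiff(names(fit$aligned), coord_names(fit$k))]
  out$distance <- d
  out$flagged <- d > thr
  tibble::as_tibble(out)
}

#' Average replicate configurations per specimen
#'
#' With replicated photography/digitization, between-group analyses run on
#' one averaged shape per specimen: coordinates (aligned or tangent) and
#' `log_cs` are averaged across a specimen's replicates; classifier columns
#' must be constant within specimen and are kept.
#'
#' @param data A landmark table carrying a `specimen_id` column (typically
#'   the output of [shape_variables()]).
#' @param by Grouping column, default `"specimen_id"`.
#' @return One row per specimen.
#' @export
average_replicates <- function(data, by = "specimen_id") {
  if (!by %in% names(data)) abort(sprintf("Column '%s' not found.", by))
  k <- landmark_count(data)
  num_cols <- intersect(c(coord_names(k), "cs", "log_cs"), names(data))
  keep <- setdiff(names(data), c(num_cols, by, "image_id", "digitization_id",
                                 "config_id", "image_file"))
  const_cols <- keep[vapply(keep, function(cl) {
    all(tapply(data[[cl]], data[[by]], function(v) length(unique(v)) == 1L))
  }, TRUE)]
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(by, const_cols)))) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(num_cols), mean), .groups = "drop")
}
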