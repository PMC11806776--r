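# shared fixtures: all synthetic, built in code at test time

# a reproducible random k-landmark configuration
rand_config <- function(k, seed = 1) {
  withr::with_seed(seed, matrix(rnorm(2 * k), k, 2))
}

# apply an independent random similarity transform to every row
apply_random_similarity <- function(data, seed = 1) {
  k <- landmark_count(data)
  m <- coord_matrix(data)
  withr::with_seed(seed, {
    for (i in seq_len(nrow(m))) {
      cfg <- cbind(m[i, 1:k], m[i, k + 1:k])
      th <- runif(1, -pi, pi)
      s <- exp(runif(1, -1, 1))
      tr <- runif(2, -5, 5)
      R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
      cfg <- s * cfg %*% R
      cfg <- sweep(cfg, 2, -tr)
      m[i, ] <- c(cfg[, 1], cfg[, 2])
    }
  })
  set_coords(data, m)
}

# a small two-population x two-sex spec, defaults tuned for fast tests
small_spec <- function(n_per_group = 8, seed = 1, k17 = TRUE, ...) {
  args <- list(...)
  g <- default_groups()
  g$n <- rep(n_per_group, 4)
  do.call(synthetic_spec, modifyList(list(groups = g, seed = seed), args))
}

# a spec with no group effects and no allometry (null conditions)
null_spec <- function(n_per_group = 10, seed = 1, ...) {
  small_spec(n_per_group = n_per_group, seed = seed,
             population_effect = NULL, sex_effect = NULL,
             interaction_effect = NULL, allometry = NULL, ...)
}

# specimen-averaged tangent coordinates straight from a spec
specimen_shapes <- function(spec) {
  average_replicates(shape_variables(gpa(generate_dataset(spec))))
}

unflatten <- function(v) cbind(v[1:(length(v) / 2)], v[(length(v) / 2 + 1):length(v)])
coord_names_17 <- function() c(paste0("x", 1:17), paste0("y", 1:17))

# embed a 2-D point set in the tangent plane of a triangle (k = 3 has
# exactly 2k - 4 = 2 shape dimensions), so hand-computed Mahalanobis
# geometry carries over through the rank reduction unchanged
embed_2d <- function(pts, ids) {
  tri <- matrix(c(0, 0, 1, 0, 0.4, 0.9), 3, 2, byrow = TRUE)
  tri <- scale(tri, scale = FALSE)
  tri <- tri / centroid_size(tri)
  B <- similarity_basis(tri)
  # orthonormal complement of the similarity directions
  Q <- qr.Q(qr(cbind(B, diag(6))))[, 5:6]
  coords <- pts %*% t(Q)
  out <- tibble::as_tibble(as.data.frame(coords))
  names(out) <- c("x1", "x2", "x3", "y1", "y2", "y3")
  dplyr::bind_cols(tibble::tibble(id = ids), out)
}

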