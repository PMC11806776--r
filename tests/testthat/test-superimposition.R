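test_that("centroid size: unit square, homogeneity, brute-force oracle", {
  sq <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), 4, 2, byrow = TRUE)
  expect_equal(centroid_size(sq), sqrt(2), tolerance = 1e-12)

  cfg <- rand_config(17, seed = 5)
  expect_equal(centroid_size(3.7 * cfg), 3.7 * centroid_size(cfg), tolerance = 1e-12)

  # direct summation oracle
  ctr <- colMeans(cfg)
  acc <- 0
  for (i in seq_len(nrow(cfg))) acc <- acc + sum((cfg[i, ] - ctr)^2)
  expect_equal(centroid_size(cfg), sqrt(acc), tolerance = 1e-12)

  expect_error(centroid_size(matrix(1, 5, 2)), "Degenerate")
})

test_that("pairwise alignment: similarity-equivalent shapes have distance 0, mirrors do not", {
  tri <- matrix(c(0, 0, 2, 0, 1, 1.5), 3, 2, byrow = TRUE)
  moved <- 2.5 * tri %*% matrix(c(0, 1, -1, 0), 2, 2) # 90 degrees + scale
  moved <- sweep(moved, 2, c(-3, 7))
  expect_lt(align_pair(moved, tri)$distance, 1e-12)

  mirror <- tri %*% diag(c(-1, 1))
  expect_gt(align_pair(mirror, tri)$distance, 0.1)
})

test_that("pairwise full-Procrustes distance matches a rotation/scale grid search", {
  a <- rand_config(4, seed = 11)
  b <- rand_config(4, seed = 12)
  got <- align_pair(a, b)$distance

  ac <- scale(a, scale = FALSE); ac <- ac / sqrt(sum(ac^2))
  bc <- scale(b, scale = FALSE); bc <- bc / sqrt(sum(bc^2))
  best <- Inf
  for (th in seq(-pi, pi, by = 1e-4)) {
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    ar <- ac %*% R
    beta <- sum(ar * bc) # optimal scale at this angle, |ar| = 1
    best <- min(best, sqrt(sum((beta * ar - bc)^2)))
  }
  expect_equal(got, best, tolerance = 1e-4)
})

test_that("GPA collapses similarity-transformed copies of one shape", {
  base <- default_mean_shape()
  d <- as_landmark_tbl(rep(list(base), 12),
                       tibble::tibble(id = sprintf("c%02d", 1:12)))
  d <- apply_random_similarity(d, seed = 3)
  fit <- gpa(d)
  expect_true(fit$converged)
  A <- coord_matrix(fit$aligned)
  cons <- c(fit$consensus[, 1], fit$consensus[, 2])
  expect_lt(max(abs(sweep(A, 2, cons))), 1e-8)
  expect_lt(sum(sweep(A, 2, cons)^2), 1e-15) # total Procrustes variance ~ 0
})

test_that("GPA consensus is the fixpoint mean of the aligned configurations", {
  d <- generate_dataset(small_spec(n_per_group = 4, seed = 2))
  fit <- gpa(d)
  A <- coord_matrix(fit$aligned)
  cons <- c(fit$consensus[, 1], fit$consensus[, 2])
  mean_aligned <- colMeans(A)
  mean_aligned_shape <- cbind(mean_aligned[1:17], mean_aligned[17 + 1:17])
  mean_aligned_shape <- mean_aligned_shape / centroid_size(mean_aligned_shape)
  expect_lt(max(abs(c(mean_aligned_shape) - c(fit$consensus))), 1e-8)
  expect_equal(centroid_size(fit$consensus), 1, tolerance = 1e-9)
  expect_lt(max(abs(colMeans(fit$consensus))), 1e-12)
})

test_that("two-configuration GPA reproduces the pairwise distance", {
  a <- rand_config(6, seed = 21)
  b <- a + withr::with_seed(22, matrix(rnorm(12, 0, 0.005), 6, 2))
  d <- as_landmark_tbl(list(a, b), tibble::tibble(id = c("a", "b")))
  fit <- gpa(d)
  A <- coord_matrix(fit$aligned)
  gpa_dist <- sqrt(sum((A[1, ] - A[2, ])^2))
  expect_lt(abs(gpa_dist - align_pair(a, b)$distance), 1e-6)
  expect_lt(abs(procrustes_distance(unflatten(A[1, ]), unflatten(A[2, ])) -
                  align_pair(a, b)$distance), 1e-6)
})

test_that("original centroid sizes are recorded before unit scaling", {
  d <- generate_dataset(small_spec(n_per_group = 3, seed = 4))
  fit <- gpa(d)
  expect_equal(fit$aligned$cs, centroid_size(d), tolerance = 1e-9)
  expect_equal(fit$aligned$log_cs, log(centroid_size(d)), tolerance = 1e-9)
})

test_that("shape variables are centered, tangent and rank-deficient by 4", {
  d <- generate_dataset(small_spec(n_per_group = 8, seed = 5))
  sv <- shape_variables(gpa(d))
  Y <- coord_matrix(sv)
  expect_lt(max(abs(colMeans(Y))), 1e-8)
  ev <- eigen(crossprod(sweep(Y, 2, colMeans(Y))), symmetric = TRUE,
              only.values = TRUE)$values
  expect_lt(max(tail(ev, 4)), 1e-10)
  expect_gt(ev[30], 1e-10) # 2k - 4 = 30 informative dimensions for k = 17
})

test_that("identical configurations give all-zero shape variables", {
  base <- default_mean_shape()
  d <- as_landmark_tbl(rep(list(base), 5),
                       tibble::tibble(id = sprintf("c%d", 1:5)))
  sv <- shape_variables(gpa(d))
  expect_lt(max(abs(coord_matrix(sv))), 1e-10)
})

test_that("GPA output is invariant to input row order", {
  d <- generate_dataset(small_spec(n_per_group = 5, seed = 6))
  fit1 <- gpa(d)
  perm <- withr::with_seed(9, sample(nrow(d)))
  fit2 <- gpa(d[perm, ])
  expect_lt(max(abs(fit1$consensus - fit2$consensus)), 1e-6)
  expect_lt(max(abs(coord_matrix(fit1$aligned) -
                      coord_matrix(fit2$aligned)[order(perm), ])), 1e-6)
})

test_that("a swapped landmark pair is flagged as an outlier", {
  spec <- small_spec(n_per_group = 10, seed = 7)
  d <- generate_dataset(spec)
  m <- coord_matrix(d)
  # swap landmarks 1 and 12 of the first configuration
  m[1, c(1, 12, 17 + 1, 17 + 12)] <- m[1, c(12, 1, 17 + 12, 17 + 1)]
  d2 <- set_coords(d, m)
  out <- detect_outliers(gpa(d2), threshold_quantile = 0.99)
  expect_true(out$flagged[1])
  clean <- detect_outliers(gpa(d), threshold_quantile = 0.999)
  expect_lte(sum(clean$flagged), 1)
})

test_that("replicate averaging keeps classifiers and averages coordinates", {
  d <- generate_dataset(small_spec(n_per_group = 3, seed = 8))
  sv <- shape_variables(gpa(d))
  av <- average_replicates(sv)
  expect_equal(nrow(av), 12)
  one <- sv[sv$specimen_id == av$specimen_id[1], ]
  expect_equal(as.numeric(av[1, coord_names_17()]),
               colMeans(coord_matrix(one)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(all(c("population", "sex", "log_cs") %in% names(av)))
})
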