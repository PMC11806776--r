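test_that("two-group Mahalanobis distance matches the pencil-and-paper toy", {
  g1 <- matrix(c(0, 0, 1, 0, 0, 1), 3, 2, byrow = TRUE)
  g2 <- sweep(g1, 2, c(-3, 0))
  d <- embed_2d(rbind(g1, g2), sprintf("s%d", 1:6))
  d$group <- rep(c("a", "b"), each = 3)
  res <- dfa(d, "group", n_perm = 19, seed = 1)
  # W = [[1/3, -1/6], [-1/6, 1/3]], dvec = (3, 0) => D^2 = 36
  expect_equal(res$mahalanobis_d, 6, tolerance = 1e-8)
  expect_equal(res$T2, (3 * 3 / 6) * 36, tolerance = 1e-8)
  expect_equal(res$procrustes_d, 3, tolerance = 1e-10)
})

test_that("T2 identity and permutation-p bounds hold for arbitrary input", {
  sv <- specimen_shapes(small_spec(n_per_group = 6, seed = 61))
  res <- dfa(sv, "sex", n_perm = 99, seed = 5)
  n1 <- sum(sv$sex == "F"); n2 <- sum(sv$sex == "M")
  expect_equal(res$T2, (n1 * n2 / (n1 + n2)) * res$mahalanobis_d^2,
               tolerance = 1e-10)
  expect_gte(res$p_perm_mahalanobis, 1 / 100)
  expect_gte(res$p_perm_procrustes, 1 / 100)
  expect_lte(res$p_perm_mahalanobis, 1)
})

test_that("Mahalanobis distance is invariant to affine maps of the shape scores", {
  pts <- withr::with_seed(63, matrix(rnorm(40), 20, 2))
  pts[11:20, 1] <- pts[11:20, 1] + 2
  d1 <- embed_2d(pts, sprintf("s%d", 1:20))
  A <- matrix(c(2, 0.5, -1, 1.5), 2, 2)
  d2 <- embed_2d(sweep(pts %*% A, 2, c(3, -4)), sprintf("s%d", 1:20))
  d1$group <- d2$group <- rep(c("a", "b"), each = 10)
  r1 <- dfa(d1, "group", n_perm = 9, seed = 1)
  r2 <- dfa(d2, "group", n_perm = 9, seed = 1)
  expect_equal(r1$mahalanobis_d, r2$mahalanobis_d, tolerance = 1e-6)
})

test_that("DFA's Procrustes distance agrees with the superimposition module", {
  # tiny effect: tangent-space Euclidean and full Procrustes distances agree
  g <- tibble::tibble(population = c("H1", "H1"), sex = c("F", "M"),
                      n = c(10L, 10L))
  spec <- synthetic_spec(groups = g, population_effect = NULL,
                         sex_effect = default_sex_effect(default_mean_shape(),
                                                         magnitude = 1e-4),
                         allometry = NULL, individual_noise_sd = 0,
                         image_noise_sd = 0, digitization_noise_sd = 0,
                         n_images_per_specimen = 1L,
                         n_digitizations_per_image = 1L, seed = 65)
  fit <- gpa(generate_dataset(spec))
  sv <- average_replicates(shape_variables(fit))
  res <- dfa(sv, "sex", n_perm = 9, seed = 1)
  Y <- coord_matrix(sv)
  mF <- unflatten(colMeans(Y[sv$sex == "F", ]))
  mM <- unflatten(colMeans(Y[sv$sex == "M", ]))
  d_full <- procrustes_distance(fit$consensus + mF, fit$consensus + mM)
  expect_lt(abs(res$procrustes_d - d_full), 1e-9)
})

test_that("well-separated groups classify perfectly under the jackknife", {
  g <- tibble::tibble(population = c("H1", "H1"), sex = c("F", "M"),
                      n = c(12L, 12L))
  spec <- synthetic_spec(groups = g, population_effect = NULL,
                         sex_effect = default_sex_effect(default_mean_shape(),
                                                         magnitude = 0.3),
                         allometry = NULL, individual_noise_sd = 0.01,
                         image_noise_sd = 0, digitization_noise_sd = 0,
                         n_images_per_specimen = 1L,
                         n_digitizations_per_image = 1L, seed = 67)
  sv <- specimen_shapes(spec)
  cls <- jackknife_classify(sv, "sex")
  expect_equal(cls$pct_correct_jackknife, 100)
  expect_equal(cls$pct_correct_resubstitution, 100)
  tab <- cls$jackknife
  expect_equal(unname(tab$total), c(12, 12))
  expect_equal(tab$F[1] + tab$M[1], 12) # rows sum to group sizes
})

test_that("two-group CVA spans the discriminant axis and is scaled to unit within-variance", {
  sv <- specimen_shapes(small_spec(n_per_group = 8, seed = 69))
  res_d <- dfa(sv, "sex", n_perm = 9, seed = 1)
  res_c <- cva(sv, "sex", n_perm = 9, seed = 1)
  expect_equal(length(res_c$values), 1L)
  corr <- abs(sum(res_c$axes[, 1] * res_d$axis) /
                sqrt(sum(res_c$axes[, 1]^2) * sum(res_d$axis^2)))
  expect_gt(corr, 1 - 1e-6)
  # pooled within-group variance of CV1 scores is 1
  s <- res_c$scores
  v <- (sum((s$CV1[s$sex == "F"] - mean(s$CV1[s$sex == "F"]))^2) +
          sum((s$CV1[s$sex == "M"] - mean(s$CV1[s$sex == "M"]))^2)) /
    (nrow(s) - 2)
  expect_equal(v, 1, tolerance = 1e-8)
})

test_that("four groups give three axes with percents summing to 100", {
  sv <- specimen_shapes(small_spec(n_per_group = 6, seed = 71))
  sv$group <- paste(sv$population, sv$sex, sep = "_")
  res <- cva(sv, "group", n_perm = 19, seed = 2)
  expect_equal(length(res$values), 3L)
  expect_equal(sum(res$pct), 100, tolerance = 1e-9)
  expect_equal(nrow(res$pairwise), 6L)
  expect_true(all(res$pairwise$p_perm_mahalanobis >= 1 / 20))
  # orthogonal population and sex effects separate the four group means
  gm <- res$scores |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(CV1 = mean(.data$CV1), CV2 = mean(.data$CV2))
  dd <- as.matrix(dist(gm[, c("CV1", "CV2")]))
  expect_gt(min(dd[upper.tri(dd)]), 0.5)
})

test_that("group labels and errors are validated", {
  sv <- specimen_shapes(small_spec(n_per_group = 4, seed = 73))
  expect_error(dfa(sv, "specimen_id"), "exactly 2")
  sv$group <- paste(sv$population, sv$sex, sep = "_")
  expect_error(dfa(sv, "group"), "exactly 2")
  tiny <- sv[c(1:2, 9:12), ] # 2 specimens in H1, 4 in H2
  expect_error(dfa(tiny, "population"), "at least 3")
})
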