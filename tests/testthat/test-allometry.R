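test_that("a perfectly allometric dataset gives 100% predicted and minimal p", {
  ms <- default_mean_shape()
  beta <- default_allometry(ms, magnitude = 0.1)
  sizes <- seq(-0.3, 0.3, length.out = 12)
  configs <- lapply(sizes, function(s) ms + unflatten(beta * s))
  d <- as_landmark_tbl(configs, tibble::tibble(id = sprintf("c%02d", 1:12)))
  sv <- shape_variables(gpa(d))
  sv$log_cs <- sizes # use the controlled covariate directly
  res <- regress_shape_on_size(sv, "log_cs", n_perm = 99, seed = 1)
  expect_gt(res$pct_predicted, 100 - 1e-4)
  expect_equal(res$p_perm, 1 / 100)
  expect_lt(max(abs(coord_matrix(res$residuals))), 1e-5)
})

test_that("the injected allometric direction is recovered at n = 100", {
  g <- tibble::tibble(population = "H1", sex = "F", n = 100L)
  beta_true <- default_allometry(default_mean_shape(), magnitude = 0.15)
  spec <- synthetic_spec(groups = g, population_effect = NULL,
                         sex_effect = NULL, allometry = beta_true,
                         log_cs = c(0.8, 0.1),
                         individual_noise_sd = 0.005,
                         image_noise_sd = 0, digitization_noise_sd = 0,
                         n_images_per_specimen = 1L,
                         n_digitizations_per_image = 1L, seed = 81)
  fit <- gpa(generate_dataset(spec))
  sv <- average_replicates(shape_variables(fit))
  res <- regress_shape_on_size(sv, "log_cs", n_perm = 99, seed = 2)
  # the fitted slope lives in the consensus frame, which GPA standardizes
  # to principal axes; rotate the injected vector into that frame first
  ang <- align_pair(default_mean_shape(), fit$consensus)$angle
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
  beta_rot <- c(unflatten(beta_true) %*% R)
  corr <- abs(sum(res$beta * beta_rot) /
                sqrt(sum(res$beta^2) * sum(beta_rot^2)))
  expect_gt(corr, 0.95)
  expect_lt(res$p_perm, 0.05)
  # slope is tangent to shape space at the consensus
  expect_lt(max(abs(crossprod(similarity_basis(fit$consensus),
                              res$beta))), 1e-6)
})

test_that("pooled-within and total regressions agree when group means coincide", {
  allo <- default_allometry(default_mean_shape(), magnitude = 0.15)
  sv <- specimen_shapes(null_spec(n_per_group = 12, seed = 83,
                                  allometry = allo,
                                  log_cs = c(0.8, 0.08), # same size law everywhere
                                  individual_noise_sd = 0.004,
                                  n_images_per_specimen = 1L,
                                  n_digitizations_per_image = 1L))
  r_tot <- regress_shape_on_size(sv, "log_cs", n_perm = 9, seed = 1)
  r_pool <- regress_shape_on_size(sv, "log_cs", "population",
                                  pooled_within = TRUE, n_perm = 9, seed = 1)
  # identical group mean shapes and sizes in expectation: slopes nearly equal
  expect_gt(abs(sum(r_tot$beta * r_pool$beta)) /
              sqrt(sum(r_tot$beta^2) * sum(r_pool$beta^2)), 0.95)

  # exact agreement when the groups are literally identical
  sv2 <- sv
  sv2$population <- "all"
  r_pool2 <- regress_shape_on_size(sv2, "log_cs", "population",
                                   pooled_within = TRUE, n_perm = 9, seed = 1)
  expect_equal(r_pool2$pct_predicted, r_tot$pct_predicted, tolerance = 1e-8)
  expect_equal(r_pool2$beta, r_tot$beta, tolerance = 1e-8)
})

test_that("percent predicted is invariant to affine rescaling of the size axis", {
  sv <- specimen_shapes(small_spec(n_per_group = 6, seed = 85,
                                   n_images_per_specimen = 1L,
                                   n_digitizations_per_image = 1L))
  r1 <- regress_shape_on_size(sv, "log_cs", n_perm = 9, seed = 1)
  sv$log_cs <- 3.2 * sv$log_cs - 1.7
  r2 <- regress_shape_on_size(sv, "log_cs", n_perm = 9, seed = 1)
  expect_equal(r1$pct_predicted, r2$pct_predicted, tolerance = 1e-10)
  expect_equal(r2$beta, r1$beta / 3.2, tolerance = 1e-10)
})

test_that("degenerate size inputs are rejected", {
  sv <- specimen_shapes(small_spec(n_per_group = 3, seed = 87))
  sv$log_cs <- 1
  expect_error(regress_shape_on_size(sv, "log_cs"), "nonzero variance")
  expect_error(regress_shape_on_size(sv[1:3, ], "log_cs"), "at least 4")
})

test_that("MANCOVA keeps its type-I error under parallel slopes and sees crossed slopes", {
  beta <- default_allometry(default_mean_shape(), magnitude = 0.12)
  run_once <- function(seed, flip) {
    allo <- list("H1:F" = beta, "H1:M" = if (flip) -beta else beta,
                 "H2:F" = beta, "H2:M" = if (flip) -beta else beta)
    g <- default_groups()
    g$n <- rep(15L, 4)
    spec <- synthetic_spec(groups = g, population_effect = NULL,
                           sex_effect = NULL, allometry = allo,
                           individual_noise_sd = 0.006,
                           image_noise_sd = 0, digitization_noise_sd = 0,
                           n_images_per_specimen = 1L,
                           n_digitizations_per_image = 1L, seed = seed)
    sv <- specimen_shapes(spec)
    tab <- tidy(mancova_trajectories(sv, "log_cs", "sex", retain = 0.9))
    tab$p[grepl(" x ", tab$effect)]
  }
  p_crossed <- vapply(1:10, run_once, 0, flip = TRUE)
  expect_gte(sum(p_crossed < 0.05), 9) # opposite slopes: near-certain rejection
  p_null <- vapply(11:25, run_once, 0, flip = FALSE)
  expect_lte(sum(p_null < 0.05), 4) # parallel slopes: rejections stay rare
})

test_that("MANCOVA demands at least two groups", {
  sv <- specimen_shapes(small_spec(n_per_group = 5, seed = 89))
  sv1 <- sv[sv$population == "H1" & sv$sex == "F", ]
  expect_error(mancova_trajectories(sv1, "log_cs", "sex"), "at least 2")
})
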