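test_that("degenerate spec reproduces the mean shape up to scale", {
  g <- tibble::tibble(population = "H1", sex = "F", n = 2L)
  spec <- synthetic_spec(groups = g, population_effect = NULL,
                         sex_effect = NULL, allometry = NULL,
                         log_cs = c(0.5, 0),
                         individual_noise_sd = 0, image_noise_sd = 0,
                         digitization_noise_sd = 0,
                         nuisance = list(enabled = FALSE,
                                         rotation = c(0, 0),
                                         translation = c(0, 0)))
  d <- generate_dataset(spec)
  expect_equal(nrow(d), 2 * 2 * 2)
  ms <- default_mean_shape()
  for (cfg in config_list(d)) {
    expect_lt(max(abs(cfg / centroid_size(cfg) - ms)), 1e-12)
    expect_equal(centroid_size(cfg), exp(0.5), tolerance = 1e-12)
  }
})

test_that("default study design yields 129 specimens and 516 configurations", {
  d <- generate_dataset(synthetic_spec(seed = 3))
  expect_equal(length(unique(d$specimen_id)), 129L)
  expect_equal(nrow(d), 516L)
  counts <- dplyr::distinct(d, .data$specimen_id, .data$population, .data$sex) |>
    dplyr::count(.data$population, .data$sex)
  expect_equal(counts$n, c(28L, 27L, 42L, 32L))
})

test_that("default effect and allometric vectors are tangent at the mean shape", {
  ms <- default_mean_shape()
  b <- similarity_basis(ms)
  for (v in list(default_population_effect(ms), default_sex_effect(ms),
                 default_allometry(ms))) {
    expect_lt(max(abs(crossprod(b, v))), 1e-10)
  }
})

test_that("non-tangent effects are rejected unless projection is requested", {
  bad <- rep(1, 34) # has a translation component
  expect_error(synthetic_spec(sex_effect = bad), "tangent")
  spec <- synthetic_spec(sex_effect = bad, project_effects = TRUE)
  expect_lt(max(abs(crossprod(similarity_basis(spec$mean_shape),
                              spec$sex_effect))), 1e-10)
  expect_error(synthetic_spec(groups = tibble::tibble(
    population = "H1", sex = "F", n = 0L)), "at least one")
})

test_that("injected sex effect is recovered as the between-sex mean distance", {
  g <- tibble::tibble(population = c("H1", "H1"), sex = c("F", "M"),
                      n = c(60L, 60L))
  spec <- synthetic_spec(groups = g, population_effect = NULL,
                         sex_effect = default_sex_effect(default_mean_shape(),
                                                         magnitude = 0.06),
                         allometry = NULL, individual_noise_sd = 0.003,
                         image_noise_sd = 0, digitization_noise_sd = 0,
                         n_images_per_specimen = 1L,
                         n_digitizations_per_image = 1L, seed = 11)
  sv <- specimen_shapes(spec)
  Y <- coord_matrix(sv)
  dhat <- sqrt(sum((colMeans(Y[sv$sex == "M", ]) -
                      colMeans(Y[sv$sex == "F", ]))^2))
  # mean-estimate noise inflates the distance by at most ~sd*sqrt(2*30/60)
  expect_lt(abs(dhat - 0.06), 0.004)
})

test_that("doubling the sex effect doubles the between-sex distance (noise-free)", {
  g <- tibble::tibble(population = c("H1", "H1"), sex = c("F", "M"), n = c(5L, 5L))
  base_args <- list(groups = g, population_effect = NULL, allometry = NULL,
                    individual_noise_sd = 0, image_noise_sd = 0,
                    digitization_noise_sd = 0, n_images_per_specimen = 1L,
                    n_digitizations_per_image = 1L, seed = 5)
  dist_for <- function(mag) {
    spec <- do.call(synthetic_spec, c(base_args, list(
      sex_effect = default_sex_effect(default_mean_shape(), magnitude = mag))))
    sv <- specimen_shapes(spec)
    Y <- coord_matrix(sv)
    sqrt(sum((colMeans(Y[sv$sex == "M", ]) - colMeans(Y[sv$sex == "F", ]))^2))
  }
  # curvature of shape space enters only at second order, so small
  # magnitudes make the additivity exact to alignment tolerance
  d1 <- dist_for(0.005)
  d2 <- dist_for(0.010)
  expect_equal(d2 / d1, 2, tolerance = 1e-4)
  expect_equal(d1, 0.005, tolerance = 1e-4)
})

test_that("nuisance transforms leave shape variables unchanged (same seed)", {
  spec_on <- small_spec(n_per_group = 5, seed = 17)
  spec_off <- small_spec(n_per_group = 5, seed = 17,
                         nuisance = list(enabled = FALSE,
                                         rotation = c(-pi, pi),
                                         translation = c(-1, 1)))
  sv_on <- shape_variables(gpa(generate_dataset(spec_on)))
  sv_off <- shape_variables(gpa(generate_dataset(spec_off)))
  rms <- sqrt(mean((coord_matrix(sv_on) - coord_matrix(sv_off))^2))
  expect_lt(rms, 1e-6)
})

test_that("true log centroid size is realized exactly in the emitted configurations", {
  d <- generate_dataset(small_spec(n_per_group = 3, seed = 19))
  expect_equal(log(centroid_size(d)), d$true_log_cs, tolerance = 1e-9)
})

test_that("a spec survives a YAML round-trip and regenerates identically", {
  spec <- small_spec(n_per_group = 3, seed = 23)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_synthetic_spec(spec, f)
  spec2 <- read_synthetic_spec(f)
  d1 <- generate_dataset(spec)
  d2 <- generate_dataset(spec2)
  expect_equal(d1$id, d2$id)
  expect_lt(max(abs(coord_matrix(d1) - coord_matrix(d2))), 1e-9)
})
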