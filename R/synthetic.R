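#' Specify a synthetic replicated landmark study
#'
#' Parameterizes a simulated two-factor landmark study with replicated
#' photography and digitization, mirroring a design in which specimens from
#' two populations and both sexes are each photographed `n_images` times and
#' every photo digitized `n_digitizations` times.  The generator draws, per
#' specimen, a true log centroid size and an individual shape deviation; adds
#' fixed population / sex / interaction shape effects and an optional
#' allometric shape component proportional to (log CS minus the group mean
#' log CS); then layers photo-level and digitization-level jitter, and
#' finally hands each emitted configuration a random rotation and
#' translation and scales it to its true centroid size.
#'
#' All effect and allometric vectors live in the tangent (pure-shape)
#' subspace at `mean_shape`: they must be orthogonal to the translation,
#' scaling and rotation directions.  Supply them via [effect_direction()] or
#' set `project_effects = TRUE` to have non-tangent inputs projected.
#'
#' Default group sizes follow the emulated study: populations H1 (28 F +
#' 27 M) and H2 (42 F + 32 M), 129 specimens, each digitized 2 x 2 times.
#' Default effect magnitudes are illustrative values on the scale that
#' study reports (see the methods vignette).
#'
#' @param mean_shape `k x 2` base shape (centered to unit centroid size
#'   internally).  Default [default_mean_shape()].
#' @param groups Data frame with columns `population`, `sex`, `n`.
#' @param population_effect,sex_effect,interaction_effect Tangent vectors of
#'   length `2k` (difference between factor-level means; half is added to
#'   each side).  `NULL` means zero.
#' @param allometry Allometric shape change per unit log CS: `NULL` (none),
#'   a single `2k` tangent vector shared by all groups, or a named list
#'   keyed `"<population>:<sex>"`.
#' @param log_cs Data frame with columns `population`, `sex`, `mean`, `sd`
#'   giving the log centroid size distribution per group; or a single
#'   `c(mean, sd)` used for all groups.
#' @param individual_noise_sd,image_noise_sd,digitization_noise_sd Isotropic
#'   per-coordinate Gaussian SDs for biological variation, photo jitter and
#'   digitizing jitter (shape-space units; the mean shape has centroid size 1).
#' @param n_images_per_specimen,n_digitizations_per_image Replicate counts.
#' @param nuisance List with `enabled` flag and uniform `rotation` (radians)
#'   and `translation` ranges for the random similarity transform applied to
#'   each emitted configuration.
#' @param project_effects If `TRUE`, project supplied effect vectors into the
#'   tangent subspace instead of rejecting non-tangent input.
#' @param seed Integer RNG seed; each tier of randomness (specimen, image,
#'   digitization, nuisance) uses its own deterministic substream so any one
#'   tier can be toggled without perturbing the others.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(mean_shape = default_mean_shape(),
                           groups = default_groups(),
                           population_effect = default_population_effect(mean_shape),
                           sex_effect = default_sex_effect(mean_shape),
                           interaction_effect = NULL,
                           allometry = default_allometry(mean_shape),
                           log_cs = default_log_cs(),
                           individual_noise_sd = 0.010,
                           image_noise_sd = 0.002,
                           digitization_noise_sd = 0.002,
                           n_images_per_specimen = 2L,
                           n_digitizations_per_image = 2L,
                           nuisance = list(enabled = TRUE,
                                           rotation = c(-pi, pi),
                                           translation = c(-1, 1)),
                           project_effects = FALSE,
                           seed = 1L) {
  k <- nrow(mean_shape)
  if (k < 3L) abort("mean_shape needs at least 3 landmarks.")
  mean_shape <- center_config(as.matrix(mean_shape))
  mean_shape <- mean_shape / centroid_size(mean_shape)

  groups <- tibble::as_tibble(groups)
  stopifnot(all(c("population", "sex", "n") %in% names(groups)))
  if (any(groups$n < 1L)) abort("Every group needs at least one specimen.")

  fix_effect <- function(v, name) {
    if (is.null(v)) return(rep(0, 2L * k))
    if (length(v) != 2L * k) abort(sprintf("%s must have length 2k = %d.", name, 2L * k))
    if (!is_tangent_vector(v, mean_shape)) {
      if (project_effects) v <- project_tangent_vector(v, mean_shape)
      else abort(sprintf(
        "%s is not in the tangent subspace at mean_shape (set project_effects = TRUE to project).",
        name))
    }
    as.numeric(v)
  }
  population_effect <- fix_effect(population_effect, "population_effect")
  sex_effect <- fix_effect(sex_effect, "sex_effect")
  interaction_effect <- fix_effect(interaction_effect, "interaction_effect")

  keys <- paste(groups$population, groups$sex, sep = ":")
  if (is.null(allometry)) {
    allometry <- setNames(rep(list(rep(0, 2L * k)), length(keys)), keys)
  } else if (is.numeric(allometry)) {
    allometry <- setNames(rep(list(as.numeric(allometry)), length(keys)), keys)
  }
  if (!all(keys %in% names(allometry))) {
    abort("allometry list must have an entry for every '<population>:<sex>' group.")
  }
  allometry <- lapply(setNames(nm = keys), function(kk) fix_effect(allometry[[kk]], paste0("allometry[", kk, "]")))

  if (is.numeric(log_cs) && length(log_cs) == 2L) {
    log_cs <- tibble::tibble(population = groups$population, sex = groups$sex,
                             mean = log_cs[1], sd = log_cs[2])
  }
  log_cs <- tibble::as_tibble(log_cs)
  stopifnot(all(c("population", "sex", "mean", "sd") %in% names(log_cs)))

  sds <- c(individual_noise_sd, image_noise_sd, digitization_noise_sd, log_cs$sd)
  if (any(sds < 0)) abort("All standard deviations must be >= 0.")
  if (n_images_per_specimen < 1L || n_digitizations_per_image < 1L) {
    abort("Replicate counts must be >= 1.")
  }

  structure(
    list(mean_shape = mean_shape, k = k, groups = groups,
         population_effect = population_effect, sex_effect = sex_effect,
         interaction_effect = interaction_effect, allometry = allometry,
         log_cs = log_cs,
         individual_noise_sd = individual_noise_sd,
         image_noise_sd = image_noise_sd,
         digitization_noise_sd = digitization_noise_sd,
         n_images_per_specimen = as.integer(n_images_per_specimen),
         n_digitizations_per_image = as.integer(n_digitizations_per_image),
         nuisance = nuisance, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(
    "Synthetic landmark study: k = %d, %d specimens (%d groups), %d x %d replicates, seed %d\n",
    x$k, sum(x$groups$n), nrow(x$groups),
    x$n_images_per_specimen, x$n_digitizations_per_image, x$seed
  ))
  invisible(x)
}

#' Default group layout of the emulated study design
#' @return Tibble with `population`, `sex`, `n`.
#' @export
default_groups <- function() {
  tibble::tibble(
    population = c("H1", "H1", "H2", "H2"),
    sex = c("F", "M", "F", "M"),
    n = c(28L, 27L, 42L, 32L)
  )
}

#' Default log centroid size distribution per group
#'
#' The second population runs slightly larger; sexes share the size
#' distribution (no size dimorphism).  Units: natural log of centroid size
#' in image units.
#' @return Tibble with `population`, `sex`, `mean`, `sd`.
#' @export
default_log_cs <- function() {
  g <- default_groups()
  tibble::tibble(population = g$population, sex = g$sex,
                 mean = ifelse(g$population == "H1", 0.74, 0.82),
                 sd = 0.08)
}

#' Build a tangent effect vector from a coordinate displacement pattern
#'
#' Projects an arbitrary `k x 2` displacement pattern into the tangent
#' subspace at `shape` and rescales it to the requested Procrustes
#' magnitude (Euclidean norm in tangent coordinates, which for small effects
#' equals the Procrustes distance the effect induces between group means).
#'
#' @param pattern `k x 2` displacement matrix.
#' @param shape Reference shape (`k x 2`).
#' @param magnitude Target norm of the projected vector.
#' @return Tangent vector of length `2k`.
#' @export
effect_direction <- function(pattern, shape, magnitude) {
  v <- project_tangent_vector(flatten_config(as.matrix(pattern)), shape)
  nv <- sqrt(sum(v^2))
  if (nv == 0) abort("Pattern projects to zero in the tangent subspace.")
  v / nv * magnitude
}

#' Default population shape effect (cephalic protrusion vs lateral expansion)
#' @param mean_shape Reference shape.
#' @param magnitude Procrustes magnitude (default 0.017).
#' @return Tangent vector of length `2k`.
#' @export
default_population_effect <- function(mean_shape, magnitude = 0.017) {
  k <- nrow(mean_shape)
  regions <- if (k == 17L) default_landmark_regions() else
    rep(c("cephalica", "thoracica"), c(ceiling(k / 2), floor(k / 2)))
  pat <- matrix(0, k, 2)
  ceph <- regions == "cephalica"
  pat[ceph, 2] <- -0.5                         # cephalic region recedes
  pat[!ceph, 1] <- sign(mean_shape[!ceph, 1])  # lateral sides expand
  effect_direction(pat, mean_shape, magnitude)
}

#' Default sex shape effect (posterior widening vs anterior elevation)
#' @inheritParams default_population_effect
#' @export
default_sex_effect <- function(mean_shape, magnitude = 0.07) {
  k <- nrow(mean_shape)
  regions <- if (k == 17L) default_landmark_regions() else
    rep(c("cephalica", "thoracica"), c(ceiling(k / 2), floor(k / 2)))
  pat <- matrix(0, k, 2)
  post <- regions == "thoracica" & mean_shape[, 2] < 0
  pat[post, 1] <- -0.7 * sign(mean_shape[post, 1]) # females wider behind
  pat[regions == "cephalica", 2] <- 0.4            # males' cephalica raised
  effect_direction(pat, mean_shape, magnitude)
}

#' Default common allometric vector (elongation with size)
#' @inheritParams default_population_effect
#' @param magnitude Shape change per unit log CS (default 0.08).
#' @export
default_allometry <- function(mean_shape, magnitude = 0.08) {
  pat <- cbind(-0.3 * mean_shape[, 1], mean_shape[, 2])
  effect_direction(pat, mean_shape, magnitude)
}

# deterministic substream seeds, one per randomness tier, all < 2^31
tier_seed <- function(seed, tier) {
  (abs(as.integer(seed)) * 7919L + tier * 104729L) %% 2147483629L
}

#' Generate a synthetic landmark dataset
#'
#' Draws the dataset described by a [synthetic_spec()]: one row per emitted
#' configuration (specimen x image x digitization), tagged with its
#' classifiers and true log centroid size.  Factor effects use the
#' level-difference convention: half the effect vector is added to the
#' second sorted level and subtracted from the first, so the Procrustes
#' distance between the two factor-level mean shapes equals the vector's
#' magnitude (noise-free).
#'
#' @param spec A [synthetic_spec()].
#' @return Landmark table with columns `id`, `specimen_id`, `population`,
#'   `sex`, `image_id`, `digitization_id`, `true_log_cs` and coordinates.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  k <- spec$k
  g <- spec$groups
  n_spec <- sum(g$n)
  r_img <- spec$n_images_per_specimen
  r_dig <- spec$n_digitizations_per_image

  pops <- rep(g$population, g$n)
  sexes <- rep(g$sex, g$n)
  keys <- paste(pops, sexes, sep = ":")
  pop_sign <- ifelse(pops == sort(unique(g$population))[1], -0.5, +0.5)
  sex_sign <- ifelse(sexes == sort(unique(g$sex))[1], -0.5, +0.5)

  lcs_tab <- spec$log_cs
  lcs_key <- paste(lcs_tab$population, lcs_tab$sex, sep = ":")
  lcs_mean <- lcs_tab$mean[match(keys, lcs_key)]
  lcs_sd <- lcs_tab$sd[match(keys, lcs_key)]
  if (any(is.na(lcs_mean))) abort("log_cs table is missing a group.")

  # tier 1: specimen-level randomness (sizes + individual shape noise)
  spec_draws <- withr::with_seed(tier_seed(spec$seed, 1L), {
    list(log_cs = rnorm(n_spec, lcs_mean, lcs_sd),
         noise = array(rnorm(n_spec * k * 2, 0, spec$individual_noise_sd),
                       dim = c(n_spec, k, 2)))
  })
  # tier 2: photo-level jitter
  img_noise <- withr::with_seed(tier_seed(spec$seed, 2L),
    array(rnorm(n_spec * r_img * k * 2, 0, spec$image_noise_sd),
          dim = c(n_spec, r_img, k, 2)))
  # tier 3: digitization-level jitter
  dig_noise <- withr::with_seed(tier_seed(spec$seed, 3L),
    array(rnorm(n_spec * r_img * r_dig * k * 2, 0, spec$digitization_noise_sd),
          dim = c(n_spec, r_img, r_dig, k, 2)))
  # tier 4: nuisance similarity transforms
  n_cfg <- n_spec * r_img * r_dig
  nuis <- withr::with_seed(tier_seed(spec$seed, 4L), list(
    angle = runif(n_cfg, spec$nuisance$rotation[1], spec$nuisance$rotation[2]),
    tx = runif(n_cfg, spec$nuisance$translation[1], spec$nuisance$translation[2]),
    ty = runif(n_cfg, spec$nuisance$translation[1], spec$nuisance$translation[2])
  ))

  counter <- tapply(seq_len(n_spec), keys, length)
  idx_in_group <- stats::ave(seq_len(n_spec), keys, FUN = seq_along)
  specimen_ids <- sprintf("%s%s%03d", pops, sexes, idx_in_group)

  configs <- vector("list", n_cfg)
  meta <- vector("list", n_cfg)
  cfg_i <- 0L
  for (i in seq_len(n_spec)) {
    tang <- pop_sign[i] * spec$population_effect +
      sex_sign[i] * spec$sex_effect +
      (2 * pop_sign[i] * sex_sign[i]) * spec$interaction_effect +
      spec$allometry[[keys[i]]] * (spec_draws$log_cs[i] - lcs_mean[i])
    base <- spec$mean_shape + unflatten_config(tang) + spec_draws$noise[i, , ]
    for (j in seq_len(r_img)) {
      img_cfg <- base + img_noise[i, j, , ]
      for (l in seq_len(r_dig)) {
        cfg_i <- cfg_i + 1L
        cfg <- img_cfg + dig_noise[i, j, l, , ]
        cfg <- center_config(cfg)
        cfg <- cfg / centroid_size(cfg) * exp(spec_draws$log_cs[i])
        if (isTRUE(spec$nuisance$enabled)) {
          cfg <- rotate_config(cfg, nuis$angle[cfg_i])
          cfg <- sweep(cfg, 2, -c(nuis$tx[cfg_i], nuis$ty[cfg_i]))
        }
        configs[[cfg_i]] <- cfg
        meta[[cfg_i]] <- tibble::tibble(
          id = sprintf("%s_i%d_d%d", specimen_ids[i], j, l),
          specimen_id = specimen_ids[i],
          population = pops[i], sex = sexes[i],
          image_id = sprintf("img%d", j),
          digitization_id = sprintf("dig%d", l),
          true_log_cs = spec_draws$log_cs[i]
        )
      }
    }
  }
  as_landmark_tbl(configs, dplyr::bind_rows(meta))
}

#' Serialize a synthetic spec to YAML
#'
#' @param spec A [synthetic_spec()].
#' @param path Output path (`.yaml`).
#' @return Invisibly, `path`.
#' @export
write_synthetic_spec <- function(spec, path) {
  stopifnot(inherits(spec, "synthetic_spec"))
  obj <- list(
    mean_shape = apply(spec$mean_shape, 1, function(r) as.numeric(r), simplify = FALSE),
    groups = as.list(spec$groups),
    population_effect = spec$population_effect,
    sex_effect = spec$sex_effect,
    interaction_effect = spec$interaction_effect,
    allometry = spec$allometry,
    log_cs = as.list(spec$log_cs),
    individual_noise_sd = spec$individual_noise_sd,
    image_noise_sd = spec$image_noise_sd,
    digitization_noise_sd = spec$digitization_noise_sd,
    n_images_per_specimen = spec$n_images_per_specimen,
    n_digitizations_per_image = spec$n_digitizations_per_image,
    nuisance = spec$nuisance,
    seed = spec$seed
  )
  yaml::write_yaml(obj, path, precision = 15L)
  invisible(path)
}

#' Read a synthetic spec from YAML
#'
#' @param path Path written by [write_synthetic_spec()].
#' @return A [synthetic_spec()].
#' @export
read_synthetic_spec <- function(path) {
  obj <- yaml::read_yaml(path)
  synthetic_spec(
    mean_shape = do.call(rbind, obj$mean_shape),
    groups = tibble::as_tibble(obj$groups),
    population_effect = unlist(obj$population_effect),
    sex_effect = unlist(obj$sex_effect),
    interaction_effect = unlist(obj$interaction_effect),
    allometry = lapply(obj$allometry, unlist),
    log_cs = tibble::as_tibble(obj$log_cs),
    individual_noise_sd = obj$individual_noise_sd,
    image_noise_sd = obj$image_noise_sd,
    digitization_noise_sd = obj$digitization_noise_sd,
    n_images_per_specimen = obj$n_images_per_specimen,
    n_digitizations_per_image = obj$n_digitizations_per_image,
    nuisance = obj$nuisance,
    project_effects = TRUE, # YAML round-trip can lose the last bits
    seed = obj$seed
  )
}
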