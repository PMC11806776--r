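#' Configure a full shape analysis
#'
#' Bundles the inputs and settings of [run_pipeline()]: either a
#' [synthetic_spec()] or a TPS file plus classifier CSV, the PC retention
#' threshold for MANOVA/MANCOVA, the permutation count, the RNG seed, the
#' replicate-averaging rule and an optional output directory for the report
#' CSVs.
#'
#' @param synthetic A [synthetic_spec()], or `NULL` when reading files.
#' @param tps_path,classifier_path Input files (used when `synthetic` is
#'   `NULL`).
#' @param retain PC retention threshold for MANOVA/MANCOVA responses
#'   (proportion of variance, default 0.90).
#' @param n_perm Permutations for all permutation tests (default 10000).
#' @param seed Master seed; each stochastic stage derives its own substream.
#' @param average_replicates Average replicate digitizations per specimen
#'   before between-group analyses (default TRUE).
#' @param out_dir Directory for report files, or `NULL` to skip writing.
#' @return Object of class `analysis_config`.
#' @export
analysis_config <- function(synthetic = NULL, tps_path = NULL,
                            classifier_path = NULL, retain = 0.90,
                            n_perm = 10000L, seed = 1L,
                            average_replicates = TRUE, out_dir = NULL) {
  if (is.null(synthetic) && is.null(tps_path)) {
    abort("Provide either a synthetic spec or a TPS file path.")
  }
  if (n_perm < 1L) abort("n_perm must be >= 1.")
  if (retain <= 0 || retain > 1) abort("retain must be in (0, 1].")
  structure(
    list(synthetic = synthetic, tps_path = tps_path,
         classifier_path = classifier_path, retain = retain,
         n_perm = as.integer(n_perm), seed = as.integer(seed),
         average_replicates = isTRUE(average_replicates), out_dir = out_dir),
    class = "analysis_config"
  )
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

#' Run the full shape-analysis pipeline
#'
#' Executes the standard sequence on replicated landmark data: load or
#' simulate -> GPA on all replicates -> outlier screen -> measurement-error
#' Procrustes ANOVA with Pillai cross-check -> per-specimen averaging ->
#' size ANOVA (log CS by population, and by sex within population) -> PCA
#' and MANOVA on retained PC scores (population; sex) -> DFA (population;
#' sex) and four-group CVA (population x sex) -> pooled-within-group
#' allometric regression -> common-slopes MANCOVA (sex x size per
#' population).  When the configuration names an output directory the
#' classification, pairwise-distance and MANCOVA tables plus score and
#' eigenvalue tables are written as CSV.
#'
#' @param config An [analysis_config()].
#' @return Object of class `analysis_report`: a named list of stage results
#'   plus `meta` (seed, config hash, package version, problem sizes).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  seed <- config$seed
  stage_seed <- function(i) tier_seed(seed, 100L + i)

  data <- run_stage("data", {
    if (!is.null(config$synthetic)) {
      generate_dataset(config$synthetic)
    } else {
      d <- read_tps(config$tps_path)
      if (!is.null(config$classifier_path)) {
        d <- attach_classifiers(d, config$classifier_path)
      }
      d
    }
  })

  fit <- run_stage("gpa", gpa(data))
  outliers <- run_stage("outliers", detect_outliers(fit))
  sv <- run_stage("shape_variables", shape_variables(fit))

  has_reps <- all(c("specimen_id", "image_id", "digitization_id") %in% names(sv)) &&
    anyDuplicated(sv$specimen_id) > 0
  error_anova <- NULL; pillai <- NULL
  if (has_reps) {
    error_anova <- run_stage("measurement_error", procrustes_anova(sv))
    pillai <- run_stage("pillai_check", pillai_check(sv, "digitization_id"))
  }

  spec_tbl <- if (has_reps && config$average_replicates) {
    run_stage("average_replicates", average_replicates(sv))
  } else sv

  size_population <- run_stage("size_anova",
                               anova_size(spec_tbl, "log_cs", "population"))
  size_sex <- run_stage("size_anova_sex", {
    purrr::map(split(spec_tbl, spec_tbl$population),
               ~ anova_size(.x, "log_cs", "sex"))
  })

  pca <- run_stage("pca", shape_pca(spec_tbl))
  n_90 <- n_components_for(pca, config$retain)
  manova_population <- run_stage("manova_population",
                                 manova_on_pcs(pca, "population", retain = config$retain))
  manova_sex <- run_stage("manova_sex",
                          manova_on_pcs(pca, "sex", retain = config$retain))

  dfa_population <- run_stage("dfa_population",
                              dfa(spec_tbl, "population", n_perm = config$n_perm,
                                  seed = stage_seed(1L)))
  dfa_sex <- run_stage("dfa_sex",
                       dfa(spec_tbl, "sex", n_perm = config$n_perm,
                           seed = stage_seed(2L)))
  spec_tbl$group <- paste(spec_tbl$population, spec_tbl$sex, sep = "_")
  cva_groups <- run_stage("cva",
                          cva(spec_tbl, "group", n_perm = config$n_perm,
                              seed = stage_seed(3L)))

  allometry <- run_stage("allometry",
                         regress_shape_on_size(spec_tbl, "log_cs", "population",
                                               n_perm = config$n_perm,
                                               seed = stage_seed(4L)))
  mancova_sex <- run_stage("mancova", {
    purrr::imap_dfr(split(spec_tbl, spec_tbl$population), function(d, pop) {
      tb <- tidy(mancova_trajectories(d, "log_cs", "sex", retain = config$retain))
      dplyr::bind_cols(tibble::tibble(population = pop), tb)
    })
  })

  # group mean shapes in the aligned frame, for wireframes/deformation grids
  mean_shapes <- run_stage("mean_shapes", {
    ms <- spec_tbl |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(dplyr::across(dplyr::all_of(coord_names(fit$k)), mean),
                       .groups = "drop")
    shapes <- lapply(seq_len(nrow(ms)), function(i) {
      fit$consensus + unflatten_config(as.numeric(ms[i, coord_names(fit$k)]))
    })
    names(shapes) <- ms$group
    shapes
  })

  cfg_for_hash <- config[setdiff(names(config), "out_dir")]
  report <- structure(
    list(
      data = data, gpa = fit, outliers = outliers,
      error_anova = error_anova, pillai = pillai,
      specimens = spec_tbl,
      size_population = size_population, size_sex = size_sex,
      pca = pca, n_components_90 = n_90,
      manova_population = manova_population, manova_sex = manova_sex,
      dfa_population = dfa_population, dfa_sex = dfa_sex,
      cva = cva_groups, allometry = allometry, mancova_sex = mancova_sex,
      mean_shapes = mean_shapes,
      meta = list(seed = seed, n_perm = config$n_perm, retain = config$retain,
                  config_hash = rlang::hash(cfg_for_hash),
                  package_version = as.character(utils::packageVersion("prosomorph")),
                  n_configurations = nrow(data),
                  n_specimens = nrow(spec_tbl), k = fit$k,
                  timestamp = format(Sys.time(), tz = "UTC"))
    ),
    class = "analysis_report"
  )
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  m <- x$meta
  cat(sprintf("Shape analysis report: %d configurations, %d specimens, k = %d (seed %d)\n",
              m$n_configurations, m$n_specimens, m$k, m$seed))
  cat(sprintf("PC1 %.1f%%, %d PCs reach %.0f%% of variance\n",
              x$pca$pct[1], x$n_components_90, 100 * m$retain))
  cat(sprintf("Population MANOVA: Wilks = %.3f, p = %.4g; sex MANOVA: Wilks = %.3f, p = %.4g\n",
              x$manova_population$wilks, x$manova_population$p,
              x$manova_sex$wilks, x$manova_sex$p))
  cat(sprintf("Allometry: %.2f%% of shape predicted by size (p = %.4g)\n",
              x$allometry$pct_predicted, x$allometry$p_perm))
  invisible(x)
}

#' Write the report tables of an analysis to CSV/JSON
#'
#' Emits the classification table (DFA), the pairwise CVA distance table,
#' the MANCOVA table, eigenvalues, PC/CV scores, aligned coordinates and a
#' JSON summary into a directory.
#'
#' @param report An [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, name) readr::write_csv(x, file.path(dir, name))
  w(report$dfa_population$jackknife, "classification_population.csv")
  w(report$dfa_sex$jackknife, "classification_sex.csv")
  w(report$cva$pairwise, "cva_pairwise_distances.csv")
  w(report$mancova_sex, "mancova_sex_by_size.csv")
  w(tidy(report$pca), "pca_eigenvalues.csv")
  w(report$pca$scores, "pca_scores.csv")
  w(report$cva$scores, "cva_scores.csv")
  w(report$gpa$aligned, "aligned_coordinates.csv")
  if (!is.null(report$error_anova)) {
    w(tidy(report$error_anova), "measurement_error_anova.csv")
  }
  summary_list <- list(
    meta = report$meta,
    manova_population = as.list(report$manova_population),
    manova_sex = as.list(report$manova_sex),
    dfa_population = as.list(glance(report$dfa_population)),
    dfa_sex = as.list(glance(report$dfa_sex)),
    allometry = as.list(glance(report$allometry))
  )
  jsonlite::write_json(summary_list, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
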