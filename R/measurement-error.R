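#' Hierarchical Procrustes ANOVA for measurement error
#'
#' Goodall-style nested analysis of variance of tangent-space shape
#' coordinates for a replicated digitization design: individuals, images
#' within individuals, digitizations within images.  Sums of squares pool
#' all coordinate dimensions (the isotropy assumption of Procrustes ANOVA);
#' degrees of freedom multiply the design df by the shape dimension
#' `2k - 4`.  Each level is tested against the level nested within it
#' (individual over image, image over digitization).
#'
#' Variance components per coordinate are estimated from the expected mean
#' squares of the balanced nested design:
#' digitization = `MS_dig`; image = `(MS_img - MS_dig) / r_dig`;
#' individual = `(MS_ind - MS_img) / (r_img * r_dig)`.
#'
#' @param data Tangent-space landmark table (from [shape_variables()]) with
#'   `specimen_id`, `image_id`, `digitization_id` columns covering all
#'   replicates.  The design must be balanced.
#' @return Object of class `procrustes_anova`; its `table` element is a
#'   tibble with `level`, `SS`, `df`, `MS`, `F`, `p`, `pct_total`,
#'   `variance_component`.
#' @export
procrustes_anova <- function(data) {
  need <- c("specimen_id", "image_id", "digitization_id")
  if (!all(need %in% names(data))) {
    abort("Replicate labels (specimen_id, image_id, digitization_id) are required.")
  }
  if (any(vapply(data[need], function(v) any(is.na(v)), TRUE))) {
    abort("Missing replicate labels.")
  }
  k <- landmark_count(data)
  Y <- coord_matrix(data)
  shape_dim <- 2L * k - 4L

  img_key <- paste(data$specimen_id, data$image_id, sep = "\r")
  n_img_per_spec <- tapply(data$image_id, data$specimen_id,
                           function(v) length(unique(v)))
  n_dig_per_img <- tapply(data$digitization_id, img_key,
                          function(v) length(unique(v)))
  if (length(unique(n_img_per_spec)) != 1L || length(unique(n_dig_per_img)) != 1L) {
    abort("Unbalanced replicate design: every specimen needs the same number of images, every image the same number of digitizations.")
  }
  r_img <- unname(n_img_per_spec[1])
  r_dig <- unname(n_dig_per_img[1])
  if (anyDuplicated(paste(img_key, data$digitization_id))) {
    abort("Duplicate (specimen, image, digitization) rows.")
  }
  n <- length(unique(data$specimen_id))

  grand <- colMeans(Y)
  m_img <- rowsum(Y, img_key) / r_dig
  spec_of_img <- sub("\r.*$", "", rownames(m_img))
  m_spec <- rowsum(m_img, spec_of_img) / r_img

  ss_ind <- r_img * r_dig * sum(sweep(m_spec, 2, grand)^2)
  ss_img <- r_dig * sum((m_img - m_spec[spec_of_img, , drop = FALSE])^2)
  ss_dig <- sum((Y - m_img[img_key, , drop = FALSE])^2)

  df_ind <- (n - 1L) * shape_dim
  df_img <- n * (r_img - 1L) * shape_dim
  df_dig <- n * r_img * (r_dig - 1L) * shape_dim

  ss <- c(individual = ss_ind, image = ss_img, digitization = ss_dig)
  df <- c(df_ind, df_img, df_dig)
  ms <- ifelse(df > 0, ss / df, NA_real_)
  fr <- c(ms[1] / ms[2], ms[2] / ms[3], NA_real_)
  pv <- c(
    if (df[1] > 0 && df[2] > 0) pf(fr[1], df[1], df[2], lower.tail = FALSE) else NA_real_,
    if (df[2] > 0 && df[3] > 0) pf(fr[2], df[2], df[3], lower.tail = FALSE) else NA_real_,
    NA_real_
  )
  vc <- c(
    individual = (ms[1] - ms[2]) / (r_img * r_dig),
    image = (ms[2] - ms[3]) / r_dig,
    digitization = ms[3]
  )
  tab <- tibble::tibble(
    level = names(ss), SS = unname(ss), df = df, MS = unname(ms),
    F = unname(fr), p = unname(pv),
    pct_total = 100 * unname(ss) / sum(ss),
    variance_component = unname(vc)
  )
  structure(
    list(table = tab, n_specimens = n, r_img = r_img, r_dig = r_dig,
         shape_dim = shape_dim, total_ss = sum(ss)),
    class = "procrustes_anova"
  )
}

#' @export
print.procrustes_anova <- function(x, ...) {
  cat(sprintf("Procrustes ANOVA: %d specimens x %d images x %d digitizations (shape dim %d)\n",
              x$n_specimens, x$r_img, x$r_dig, x$shape_dim))
  print(x$table)
  invisible(x)
}

#' @export
tidy.procrustes_anova <- function(x, ...) x$table

#' Pillai's trace MANOVA check on a replicate factor
#'
#' The non-isotropic companion to [procrustes_anova()]: a one-way MANOVA of
#' a replicate factor (e.g. digitization session) on shape scores.  Shape
#' variables are first reduced to their leading principal components --
#' enough to reach `retain` of the variance, capped at the residual degrees
#' of freedom minus one so the error covariance stays nonsingular (a warning
#' reports when the cap bites).
#'
#' @param data Tangent-space landmark table.
#' @param factor_col Name of the factor column (>= 2 levels).
#' @param retain Proportion of variance the retained PCs must reach
#'   (default 0.95).
#' @return Tibble with `pillai`, `F`, `df1`, `df2`, `p`, `m` (response
#'   dimension used).
#' @export
pillai_check <- function(data, factor_col, retain = 0.95) {
  f <- factor(data[[factor_col]])
  if (nlevels(f) < 2L) abort("Replicate factor needs at least 2 levels.")
  Y <- coord_matrix(data)
  n <- nrow(Y)
  g <- nlevels(f)
  pc <- prcomp_shape(Y)
  m_var <- smallest_m(pc$values, retain)
  cap <- n - g - 1L
  m <- min(m_var, cap, sum(pc$values > max(pc$values) * 1e-10))
  if (m < m_var) warn(sprintf("Response reduced from %d to %d PCs to keep the error covariance nonsingular.", m_var, m))
  if (m < 1L) abort("Not enough residual degrees of freedom for a MANOVA.")
  Z <- pc$scores[, seq_len(m), drop = FALSE]
  if (m == 1L) {
    a <- anova(lm(Z[, 1] ~ f))
    ssb <- a$`Sum Sq`[1]; ssw <- a$`Sum Sq`[2]
    return(tibble::tibble(pillai = ssb / (ssb + ssw), F = a$`F value`[1],
                          df1 = a$Df[1], df2 = a$Df[2], p = a$`Pr(>F)`[1], m = m))
  }
  fit <- manova(Z ~ f)
  s <- summary(fit, test = "Pillai")$stats
  tibble::tibble(pillai = s[1, "Pillai"], F = s[1, "approx F"],
                 df1 = s[1, "num Df"], df2 = s[1, "den Df"],
                 p = s[1, "Pr(>F)"], m = m)
}
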