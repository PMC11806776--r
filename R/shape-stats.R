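# covariance-matrix PCA of an n x p coordinate matrix (divisor n - 1),
# deterministic sign: the largest-magnitude loading of each PC is positive
prcomp_shape <- function(Y) {
  n <- nrow(Y)
  ctr <- colMeans(Y)
  Yc <- sweep(Y, 2, ctr)
  S <- crossprod(Yc) / (n - 1)
  e <- eigen(S, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  vecs <- e$vectors
  for (j in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  list(values = vals, vectors = vecs, scores = Yc %*% vecs, center = ctr)
}

smallest_m <- function(values, threshold) {
  pct <- cumsum(values) / sum(values)
  which(pct >= threshold - 1e-12)[1]
}

#' Principal component analysis of shape variables
#'
#' Eigendecomposition of the sample variance-covariance matrix (divisor
#' `n - 1`) of the tangent coordinates.  Loadings follow a deterministic
#' sign convention (largest-magnitude component positive).  For `k` 2-D
#' landmarks at most `2k - 4` eigenvalues are positive.
#'
#' @param data Tangent-space landmark table (from [shape_variables()]),
#'   usually averaged per specimen first.
#' @return Object of class `shape_pca` with `values` (all eigenvalues,
#'   descending), `pct` / `cum_pct`, `loadings` (`2k x m`), `scores`
#'   (tibble: metadata plus `PC1..PCm` for PCs with nonzero variance),
#'   `center`, and the source metadata.
#' @export
shape_pca <- function(data) {
  Y <- coord_matrix(data)
  if (nrow(Y) < 3L) abort("PCA needs at least 3 configurations.")
  pc <- prcomp_shape(Y)
  m <- max(1L, sum(pc$values > max(pc$values) * 1e-12))
  meta <- data[setdiff(names(data), coord_names(landmark_count(data)))]
  scores <- as.data.frame(pc$scores[, seq_len(m), drop = FALSE])
  names(scores) <- paste0("PC", seq_len(m))
  structure(
    list(values = pc$values, pct = 100 * pc$values / sum(pc$values),
         cum_pct = 100 * cumsum(pc$values) / sum(pc$values),
         loadings = pc$vectors[, seq_len(m), drop = FALSE],
         scores = dplyr::bind_cols(tibble::as_tibble(meta), scores),
         center = pc$center, n = nrow(Y), m = m),
    class = "shape_pca"
  )
}

#' @export
print.shape_pca <- function(x, ...) {
  cat(sprintf("Shape PCA: %d configurations, %d PCs with nonzero variance\n", x$n, x$m))
  cat(sprintf("PC1 %.2f%%, PC2 %.2f%% (cumulative %.2f%%)\n",
              x$pct[1], x$pct[2], x$cum_pct[2]))
  invisible(x)
}

#' @export
tidy.shape_pca <- function(x, ...) {
  tibble::tibble(PC = seq_along(x$values), eigenvalue = x$values,
                 pct = x$pct, cum_pct = x$cum_pct)
}

#' @export
glance.shape_pca <- function(x, ...) {
  tibble::tibble(n = x$n, m = x$m, total_variance = sum(x$values),
                 pc1_pct = x$pct[1], pc2_pct = x$pct[2])
}

#' Number of PCs needed to reach a variance threshold
#'
#' @param pca A [shape_pca()] result.
#' @param threshold Proportion of total variance in `(0, 1]` (e.g. 0.90).
#' @return Smallest number of leading PCs whose cumulative variance reaches
#'   the threshold (for `threshold = 1`, the number of positive eigenvalues).
#' @export
n_components_for <- function(pca, threshold) {
  stopifnot(inherits(pca, "shape_pca"))
  if (threshold <= 0 || threshold > 1) abort("threshold must be in (0, 1].")
  min(smallest_m(pca$values, threshold), x_positive(pca$values))
}

x_positive <- function(values) max(1L, sum(values > max(values) * 1e-12))

#' MANOVA of a factor on retained PC scores
#'
#' Wilks' lambda test of group mean differences on the leading `m` principal
#' component scores, with Rao's F approximation (exact for a 2-level
#' factor).  `m` defaults to the PCs reaching `retain` of the variance;
#' pass `retain = 1` to use the full nonzero-variance space.
#'
#' @param pca A [shape_pca()] result.
#' @param factor_col Name of the grouping column in the score table.
#' @param retain Variance proportion determining `m`, or use `m` directly.
#' @param m Number of leading PCs to use (overrides `retain`).
#' @return Tibble with `factor`, `m`, `wilks`, `F`, `df1`, `df2`, `p`.
#' @export
manova_on_pcs <- function(pca, factor_col, retain = 0.90, m = NULL) {
  stopifnot(inherits(pca, "shape_pca"))
  f <- factor(pca$scores[[factor_col]])
  g <- nlevels(f)
  if (g < 2L) abort("Factor needs at least 2 levels.")
  n <- pca$n
  if (is.null(m)) m <- n_components_for(pca, retain)
  cap <- n - g
  if (m >= cap) {
    warn(sprintf("Response reduced from %d to %d PCs (residual df).", m, cap - 1L))
    m <- cap - 1L
  }
  Z <- as.matrix(pca$scores[paste0("PC", seq_len(m))])
  wl <- wilks_test(Z, f)
  tibble::tibble(factor = factor_col, m = m, wilks = wl$lambda, F = wl$F,
                 df1 = wl$df1, df2 = wl$df2, p = wl$p)
}

# Wilks' lambda with Rao's F approximation (exact when min(p, g-1) <= 2)
wilks_test <- function(Z, f) {
  n <- nrow(Z); p <- ncol(Z); g <- nlevels(f)
  Zc <- sweep(Z, 2, colMeans(Z))
  Tm <- crossprod(Zc)
  gm <- rowsum(Z, f) / as.vector(table(f))
  W <- crossprod(Zc) * 0
  for (lev in levels(f)) {
    Zi <- Z[f == lev, , drop = FALSE]
    W <- W + crossprod(sweep(Zi, 2, colMeans(Zi)))
  }
  lambda <- det(W) / det(Tm)
  q <- g - 1
  t_df <- n - 1 - (p + g) / 2
  s <- if (p^2 + q^2 - 5 > 0) sqrt((p^2 * q^2 - 4) / (p^2 + q^2 - 5)) else 1
  df1 <- p * q
  df2 <- t_df * s - (p * q - 2) / 2
  L <- lambda^(1 / s)
  Fstat <- (1 - L) / L * df2 / df1
  list(lambda = lambda, F = Fstat, df1 = df1, df2 = df2,
       p = pf(Fstat, df1, df2, lower.tail = FALSE))
}

#' One-way ANOVA of a size (or other scalar) variable
#'
#' Standard one-way ANOVA plus the per-group mean and SD summary used for
#' size comparisons (log centroid size, prosoma length/width, ...).
#'
#' @param data Data frame.
#' @param value_col Name of the numeric column.
#' @param group_col Name of the grouping column.
#' @return Object of class `size_anova`: list with `test` (tibble: `F`,
#'   `df1`, `df2`, `p`) and `groups` (tibble: group, n, mean, sd).
#' @export
anova_size <- function(data, value_col, group_col) {
  v <- data[[value_col]]
  f <- factor(data[[group_col]])
  if (nlevels(f) < 2L) abort("Need at least 2 groups.")
  if (any(table(f) < 2L)) abort("Every group needs at least 2 observations.")
  a <- anova(lm(v ~ f))
  grp <- data |>
    dplyr::group_by(group = factor(.data[[group_col]])) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data[[value_col]]),
                     sd = sd(.data[[value_col]]), .groups = "drop")
  structure(
    list(test = tibble::tibble(F = a$`F value`[1], df1 = a$Df[1], df2 = a$Df[2],
                               p = a$`Pr(>F)`[1]),
         groups = grp, value = value_col, factor = group_col),
    class = "size_anova"
  )
}

#' @export
print.size_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA of %s by %s: F(%d, %d) = %.3f, p = %.4g\n",
              x$value, x$factor, x$test$df1, x$test$df2, x$test$F, x$test$p))
  print(x$groups)
  invisible(x)
}

#' @export
tidy.size_anova <- function(x, ...) x$groups

#' @export
glance.size_anova <- function(x, ...) x$test
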