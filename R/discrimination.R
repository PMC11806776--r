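# reduce tangent coordinates to a full-rank PC subspace before inverting
# within-group covariances (raw tangent coordinates are rank-deficient);
# cap keeps the pooled covariance nonsingular after grouping
reduce_rank <- function(Y, cap) {
  pc <- prcomp_shape(Y)
  r <- sum(pc$values > max(pc$values) * 1e-10)
  r <- min(r, cap)
  if (r < 1L) abort("No usable shape variation after rank reduction.")
  list(Z = pc$scores[, seq_len(r), drop = FALSE],
       V = pc$vectors[, seq_len(r), drop = FALSE], r = r)
}

# two-group Mahalanobis machinery on a full-rank score matrix
mahal_two_group <- function(Z, f) {
  lev <- levels(f)
  Z1 <- Z[f == lev[1], , drop = FALSE]
  Z2 <- Z[f == lev[2], , drop = FALSE]
  n1 <- nrow(Z1); n2 <- nrow(Z2)
  m1 <- colMeans(Z1); m2 <- colMeans(Z2)
  W <- (crossprod(sweep(Z1, 2, m1)) + crossprod(sweep(Z2, 2, m2))) / (n1 + n2 - 2)
  dvec <- m2 - m1
  a <- solve(W, dvec)
  list(D2 = sum(dvec * a), a = a, W = W, m1 = m1, m2 = m2, n1 = n1, n2 = n2)
}

# true x predicted classification table with row percentages
classification_table <- function(truth, predicted) {
  lev <- levels(truth)
  tab <- table(truth = truth, predicted = factor(predicted, levels = lev))
  out <- tibble::as_tibble(as.data.frame.matrix(tab), rownames = "group")
  out$total <- rowSums(tab)
  out
}

pct_correct <- function(truth, predicted) 100 * mean(as.character(truth) == as.character(predicted))

# nearest-Mahalanobis assignment given group means (rows) and pooled W;
# ties go to the first group in sorted label order
assign_nearest <- function(Z, means, W, lev) {
  Winv <- solve(W)
  d2 <- sapply(seq_len(nrow(means)), function(gi) {
    dd <- sweep(Z, 2, means[gi, ])
    rowSums((dd %*% Winv) * dd)
  })
  if (is.null(dim(d2))) d2 <- matrix(d2, nrow = 1)
  lev[apply(d2, 1, which.min)]
}

#' Two-group discriminant function analysis of shape
#'
#' Linear discriminant analysis of tangent-space shape variables between two
#' groups.  Shape variables are first projected onto their nonzero-variance
#' principal components (capped at `n - 3` so the pooled within-group
#' covariance `W` is invertible); the discriminant axis is `W^-1 (m2 - m1)`.
#' Reported alongside the Mahalanobis distance `D` are the Procrustes
#' (tangent-space Euclidean) distance between the group mean shapes,
#' Hotelling's T-squared with its parametric F test, and permutation
#' p-values for both distances obtained by reshuffling group labels
#' (specimens are the exchangeable units, so run this on per-specimen
#' averaged shapes).  Classification accuracy is reported both by
#' resubstitution and by jackknife (leave-one-out) cross-validation.
#'
#' @param data Tangent-space landmark table, one row per specimen.
#' @param group_col Name of the two-level grouping column.
#' @param n_perm Number of label permutations (p-values use the add-one
#'   estimator, so the smallest attainable p is `1/(n_perm + 1)`).
#' @param seed RNG seed for the permutations.
#' @return Object of class `shape_dfa`.
#' @export
dfa <- function(data, group_col, n_perm = 10000L, seed = 1L) {
  f <- droplevels(factor(data[[group_col]]))
  if (nlevels(f) != 2L) abort("DFA needs exactly 2 groups.")
  if (any(table(f) < 3L)) abort("Each group needs at least 3 specimens.")
  Y <- coord_matrix(data)
  n <- nrow(Y)
  red <- reduce_rank(Y, cap = n - 3L)
  Z <- red$Z
  lev <- levels(f)

  mh <- mahal_two_group(Z, f)
  D2 <- mh$D2
  p_dim <- red$r
  T2 <- (mh$n1 * mh$n2) / n * D2
  F_stat <- T2 * (n - p_dim - 1) / ((n - 2) * p_dim)
  p_param <- pf(F_stat, p_dim, n - p_dim - 1, lower.tail = FALSE)

  mu1 <- colMeans(Y[f == lev[1], , drop = FALSE])
  mu2 <- colMeans(Y[f == lev[2], , drop = FALSE])
  d_proc <- sqrt(sum((mu2 - mu1)^2))

  perm <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      fp <- sample(f)
      c(mahal_two_group(Z, fp)$D2,
        sqrt(sum((colMeans(Y[fp == lev[2], , drop = FALSE]) -
                    colMeans(Y[fp == lev[1], , drop = FALSE]))^2)))
    }, c(0, 0))
  })
  eps <- 1e-12
  p_perm_D <- (sum(perm[1, ] >= D2 - eps) + 1) / (n_perm + 1)
  p_perm_proc <- (sum(perm[2, ] >= d_proc - eps) + 1) / (n_perm + 1)

  axis <- as.numeric(red$V %*% mh$a)
  axis <- axis / sqrt(sum(axis^2))
  mid <- (mh$m1 + mh$m2) / 2
  disc_scores <- as.numeric(sweep(Z, 2, mid) %*% mh$a) / sqrt(D2)

  means <- rbind(mh$m1, mh$m2)
  resub_pred <- assign_nearest(Z, means, mh$W, lev)
  cls <- jackknife_classify(data, group_col)

  meta <- data[setdiff(names(data), coord_names(landmark_count(data)))]
  scores <- dplyr::bind_cols(tibble::as_tibble(meta),
                             tibble::tibble(score = disc_scores))

  structure(
    list(groups = lev, group_col = group_col, axis = axis, scores = scores,
         mahalanobis_d = sqrt(D2), procrustes_d = d_proc,
         T2 = T2, F = F_stat, df1 = p_dim, df2 = n - p_dim - 1,
         p_param = p_param,
         p_perm_mahalanobis = p_perm_D, p_perm_procrustes = p_perm_proc,
         n_perm = n_perm, seed = seed, rank = p_dim,
         resubstitution = classification_table(f, resub_pred),
         jackknife = cls$jackknife,
         pct_correct_resubstitution = pct_correct(f, resub_pred),
         pct_correct_jackknife = cls$pct_correct_jackknife),
    class = "shape_dfa"
  )
}

#' @export
print.shape_dfa <- function(x, ...) {
  cat(sprintf(
    paste0("Discriminant function analysis: %s vs %s\n",
           "Mahalanobis D = %.3f, Procrustes d = %.4f\n",
           "Hotelling's T2 = %.2f, F(%d, %d) = %.2f, parametric p = %.4g\n",
           "Permutation p (%d perms): D %.4g, Procrustes %.4g\n",
           "Correctly classified: %.1f%% (resubstitution), %.1f%% (jackknife)\n"),
    x$groups[1], x$groups[2], x$mahalanobis_d, x$procrustes_d,
    x$T2, x$df1, x$df2, x$F, x$p_param,
    x$n_perm, x$p_perm_mahalanobis, x$p_perm_procrustes,
    x$pct_correct_resubstitution, x$pct_correct_jackknife
  ))
  invisible(x)
}

#' @export
glance.shape_dfa <- function(x, ...) {
  tibble::tibble(
    group1 = x$groups[1], group2 = x$groups[2],
    mahalanobis_d = x$mahalanobis_d, procrustes_d = x$procrustes_d,
    T2 = x$T2, F = x$F, df1 = x$df1, df2 = x$df2, p_param = x$p_param,
    p_perm_mahalanobis = x$p_perm_mahalanobis,
    p_perm_procrustes = x$p_perm_procrustes,
    pct_correct_resubstitution = x$pct_correct_resubstitution,
    pct_correct_jackknife = x$pct_correct_jackknife
  )
}

#' @export
tidy.shape_dfa <- function(x, ...) x$scores

#' Jackknife (leave-one-out) cross-validated classification
#'
#' For each specimen, the group means and pooled within-group covariance are
#' recomputed with that specimen held out, and the specimen is assigned to
#' the nearest group mean by Mahalanobis distance.  Works for two or more
#' groups; ties break toward the first group in sorted label order.
#'
#' @param data Tangent-space landmark table, one row per specimen.
#' @param group_col Name of the grouping column.
#' @return List with `resubstitution` and `jackknife` classification tables
#'   (true group x predicted counts) and percent-correct rates for both.
#' @export
jackknife_classify <- function(data, group_col) {
  f <- droplevels(factor(data[[group_col]]))
  g <- nlevels(f)
  if (g < 2L) abort("Need at least 2 groups.")
  if (any(table(f) < 3L)) abort("Each group needs at least 3 specimens (leaving one out must not empty a group).")
  Y <- coord_matrix(data)
  n <- nrow(Y)
  red <- reduce_rank(Y, cap = n - g - 2L)
  Z <- red$Z
  lev <- levels(f)

  counts <- as.vector(table(f))
  means <- rowsum(Z, f) / counts
  S <- matrix(0, ncol(Z), ncol(Z))
  for (gi in seq_len(g)) {
    S <- S + crossprod(sweep(Z[f == lev[gi], , drop = FALSE], 2, means[gi, ]))
  }
  W <- S / (n - g)
  resub_pred <- assign_nearest(Z, means, W, lev)

  jack_pred <- character(n)
  for (i in seq_len(n)) {
    gi <- match(as.character(f[i]), lev)
    ni <- counts[gi]
    d <- Z[i, ] - means[gi, ]
    means_i <- means
    means_i[gi, ] <- (means[gi, ] * ni - Z[i, ]) / (ni - 1)
    # SSCP downdate for removing one observation from its group
    S_i <- S - (ni / (ni - 1)) * tcrossprod(d)
    W_i <- S_i / (n - 1 - g)
    jack_pred[i] <- assign_nearest(Z[i, , drop = FALSE], means_i, W_i, lev)
  }
  list(
    resubstitution = classification_table(f, resub_pred),
    jackknife = classification_table(f, jack_pred),
    pct_correct_resubstitution = pct_correct(f, resub_pred),
    pct_correct_jackknife = pct_correct(f, jack_pred)
  )
}

#' Canonical variate analysis of shape
#'
#' Multi-group ordination maximizing between-group relative to within-group
#' shape variation.  On the reduced full-rank subspace the canonical axes
#' solve the generalized eigenproblem of the between-group covariance
#' against the pooled within-group covariance; axes are scaled so the
#' pooled within-group variance along each axis is 1.  There are
#' `min(groups - 1, shape dimension)` axes; each axis' share of the
#' between-group variation is its eigenvalue share.  Every pair of groups
#' also gets the two-group analysis of [dfa()] (Procrustes and Mahalanobis
#' distances, Hotelling's T-squared, permutation p-values).
#'
#' @param data Tangent-space landmark table, one row per specimen.
#' @param group_col Grouping column (>= 2 levels, each with >= 3 specimens).
#' @param n_perm,seed Passed to the pairwise permutation tests.
#' @return Object of class `shape_cva` with `values`, `pct`, `axes`
#'   (`2k x m` vectors in tangent space), `scores` (tibble with `CV1..CVm`),
#'   and `pairwise` (tibble of pairwise distances and tests).
#' @export
cva <- function(data, group_col, n_perm = 10000L, seed = 1L) {
  f <- droplevels(factor(data[[group_col]]))
  g <- nlevels(f)
  if (g < 2L) abort("CVA needs at least 2 groups.")
  if (any(table(f) < 3L)) abort("Each group needs at least 3 specimens.")
  Y <- coord_matrix(data)
  n <- nrow(Y)
  red <- reduce_rank(Y, cap = n - g - 1L)
  Z <- red$Z
  lev <- levels(f)

  counts <- as.vector(table(f))
  means <- rowsum(Z, f) / counts
  grand <- colMeans(Z)
  S_w <- matrix(0, ncol(Z), ncol(Z))
  for (gi in seq_len(g)) {
    S_w <- S_w + crossprod(sweep(Z[f == lev[gi], , drop = FALSE], 2, means[gi, ]))
  }
  W <- S_w / (n - g)
  B <- crossprod(sweep(means, 2, grand) * sqrt(counts)) / (g - 1)

  # whiten by W, then symmetric eigenproblem
  L <- chol(W)
  M <- backsolve(L, t(backsolve(L, t(B), transpose = TRUE)), transpose = TRUE)
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  m_axes <- min(g - 1L, ncol(Z))
  vals <- pmax(e$values[seq_len(m_axes)], 0)
  U <- e$vectors[, seq_len(m_axes), drop = FALSE]
  A <- backsolve(L, U) # a' W a = 1
  for (j in seq_len(m_axes)) {
    i <- which.max(abs(A[, j]))
    if (A[i, j] < 0) A[, j] <- -A[, j]
  }
  cv_scores <- sweep(Z, 2, grand) %*% A
  axes_full <- red$V %*% A

  meta <- data[setdiff(names(data), coord_names(landmark_count(data)))]
  scores <- dplyr::bind_cols(
    tibble::as_tibble(meta),
    tibble::as_tibble(as.data.frame(cv_scores) |>
                        setNames(paste0("CV", seq_len(m_axes))))
  )

  pairs <- utils::combn(lev, 2, simplify = FALSE)
  pairwise <- purrr::map_dfr(pairs, function(pr) {
    sub <- data[f %in% pr, , drop = FALSE]
    d <- dfa(sub, group_col, n_perm = n_perm, seed = seed)
    tibble::tibble(
      group1 = pr[1], group2 = pr[2],
      procrustes_d = d$procrustes_d, mahalanobis_d = d$mahalanobis_d,
      T2 = d$T2,
      p_perm_mahalanobis = d$p_perm_mahalanobis,
      p_perm_procrustes = d$p_perm_procrustes
    )
  })

  structure(
    list(values = vals, pct = 100 * vals / sum(vals), axes = axes_full,
         scores = scores, pairwise = pairwise, groups = lev,
         n_perm = n_perm, seed = seed, rank = red$r),
    class = "shape_cva"
  )
}

#' @export
print.shape_cva <- function(x, ...) {
  cat(sprintf("Canonical variate analysis: %d groups, %d axes\n",
              length(x$groups), length(x$values)))
  cat(sprintf("CV%d: %.1f%%\n", seq_along(x$pct), x$pct))
  cat("\nPairwise tests:\n")
  print(x$pairwise)
  invisible(x)
}

#' @export
tidy.shape_cva <- function(x, ...) x$scores

#' @export
glance.shape_cva <- function(x, ...) {
  tibble::tibble(n_groups = length(x$groups), n_axes = length(x$values),
                 cv1_pct = x$pct[1],
                 cv2_pct = if (length(x$pct) > 1) x$pct[2] else NA_real_)
}
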