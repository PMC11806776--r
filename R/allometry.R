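#' Multivariate regression of shape on log centroid size
#'
#' Least-squares regression of every tangent coordinate on log centroid
#' size.  With `pooled_within = TRUE` (the default when groups are given)
#' shapes and sizes are centered within groups first, so the slope is the
#' common within-group (static) allometry and between-group mean differences
#' do not masquerade as allometry.  The summary statistic is the percent of
#' total shape variation predicted by size, `100 * SS_predicted / SS_total`
#' with sums of squares pooled over all shape dimensions; its significance
#' comes from a permutation test that reshuffles the size values against the
#' shapes (within groups when pooled) and uses the add-one estimator.
#'
#' @param data Tangent-space landmark table, one row per specimen, carrying
#'   a log centroid size column.
#' @param size_col Name of the log centroid size column (default `log_cs`).
#' @param group_col Optional grouping column for pooled-within-group
#'   regression.
#' @param pooled_within Center within groups first (requires `group_col`).
#' @param n_perm,seed Permutation count and RNG seed.
#' @return Object of class `shape_allometry` with `beta` (`2k` shape change
#'   per unit log CS), `intercept`, `pct_predicted`, `p_perm`, plus the
#'   fitted and residual shape tables.
#' @export
regress_shape_on_size <- function(data, size_col = "log_cs", group_col = NULL,
                                  pooled_within = !is.null(group_col),
                                  n_perm = 10000L, seed = 1L) {
  Y <- coord_matrix(data)
  n <- nrow(Y)
  if (n < 4L) abort("Need at least 4 specimens.")
  x <- data[[size_col]]
  if (is.null(x)) abort(sprintf("Column '%s' not found.", size_col))
  if (any(!is.finite(x)) || var(x) == 0) abort("Size must be finite with nonzero variance.")
  if (pooled_within && is.null(group_col)) abort("pooled_within = TRUE needs group_col.")

  if (pooled_within) {
    f <- factor(data[[group_col]])
    xc <- x - stats::ave(x, f)
    Yc <- Y - rowsum(Y, f)[f, , drop = FALSE] / as.vector(table(f))[f]
  } else {
    f <- NULL
    xc <- x - mean(x)
    Yc <- sweep(Y, 2, colMeans(Y))
  }

  sxx <- sum(xc^2)
  beta <- as.numeric(crossprod(Yc, xc)) / sxx
  pred <- outer(xc, beta)
  ss_tot <- sum(Yc^2)
  ss_pred <- sum(pred^2)
  pct <- 100 * ss_pred / ss_tot

  perm_pct <- withr::with_seed(seed, vapply(seq_len(n_perm), function(b) {
    xp <- if (is.null(f)) sample(xc) else {
      out <- xc
      for (lev in levels(f)) {
        idx <- which(f == lev)
        out[idx] <- xc[sample(idx)]
      }
      out
    }
    bp <- as.numeric(crossprod(Yc, xp)) / sum(xp^2)
    100 * sum(xp^2) * sum(bp^2) / ss_tot
  }, 0))
  p_perm <- (sum(perm_pct >= pct - 1e-12) + 1) / (n_perm + 1)

  intercept <- colMeans(Y) - beta * mean(x)
  fitted <- set_coords(data, (Y - Yc) + pred)
  residuals <- set_coords(data, Yc - pred)

  structure(
    list(beta = beta, intercept = intercept, pct_predicted = pct,
         p_perm = p_perm, n_perm = n_perm, seed = seed,
         pooled_within = pooled_within, group_col = group_col,
         size_col = size_col, n = n, fitted = fitted, residuals = residuals),
    class = "shape_allometry"
  )
}

#' @export
print.shape_allometry <- function(x, ...) {
  cat(sprintf(
    "Shape-on-size regression (%s): size predicts %.2f%% of shape variation\npermutation p = %.4g (%d permutations)\n",
    if (x$pooled_within) paste0("pooled within ", x$group_col) else "total",
    x$pct_predicted, x$p_perm, x$n_perm
  ))
  invisible(x)
}

#' @export
glance.shape_allometry <- function(x, ...) {
  tibble::tibble(pct_predicted = x$pct_predicted, p_perm = x$p_perm,
                 n = x$n, n_perm = x$n_perm,
                 pooled_within = x$pooled_within,
                 beta_norm = sqrt(sum(x$beta^2)))
}

#' MANCOVA comparison of allometric trajectories
#'
#' Tests whether groups share a common allometric slope.  Shape variables
#' are reduced to principal components (to `retain` of the variance by
#' default, or the full nonzero-variance space with `retain = 1`), then the
#' multivariate linear model `scores ~ group * log CS` is fitted and the
#' group-by-size interaction tested by Wilks' lambda (sequential sums of
#' squares).  A second model without the interaction -- parallel slopes --
#' tests the group effect with size controlled.
#'
#' @param data Tangent-space landmark table, one row per specimen.
#' @param size_col Log centroid size column.
#' @param group_col Grouping column (>= 2 levels).
#' @param retain Variance proportion for the PC reduction (default 0.90).
#' @return Object of class `shape_mancova`; its `table` has one row per
#'   tested effect (`group:size` interaction from the full model; `group`
#'   and `size` from the parallel-slopes model) with Wilks' lambda, F, df
#'   and p.
#' @export
mancova_trajectories <- function(data, size_col = "log_cs", group_col,
                                 retain = 0.90) {
  f <- droplevels(factor(data[[group_col]]))
  g <- nlevels(f)
  if (g < 2L) abort("MANCOVA needs at least 2 groups.")
  x <- data[[size_col]]
  if (any(!is.finite(x)) || var(x) == 0) abort("Size must be finite with nonzero variance.")
  Y <- coord_matrix(data)
  n <- nrow(Y)
  pc <- prcomp_shape(Y)
  m <- smallest_m(pc$values, retain)
  m <- min(m, sum(pc$values > max(pc$values) * 1e-10))
  cap <- n - 2L * g - 1L # residual df of the interaction model
  if (m > cap) {
    warn(sprintf("Response reduced from %d to %d PCs (residual df).", m, cap))
    m <- cap
  }
  if (m < 1L) abort("Not enough specimens for the requested response dimension.")
  Z <- pc$scores[, seq_len(m), drop = FALSE]

  fit_full <- manova(Z ~ f * x)
  s_full <- summary(fit_full, test = "Wilks")$stats
  fit_par <- manova(Z ~ x + f)
  s_par <- summary(fit_par, test = "Wilks")$stats

  row_of <- function(s, term, label) {
    tibble::tibble(effect = label, wilks = s[term, "Wilks"],
                   F = s[term, "approx F"], df1 = s[term, "num Df"],
                   df2 = s[term, "den Df"], p = s[term, "Pr(>F)"])
  }
  tab <- dplyr::bind_rows(
    row_of(s_full, "f:x", paste0(group_col, " x ", size_col)),
    row_of(s_par, "f", group_col),
    row_of(s_par, "x", size_col)
  )
  structure(
    list(table = tab, m = m, n = n, group_col = group_col,
         size_col = size_col, retain = retain),
    class = "shape_mancova"
  )
}

#' @export
print.shape_mancova <- function(x, ...) {
  cat(sprintf("MANCOVA of shape on %s by %s (%d PCs, n = %d)\n",
              x$size_col, x$group_col, x$m, x$n))
  print(x$table)
  invisible(x)
}

#' @export
tidy.shape_mancova <- function(x, ...) x$table
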