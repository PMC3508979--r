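# Statistics module: the evaluation metric (MAPE) and the multivariate
# population-comparison statistics.

#' Mean absolute percentage error
#'
#' `100 * mean(|est - true| / |true|)`, the parameter-recovery metric.
#'
#' @param true_vals,est_vals Equal-length numeric vectors; `true_vals`
#'   must be nonzero.
#' @return MAPE in percent.
#' @export
mape <- function(true_vals, est_vals) {
  stopifnot(length(true_vals) == length(est_vals),
            length(true_vals) > 0)
  if (any(true_vals == 0)) stop("true values must be nonzero")
  100 * mean(abs(est_vals - true_vals) / abs(true_vals))
}

# per-element absolute percentage errors (for spread reporting)
ape <- function(true_vals, est_vals) {
  100 * abs(est_vals - true_vals) / abs(true_vals)
}

#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean.
#'
#' @param vals Numeric vector with nonzero mean.
#' @return Scalar CV.
#' @export
coefficient_of_variation <- function(vals) {
  m <- mean(vals)
  if (m == 0) stop("mean is zero")
  sd(vals) / m
}

#' Total polymerized tubulin
#'
#' The product of the number of microtubules and the mean length: the
#' expected total filament length in the cell.
#'
#' @param n_hat Estimated number of microtubules.
#' @param mu_hat Estimated mean length (micrometres).
#' @return `n_hat * mu_hat`.
#' @export
polymerized_tubulin <- function(n_hat, mu_hat) {
  stopifnot(all(n_hat >= 0), all(mu_hat >= 0))
  n_hat * mu_hat
}

#' Two-sample Hotelling's T-squared test
#'
#' Tests equality of multivariate means of two groups using the pooled
#' covariance; the p-value comes from the F transformation
#' `F = (na + nb - p - 1) / (p (na + nb - 2)) * T2` with
#' `(p, na + nb - p - 1)` degrees of freedom.
#'
#' @param group_a,group_b Numeric matrices (rows = observations,
#'   columns = variables), at least 3 rows each.
#' @return List with `T2`, `p`, `df` and the group sizes.
#' @export
hotelling_t2 <- function(group_a, group_b) {
  a <- as.matrix(group_a); b <- as.matrix(group_b)
  stopifnot(ncol(a) == ncol(b), nrow(a) >= 3, nrow(b) >= 3)
  p <- ncol(a); na <- nrow(a); nb <- nrow(b)
  dm <- colMeans(a) - colMeans(b)
  sp <- ((na - 1) * cov(a) + (nb - 1) * cov(b)) / (na + nb - 2)
  si <- tryCatch(solve(sp), error = function(e)
    stop("singular pooled covariance"))
  t2 <- as.numeric(na * nb / (na + nb) * t(dm) %*% si %*% dm)
  fstat <- (na + nb - p - 1) / (p * (na + nb - 2)) * t2
  pval <- pf(fstat, p, na + nb - p - 1, lower.tail = FALSE)
  list(T2 = t2, p = pval, df = c(p, na + nb - p - 1),
       n = c(na, nb))
}

#' Box's M test of covariance homogeneity
#'
#' `M = (N - k) log|S_pooled| - sum_i (n_i - 1) log|S_i|` with the
#' standard chi-square approximation
#' `X2 = M (1 - c)` on `p (p + 1) (k - 1) / 2` degrees of freedom.
#'
#' @param groups List of numeric matrices with a common column count,
#'   each with at least 3 rows.
#' @return List with `M`, `chi_sq`, `df` and `p`.
#' @export
box_m_test <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  groups <- lapply(groups, as.matrix)
  p <- ncol(groups[[1]])
  stopifnot(all(vapply(groups, ncol, 0L) == p),
            all(vapply(groups, nrow, 0L) >= 3))
  k <- length(groups)
  ns <- vapply(groups, nrow, 0L)
  N <- sum(ns)
  covs <- lapply(groups, cov)
  lds <- vapply(covs, function(s) {
    d <- determinant(s, logarithm = TRUE)
    if (d$sign <= 0) stop("singular group covariance")
    as.numeric(d$modulus)
  }, 0.0)
  sp <- Reduce(`+`, Map(function(s, n) (n - 1) * s, covs, ns)) / (N - k)
  dp <- determinant(sp, logarithm = TRUE)
  if (dp$sign <= 0) stop("singular pooled covariance")
  M <- (N - k) * as.numeric(dp$modulus) - sum((ns - 1) * lds)
  cc <- (sum(1 / (ns - 1)) - 1 / (N - k)) *
    (2 * p^2 + 3 * p - 1) / (6 * (p + 1) * (k - 1))
  chi <- M * (1 - cc)
  df <- p * (p + 1) * (k - 1) / 2
  list(M = M, chi_sq = chi, df = df,
       p = pchisq(chi, df, lower.tail = FALSE))
}

#' Subsampled pairwise Hotelling's T-squared comparisons
#'
#' For every unordered pair of groups, draws `repeats` seeded
#' subsamples of `subsample_n` rows per group (without replacement),
#' runs Hotelling's T-squared on each, takes the minimum p-value over
#' the repeats, multiplies it by `repeats` (Bonferroni over repeats)
#' and then by the number of pairs (family-wise Bonferroni), clipping
#' at 1.  Subsampling equalizes unbalanced group sizes.  The reported
#' T2 is that of the repeat attaining the minimum p.
#'
#' @param table Data frame with a `group` column and the measurement
#'   columns.
#' @param columns Character vector (typically length 2) of measurement
#'   column names.
#' @param subsample_n Rows per group per repeat (default 35).
#' @param repeats Number of subsample repeats (default 100).
#' @param seed Master seed; per-(pair, repeat) seeds are derived
#'   deterministically from it, so the result for a pair does not
#'   depend on pair order.
#' @return Data frame with one row per pair: `group_a`, `group_b`,
#'   `T2`, `p_adjusted`, `n_subsample`, `n_repeats`.
#' @export
pairwise_compare <- function(table, columns, subsample_n = 35L,
                             repeats = 100L, seed = 1L) {
  stopifnot(is.data.frame(table), "group" %in% names(table),
            all(columns %in% names(table)))
  groups <- sort(unique(as.character(table$group)))
  sizes <- table(as.character(table$group))
  small <- names(sizes)[sizes < subsample_n]
  if (length(small))
    stop("group(s) smaller than subsample_n: ",
         paste(small, collapse = ", "))
  pairs <- utils::combn(groups, 2L)
  n_pairs <- ncol(pairs)
  out <- vector("list", n_pairs)
  for (j in seq_len(n_pairs)) {
    ga <- as.matrix(table[table$group == pairs[1, j], columns])
    gb <- as.matrix(table[table$group == pairs[2, j], columns])
    # deterministic row order, so results do not depend on input order
    ga <- ga[do.call(order, as.data.frame(ga)), , drop = FALSE]
    gb <- gb[do.call(order, as.data.frame(gb)), , drop = FALSE]
    best_p <- Inf; best_t2 <- NA_real_
    for (r in seq_len(repeats)) {
      set.seed(seed + 7919L * j + r)
      ia <- sample.int(nrow(ga), subsample_n)
      ib <- sample.int(nrow(gb), subsample_n)
      h <- hotelling_t2(ga[ia, , drop = FALSE], gb[ib, , drop = FALSE])
      if (h$p < best_p) { best_p <- h$p; best_t2 <- h$T2 }
    }
    out[[j]] <- data.frame(group_a = pairs[1, j], group_b = pairs[2, j],
                           T2 = best_t2,
                           p_adjusted = min(1, best_p * repeats * n_pairs),
                           n_subsample = subsample_n,
                           n_repeats = repeats)
  }
  do.call(rbind, out)
}

#' Hierarchical clustering tree from a T-squared dissimilarity matrix
#'
#' Agglomerative clustering (average linkage by default) on the
#' symmetric matrix of pairwise Hotelling's T-squared statistics, used
#' directly as dissimilarities.
#'
#' @param t2_matrix Symmetric nonnegative matrix with zero diagonal
#'   and group names as dimnames.
#' @param method `hclust` linkage method (default "average").
#' @return List with the `hclust` object (`tree`) and a Newick string
#'   (`newick`).
#' @export
cluster_tree <- function(t2_matrix, method = "average") {
  m <- as.matrix(t2_matrix)
  if (!isSymmetric(unname(m), tol = 1e-8)) stop("matrix must be symmetric")
  if (any(diag(m) != 0)) stop("diagonal must be zero")
  if (any(m < 0)) stop("dissimilarities must be nonnegative")
  hc <- hclust(as.dist(m), method = method)
  list(tree = hc,
       newick = ape::write.tree(ape::as.phylo(hc)))
}

#' First two principal components
#'
#' Mean-centered (unscaled) PCA; returns the per-row scores on the
#' first two components and their variance fractions.  Sign
#' convention: each component's largest-magnitude loading is positive,
#' so runs are reproducible.
#'
#' @param features Numeric matrix (rows = observations), at least 3
#'   rows and 2 columns, rank >= 2.
#' @return List with `scores` (n x 2) and `variance_fractions`
#'   (length 2).
#' @export
pca_first_two <- function(features) {
  x <- as.matrix(features)
  stopifnot(nrow(x) >= 3, ncol(x) >= 2)
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  if (length(pc$sdev) < 2 || pc$sdev[2] < 1e-12 * pc$sdev[1])
    stop("feature matrix has rank < 2")
  flip <- vapply(1:2, function(j) {
    l <- pc$rotation[, j]
    sign(l[which.max(abs(l))])
  }, 0.0)
  scores <- sweep(pc$x[, 1:2, drop = FALSE], 2L, flip, "*")
  list(scores = scores,
       variance_fractions = pc$sdev[1:2]^2 / sum(pc$sdev^2))
}

#' Pearson correlation
#'
#' @param x,y Equal-length numeric vectors (length >= 3) with nonzero
#'   variance.
#' @return Pearson correlation coefficient.
#' @export
correlate <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance")
  cor(x, y)
}
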