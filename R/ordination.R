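#' Principal component analysis of a dosage matrix
#'
#' Columns (loci) are mean-centered but not variance-scaled; axes are ordered
#' by decreasing variance and each axis's variance fraction is its variance
#' divided by the total variance of the centered matrix.
#'
#' @param dosage a `dosage_matrix` or plain individuals x loci matrix.
#' @param n_axes number of axes to return (truncated with a warning if it
#'   exceeds what the data support).
#' @param loadings return locus loadings as well?
#' @return An `ordination_result` with `scores`, `axis_variance_fraction`,
#'   optional `loadings`, and `method = "PCA"`.
#' @export
run_pca <- function(dosage, n_axes = 2, loadings = FALSE) {
  x <- if (inherits(dosage, "dosage_matrix")) dosage$dosage else as.matrix(dosage)
  n <- nrow(x)
  max_axes <- min(n - 1, ncol(x))
  if (n_axes > max_axes) {
    warning(sprintf("n_axes reduced from %d to %d", n_axes, max_axes))
    n_axes <- max_axes
  }
  xc <- scale(x, center = TRUE, scale = FALSE)
  sv <- svd(xc, nu = n_axes, nv = if (loadings) n_axes else 0)
  total_var <- sum(xc^2)
  scores <- sv$u * rep(sv$d[seq_len(n_axes)], each = n)
  rownames(scores) <- rownames(x)
  colnames(scores) <- paste0("PC", seq_len(n_axes))
  varfrac <- if (total_var > 0) sv$d[seq_len(n_axes)]^2 / total_var else rep(0, n_axes)
  structure(
    list(
      scores = scores,
      axis_variance_fraction = varfrac,
      loadings = if (loadings) sv$v else NULL,
      method = "PCA"
    ),
    class = "ordination_result"
  )
}

#' @export
print.ordination_result <- function(x, ...) {
  cat(sprintf(
    "%s ordination: %d individuals, %d axes (variance fractions: %s)\n",
    x$method, nrow(x$scores), ncol(x$scores),
    paste(sprintf("%.3f", x$axis_variance_fraction), collapse = ", ")
  ))
  invisible(x)
}

# center a 2-column configuration and scale to unit sum of squares
procrustes_prepare <- function(m, name) {
  m <- as.matrix(m)
  mc <- scale(m, center = TRUE, scale = FALSE)
  ss <- sum(mc^2)
  if (ss < 1e-300) stop(sprintf("configuration `%s` has zero variance", name))
  mc / sqrt(ss)
}

#' Symmetric Procrustes correlation between two configurations
#'
#' Both configurations are centered and scaled to unit sum of squares; the
#' optimal rotation (reflection allowed) comes from the SVD of the
#' cross-product, giving residual m^2 = 1 - (sum of singular values)^2 and
#' correlation t = sqrt(1 - m^2). Symmetric in its arguments.
#'
#' @param genetic_config,geo_config matrices with the same individuals in the
#'   same row order (typically two genetic PCs vs. longitude/latitude).
#' @return The Procrustes correlation t in `[0, 1]`.
#' @export
procrustes_correlation <- function(genetic_config, geo_config) {
  x <- procrustes_prepare(genetic_config, "genetic_config")
  y <- procrustes_prepare(geo_config, "geo_config")
  if (nrow(x) != nrow(y)) stop("configurations must have the same rows")
  d <- svd(crossprod(x, y), nu = 0, nv = 0)$d
  min(sum(d), 1)
}

#' Permutation test for the Procrustes correlation
#'
#' Rows of one configuration are permuted in each replicate; significance is
#' the upper-tail add-one p-value on t.
#'
#' @inheritParams procrustes_correlation
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @return A [perm_test_result()].
#' @export
procrustes_permutation_test <- function(genetic_config, geo_config,
                                        n_perm = 999, seed = 1L) {
  x <- procrustes_prepare(genetic_config, "genetic_config")
  y <- procrustes_prepare(geo_config, "geo_config")
  if (nrow(x) != nrow(y)) stop("configurations must have the same rows")
  observed <- min(sum(svd(crossprod(x, y), nu = 0, nv = 0)$d), 1)
  n <- nrow(x)
  null_t <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
    xp <- x[sample.int(n), , drop = FALSE]
    # re-center after permutation is a no-op (row permutation preserves
    # column means), so the cross-product can be used directly
    min(sum(svd(crossprod(xp, y), nu = 0, nv = 0)$d), 1)
  }, numeric(1)))
  perm_test_result(observed, null_t, tail = "upper")
}

#' Pair-sharing genetic distance permutation test
#'
#' Tests whether individuals sharing a group (lek or lek complex) are closer
#' in ordination space than expected: the statistic is the mean Euclidean
#' distance over all individual pairs that share a group, and the null is
#' built by permutation. Elevated within-group relatedness shows up as a
#' small observed mean, so the p-value is lower-tailed.
#'
#' Two permutation nulls are available. `"labels"` (default) permutes group
#' labels across individuals and recomputes the sharing pattern — a standard
#' exchangeable null with exact type-I control (group sizes, and hence the
#' number of sharing pairs, are preserved automatically). `"pairs"` shuffles
#' the sharing indicator directly among all pairs with the count of sharing
#' pairs held fixed; it ignores the dependence between pairs that share an
#' individual and is mildly conservative, but is retained as the literal
#' pair-level randomization.
#'
#' @param scores individuals x 2 ordination scores.
#' @param groups group label per individual.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @param null `"labels"` (permute individuals' group labels) or `"pairs"`
#'   (shuffle the pair-sharing indicator).
#' @return A [perm_test_result()] (lower tail).
#' @export
pair_sharing_distance_test <- function(scores, groups, n_perm = 1000, seed = 1L,
                                       null = c("labels", "pairs")) {
  null <- match.arg(null)
  scores <- as.matrix(scores)
  if (nrow(scores) != length(groups)) stop("one group label per row of scores required")
  n <- nrow(scores)
  d <- as.numeric(dist(scores))
  gid <- as.numeric(factor(groups))
  share <- as.numeric(dist(gid)) == 0
  m <- sum(share)
  if (m == 0) stop("no pair of individuals shares a group")
  if (m == length(d)) stop("all pairs share a group; the null is degenerate")
  observed <- mean(d[share])
  null_m <- with_seed(seed, {
    if (null == "pairs") {
      vapply(seq_len(n_perm), function(b) {
        mean(d[sample.int(length(d), m)])
      }, numeric(1))
    } else {
      vapply(seq_len(n_perm), function(b) {
        mean(d[as.numeric(dist(gid[sample.int(n)])) == 0])
      }, numeric(1))
    }
  })
  perm_test_result(observed, null_m, tail = "lower")
}

# within-group sum of squares over all axes, via group sums (exact ANOVA
# partition; for Euclidean distances identical to the distance-matrix form)
ss_within <- function(x, groups, group_sizes) {
  gs <- rowsum(x, groups) # reordered to factor-level order, matching sizes
  sum(x^2) - sum(gs^2 / group_sizes)
}

#' PERMANOVA on ordination scores
#'
#' Permutational multivariate analysis of variance based on Euclidean
#' distances of the supplied score matrix (typically the first two ordination
#' axes). The sums of squares are computed through the exact ANOVA partition
#' of the scores, which for Euclidean distances coincides with the
#' distance-matrix partition SS_total = (1/n) sum_{i<j} d_ij^2. Pseudo-F =
#' (SS_between/(k-1)) / (SS_within/(n-k)); R^2 = SS_between/SS_total; the
#' p-value permutes individual labels.
#'
#' @param scores individuals x axes matrix.
#' @param groups group label per individual (>= 2 non-empty groups).
#' @param n_perm permutations (default 999).
#' @param seed integer seed.
#' @return List with `R2`, `pseudo_F`, `df`, and `test` (a [perm_test_result()]
#'   on pseudo-F, upper tail).
#' @export
permanova <- function(scores, groups, n_perm = 999, seed = 1L) {
  x <- as.matrix(scores)
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups")
  if (any(table(groups) == 0)) stop("empty group")
  n <- nrow(x)
  k <- nlevels(groups)
  xc <- scale(x, center = TRUE, scale = FALSE)
  sst <- sum(xc^2)
  sizes <- as.numeric(table(groups)) # factor-level order, matching ss_within
  f_stat <- function(g_idx) {
    ssw <- ss_within(xc, g_idx, sizes)
    ssb <- sst - ssw
    (ssb / (k - 1)) / (ssw / (n - k))
  }
  observed_f <- f_stat(groups)
  ssw_obs <- ss_within(xc, groups, sizes)
  null_f <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
    f_stat(groups[sample.int(n)])
  }, numeric(1)))
  list(
    R2 = (sst - ssw_obs) / sst,
    pseudo_F = observed_f,
    df = c(between = k - 1, within = n - k),
    test = perm_test_result(observed_f, null_f, tail = "upper")
  )
}
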