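# per-population per-locus summaries (allele frequency p, heterozygote
# frequency h) from a dosage_matrix (expected fractional genotype counts) or
# from hard-called genotypes (dosages rounded to 0/1/2)
pop_locus_summaries <- function(x, rows, mode) {
  if (inherits(x, "dosage_matrix")) {
    d <- x$dosage[rows, , drop = FALSE]
    if (mode == "hard") {
      g <- round(d)
      list(p = colMeans(g) / 2, h = colMeans(g == 1), n = length(rows))
    } else {
      het <- x$genotype_probs[rows, , 2, drop = FALSE]
      list(p = colMeans(d) / 2, h = colMeans(het), n = length(rows))
    }
  } else {
    g <- as.matrix(x)[rows, , drop = FALSE]
    list(p = colMeans(g) / 2, h = colMeans(g == 1), n = length(rows))
  }
}

# Weir-Cockerham (1984) two-population diploid variance components,
# vectorized across loci. Returns a (among populations), b (among
# individuals within populations), c (within individuals).
wc_components <- function(p1, h1, n1, p2, h2, n2) {
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  list(a = a, b = b, c = cc)
}

#' Pairwise Weir-Cockerham F_ST between two populations
#'
#' Computes the Weir-Cockerham (1984) theta estimator in its two-population
#' diploid form. By default genotype uncertainty enters through fractional
#' expected genotype counts: each population's allele frequency is the mean
#' dosage / 2 and its heterozygote frequency the mean posterior heterozygote
#' probability. `mode = "hard"` rounds dosages to hard genotype calls first.
#' The multi-locus estimate is the ratio of sums sum(a) / sum(a + b + c)
#' over loci with a nonzero denominator; per-locus theta is a / (a + b + c)
#' (NA where undefined).
#'
#' @param x a `dosage_matrix` or individuals x loci genotype matrix (0/1/2).
#' @param pop_labels population label per individual.
#' @param pair length-2 vector naming the two populations to compare.
#' @param mode `"probs"` (fractional expected counts, default) or `"hard"`.
#' @return List: `theta` (multi-locus), `theta_locus`, and the per-locus
#'   variance components `a`, `b`, `c`.
#' @export
weir_cockerham_fst <- function(x, pop_labels, pair, mode = c("probs", "hard")) {
  mode <- match.arg(mode)
  rows1 <- which(pop_labels == pair[1])
  rows2 <- which(pop_labels == pair[2])
  if (length(rows1) < 2 || length(rows2) < 2) {
    stop("both populations need at least two individuals")
  }
  s1 <- pop_locus_summaries(x, rows1, mode)
  s2 <- pop_locus_summaries(x, rows2, mode)
  comp <- wc_components(s1$p, s1$h, s1$n, s2$p, s2$h, s2$n)
  denom <- comp$a + comp$b + comp$c
  ok <- abs(denom) > 1e-300
  if (!any(ok)) {
    stop(sprintf(
      "populations %s and %s are monomorphic at every locus; theta undefined",
      pair[1], pair[2]
    ))
  }
  list(
    theta = sum(comp$a[ok]) / sum(denom[ok]),
    theta_locus = ifelse(ok, comp$a / denom, NA_real_),
    a = comp$a, b = comp$b, c = comp$c
  )
}

#' Permutation significance for pairwise F_ST
#'
#' Individuals from the two populations are pooled and randomly repartitioned
#' at the original sample sizes in each replicate; the upper-tail add-one
#' p-value is reported on the multi-locus theta.
#'
#' @inheritParams weir_cockerham_fst
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @return A [perm_test_result()].
#' @export
fst_permutation_test <- function(x, pop_labels, pair, n_perm = 999, seed = 1L,
                                 mode = c("probs", "hard")) {
  mode <- match.arg(mode)
  rows <- which(pop_labels %in% pair)
  n1 <- sum(pop_labels == pair[1])
  sub_labels <- pop_labels[rows]
  theta_of <- function(labels) {
    weir_cockerham_fst_rows(x, rows, labels, pair, mode)
  }
  observed <- theta_of(sub_labels)
  null_theta <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
    perm <- sample(sub_labels)
    theta_of(perm)
  }, numeric(1)))
  perm_test_result(observed, null_theta, tail = "upper")
}

# multi-locus theta where `labels` indexes within the pooled `rows` subset
weir_cockerham_fst_rows <- function(x, rows, labels, pair, mode) {
  s1 <- pop_locus_summaries(x, rows[labels == pair[1]], mode)
  s2 <- pop_locus_summaries(x, rows[labels == pair[2]], mode)
  comp <- wc_components(s1$p, s1$h, s1$n, s2$p, s2$h, s2$n)
  denom <- comp$a + comp$b + comp$c
  ok <- abs(denom) > 1e-300
  sum(comp$a[ok]) / sum(denom[ok])
}

#' All pairwise F_ST as a labeled matrix
#'
#' @inheritParams weir_cockerham_fst
#' @param levels optional population ordering (default: order of appearance).
#' @return A [pairwise_matrix()] of kind `"fst"`.
#' @export
fst_matrix <- function(x, pop_labels, levels = unique(pop_labels),
                       mode = c("probs", "hard")) {
  mode <- match.arg(mode)
  k <- length(levels)
  m <- matrix(0, k, k)
  for (i in seq_len(k - 1)) {
    for (j in seq.int(i + 1, k)) {
      m[i, j] <- m[j, i] <-
        weir_cockerham_fst(x, pop_labels, c(levels[i], levels[j]), mode)$theta
    }
  }
  pairwise_matrix(m, levels, "fst")
}

#' Per-locus pairwise theta table
#'
#' Per-locus Weir-Cockerham theta for every population pair, as needed for
#' F_ST-quantile outlier trimming.
#'
#' @inheritParams fst_matrix
#' @return A loci x pairs matrix of per-locus theta (NA where undefined);
#'   pair names as `"A|B"` column names.
#' @export
locus_fst_table <- function(x, pop_labels, levels = unique(pop_labels),
                            mode = c("probs", "hard")) {
  mode <- match.arg(mode)
  pairs <- utils::combn(levels, 2)
  out <- apply(pairs, 2, function(pr) {
    weir_cockerham_fst(x, pop_labels, pr, mode)$theta_locus
  })
  colnames(out) <- apply(pairs, 2, paste, collapse = "|")
  out
}

#' Trim high-F_ST outlier loci
#'
#' For each population pair, the threshold is the given quantile of that
#' pair's per-locus theta distribution; a locus is removed if it exceeds the
#' threshold in any pair. Returns the retained locus indices.
#'
#' @param locus_fst loci x pairs matrix from [locus_fst_table()].
#' @param quantile_cut quantile in `[0, 1]` (e.g. 0.98).
#' @return Integer vector of retained locus indices.
#' @export
outlier_trim <- function(locus_fst, quantile_cut) {
  locus_fst <- as.matrix(locus_fst)
  quantile_cut <- check_prob(quantile_cut, "quantile_cut")
  removed <- rep(FALSE, nrow(locus_fst))
  if (quantile_cut < 1) {
    for (jp in seq_len(ncol(locus_fst))) {
      v <- locus_fst[, jp]
      thr <- quantile(v, quantile_cut, na.rm = TRUE, names = FALSE)
      removed <- removed | (!is.na(v) & v > thr)
    }
  }
  which(!removed)
}

#' Nei's (1972) standard genetic distance between two populations
#'
#' For biallelic loci with alternate-allele frequencies `x` and `y`,
#' J_X = mean(x^2 + (1-x)^2), J_Y likewise, J_XY = mean(x y + (1-x)(1-y)),
#' normalized identity I = J_XY / sqrt(J_X J_Y), and D = -ln(I).
#'
#' @param x,y numeric vectors of alternate-allele frequencies (one per locus).
#' @return Nei's D (nonnegative, symmetric).
#' @export
nei_distance <- function(x, y) {
  if (length(x) != length(y)) stop("frequency vectors differ in length")
  jx <- mean(x^2 + (1 - x)^2)
  jy <- mean(y^2 + (1 - y)^2)
  jxy <- mean(x * y + (1 - x) * (1 - y))
  i <- jxy / sqrt(jx * jy)
  if (i <= 0) stop("genetic identity is zero; Nei's D is infinite")
  -log(i)
}

#' All pairwise Nei's D as a labeled matrix
#'
#' Population allele frequencies are mean dosage / 2 within each population.
#'
#' @inheritParams fst_matrix
#' @return A [pairwise_matrix()] of kind `"nei_d"`.
#' @export
nei_matrix <- function(x, pop_labels, levels = unique(pop_labels)) {
  d <- if (inherits(x, "dosage_matrix")) x$dosage else as.matrix(x)
  freqs <- lapply(levels, function(l) colMeans(d[pop_labels == l, , drop = FALSE]) / 2)
  k <- length(levels)
  m <- matrix(0, k, k)
  for (i in seq_len(k - 1)) {
    for (j in seq.int(i + 1, k)) {
      m[i, j] <- m[j, i] <- nei_distance(freqs[[i]], freqs[[j]])
    }
  }
  pairwise_matrix(m, levels, "nei_d")
}

#' Neighbor-joining tree from a pairwise distance matrix
#'
#' Saitou-Nei agglomeration (via ape); negative branch lengths are reported
#' as computed, not clamped. The unrooted tree is returned both as a `phylo`
#' object and as a newick string.
#'
#' @param x a [pairwise_matrix()] (or plain symmetric matrix with dimnames).
#' @return List: `tree` (ape `phylo`), `newick` (character).
#' @export
neighbor_joining <- function(x) {
  v <- if (inherits(x, "pairwise_matrix")) x$values else as.matrix(x)
  if (nrow(v) < 3) stop("neighbor-joining needs at least 3 taxa")
  tree <- ape::nj(stats::as.dist(v))
  list(tree = tree, newick = ape::write.tree(tree))
}
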