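# Independent brute-force oracles used to cross-check the implementation.

# Weir-Cockerham theta via the definitional nested ANOVA of allele indicators
# (alleles within individuals within populations), estimated by method of
# moments from the observed mean squares. Works on hard genotypes (0/1/2).
bf_theta_anova <- function(geno, pops) {
  pops <- as.character(pops)
  levs <- unique(pops)
  r <- length(levs)
  per_locus <- function(g) {
    # explode genotypes into allele indicators
    y <- list()
    pop_of <- list()
    ind_of <- list()
    for (i in seq_along(g)) {
      a1 <- as.numeric(g[i] >= 1)
      a2 <- as.numeric(g[i] == 2)
      y[[i]] <- c(a1, a2)
      pop_of[[i]] <- rep(pops[i], 2)
      ind_of[[i]] <- rep(i, 2)
    }
    y <- unlist(y)
    pop_of <- unlist(pop_of)
    ind_of <- unlist(ind_of)
    n_i <- table(factor(pops, levels = levs))
    ybar <- mean(y)
    ssp <- 0
    ssi <- 0
    ssg <- 0
    for (l in levs) {
      sel <- pop_of == l
      ssp <- ssp + sum(sel) * (mean(y[sel]) - ybar)^2
      for (ind in unique(ind_of[sel])) {
        si <- ind_of == ind
        ssi <- ssi + 2 * (mean(y[si]) - mean(y[sel]))^2
        ssg <- ssg + sum((y[si] - mean(y[si]))^2)
      }
    }
    ntot <- sum(n_i)
    msp <- ssp / (r - 1)
    msi <- ssi / (ntot - r)
    msg <- ssg / ntot
    nbar <- mean(n_i)
    nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
    sig_g <- msg
    sig_i <- (msi - msg) / 2
    sig_p <- (msp - msi) / (2 * nc)
    c(a = sig_p, tot = sig_p + sig_i + sig_g)
  }
  comps <- apply(geno, 2, per_locus)
  ok <- abs(comps["tot", ]) > 1e-300
  sum(comps["a", ok]) / sum(comps["tot", ok])
}

# PERMANOVA sums of squares computed literally from the pairwise distance
# matrix: SS_total = (1/n) sum_{i<j} d_ij^2, SS_within from per-group blocks.
bf_permanova_dist <- function(scores, groups) {
  d <- as.matrix(dist(scores))
  n <- nrow(d)
  groups <- as.character(groups)
  sst <- sum(d[lower.tri(d)]^2) / n
  ssw <- 0
  for (g in unique(groups)) {
    sel <- which(groups == g)
    dg <- d[sel, sel]
    ssw <- ssw + sum(dg[lower.tri(dg)]^2) / length(sel)
  }
  k <- length(unique(groups))
  ssb <- sst - ssw
  list(R2 = ssb / sst, F = (ssb / (k - 1)) / (ssw / (n - k)))
}

# Bellman-Ford shortest paths from one source cell over the same grid-graph
# cost convention (8 neighbors, mean-of-cells edge weight, sqrt(2) diagonal),
# built here with naive nested loops.
bf_least_cost <- function(raster, src_cell) {
  v <- raster$values
  nr <- nrow(v)
  nc <- ncol(v)
  cs <- raster$cell_size
  edges <- list()
  for (row in seq_len(nr)) {
    for (col in seq_len(nc)) {
      for (dr in -1:1) {
        for (dc in -1:1) {
          if (dr == 0 && dc == 0) next
          r2 <- row + dr
          c2 <- col + dc
          if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
          w <- (v[row, col] + v[r2, c2]) / 2 * cs *
            if (dr != 0 && dc != 0) sqrt(2) else 1
          edges[[length(edges) + 1]] <-
            c(row + (col - 1) * nr, r2 + (c2 - 1) * nr, w)
        }
      }
    }
  }
  em <- do.call(rbind, edges)
  dist <- rep(Inf, nr * nc)
  dist[src_cell] <- 0
  repeat {
    relaxed <- dist[em[, 1]] + em[, 3]
    newd <- pmin(dist, tapply(relaxed, em[, 2], min)[as.character(seq_len(nr * nc))])
    newd[is.na(newd)] <- dist[is.na(newd)]
    if (max(abs(newd - dist), na.rm = TRUE) < 1e-15) break
    dist <- newd
  }
  dist
}

# all pairwise leaf-to-leaf path lengths of a phylo tree
tree_path_lengths <- function(tree) {
  d <- ape::cophenetic.phylo(tree)
  d[tree$tip.label, tree$tip.label]
}
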