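test_that("two-population theta matches the nested-ANOVA oracle on toys", {
  set.seed(23)
  for (rep in 1:4) {
    geno <- matrix(sample(0:2, 20 * 5, replace = TRUE), 20, 5)
    pops <- rep(c("p1", "p2"), each = 10)
    # guard against an all-monomorphic draw
    if (all(apply(geno, 2, function(g) length(unique(g)) == 1))) next
    ours <- weir_cockerham_fst(geno, pops, c("p1", "p2"), mode = "hard")
    expect_equal(ours$theta, bf_theta_anova(geno, pops), tolerance = 1e-10)
  }
  # unequal sample sizes
  geno <- matrix(sample(0:2, 25 * 5, replace = TRUE), 25, 5)
  pops <- c(rep("p1", 10), rep("p2", 15))
  ours <- weir_cockerham_fst(geno, pops, c("p1", "p2"), mode = "hard")
  expect_equal(ours$theta, bf_theta_anova(geno, pops), tolerance = 1e-10)
})

test_that("theta hits its analytic extremes", {
  # fixed difference: per-locus theta = 1
  geno <- rbind(matrix(0, 10, 4), matrix(2, 10, 4))
  pops <- rep(c("a", "b"), each = 10)
  res <- weir_cockerham_fst(geno, pops, c("a", "b"), mode = "hard")
  expect_equal(unname(res$theta_locus), rep(1, 4), tolerance = 1e-12)
  expect_equal(res$theta, 1, tolerance = 1e-12)
  # two independent samples from one panmictic pool: theta ~ 0
  # (note: duplicating one sample into both populations would instead give
  # the estimator's small negative bias -1/(2n-1), since identical samples
  # are less variable than independent ones)
  set.seed(24)
  pool <- matrix(rbinom(60 * 2000, 2, 0.3), 60, 2000)
  res0 <- weir_cockerham_fst(pool, rep(c("a", "b"), each = 30), c("a", "b"),
    mode = "hard"
  )
  expect_lt(abs(res0$theta), 0.01)
  # all-monomorphic pair errors
  expect_error(
    weir_cockerham_fst(matrix(0, 10, 3), rep(c("a", "b"), each = 5), c("a", "b")),
    "monomorphic"
  )
  expect_error(
    weir_cockerham_fst(matrix(0:2, 3, 4), c("a", "a", "b"), c("a", "b")),
    "two individuals"
  )
})

test_that("fractional-count and hard-call modes agree when probabilities are crisp", {
  set.seed(25)
  geno <- matrix(rbinom(40 * 50, 2, 0.4), 40, 50)
  dm <- as_dosage_matrix(geno)
  pops <- rep(c("a", "b"), each = 20)
  soft <- weir_cockerham_fst(dm, pops, c("a", "b"), mode = "probs")
  hard <- weir_cockerham_fst(dm, pops, c("a", "b"), mode = "hard")
  expect_equal(soft$theta, hard$theta, tolerance = 1e-12)
})

test_that("F_ST permutation test is significant under structure, calibrated-ish under none", {
  truth <- simulate_hierarchical_frequencies(sim_config(
    n_complexes = 1, leks_per_complex = 2, individuals_per_lek = 30,
    n_loci = 2000, f_complex = 0, f_lek = 0.05, ibd_strength = 0, seed = 61
  ))
  md <- truth$metadata
  res <- fst_permutation_test(truth$genotypes, md$lek, unique(md$lek),
    n_perm = 199, seed = 3, mode = "hard"
  )
  expect_equal(res$p_value, 1 / 200)
  # panmictic: arbitrary split should not be significant
  null_truth <- simulate_hierarchical_frequencies(sim_config(
    n_complexes = 1, leks_per_complex = 2, individuals_per_lek = 30,
    n_loci = 500, f_complex = 0, f_lek = 0, ibd_strength = 0, seed = 62
  ))
  res0 <- fst_permutation_test(null_truth$genotypes, null_truth$metadata$lek,
    unique(null_truth$metadata$lek),
    n_perm = 199, seed = 4, mode = "hard"
  )
  expect_gt(res0$p_value, 0.01)
})

test_that("Nei's D matches hand computation and is symmetric", {
  expect_equal(nei_distance(c(0.2, 0.7), c(0.2, 0.7)), 0)
  # single locus, pop X fixed for reference, pop Y at 0.5
  expect_equal(nei_distance(0, 0.5), -log(0.5 / sqrt(0.5)), tolerance = 1e-12)
  expect_equal(nei_distance(0, 0.5), 0.34657, tolerance = 1e-4)
  set.seed(26)
  x <- runif(20)
  y <- runif(20)
  expect_equal(nei_distance(x, y), nei_distance(y, x))
  expect_error(nei_distance(c(0, 1), c(1, 0)), "infinite")
})

test_that("neighbor joining reproduces closed forms and additive matrices", {
  # 3 taxa: branch lengths from the closed form
  d <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  d["A", "B"] <- d["B", "A"] <- 5
  d["A", "C"] <- d["C", "A"] <- 9
  d["B", "C"] <- d["C", "B"] <- 10
  nj <- neighbor_joining(pairwise_matrix(d, rownames(d), "nei_d"))
  pl <- tree_path_lengths(nj$tree)
  expect_equal(pl["A", "B"], 5, tolerance = 1e-10)
  expect_equal(pl["A", "C"], 9, tolerance = 1e-10)
  expect_equal(pl["B", "C"], 10, tolerance = 1e-10)
  # v_A = (d_AB + d_AC - d_BC)/2 = 2
  edge_a <- nj$tree$edge.length[nj$tree$edge[, 2] == which(nj$tree$tip.label == "A")]
  expect_equal(edge_a, 2, tolerance = 1e-10)

  # 4-taxon additive matrix: path lengths reproduce the input exactly
  tree_txt <- "((A:1,B:2):0.5,C:3,D:4);"
  ref_tree <- ape::read.tree(text = tree_txt)
  dm <- tree_path_lengths(ref_tree)
  nj4 <- neighbor_joining(dm)
  expect_equal(tree_path_lengths(nj4$tree)[rownames(dm), colnames(dm)], dm,
    tolerance = 1e-10
  )
  # label invariance: permuting taxa preserves the recovered distances
  perm <- c("C", "A", "D", "B")
  nj_perm <- neighbor_joining(dm[perm, perm])
  expect_equal(tree_path_lengths(nj_perm$tree)[rownames(dm), colnames(dm)], dm,
    tolerance = 1e-10
  )
  expect_match(nj4$newick, "^\\(.*\\);$")
  expect_error(neighbor_joining(d[1:2, 1:2]), "at least 3")
})

test_that("D and theta rank leks consistently on hierarchical simulations", {
  cors <- vapply(1:5, function(s) {
    truth <- small_hier_truth(500 + s, n_loci = 600)
    md <- truth$metadata
    fst <- fst_matrix(truth$genotypes, md$lek, mode = "hard")
    nei <- nei_matrix(truth$genotypes, md$lek)
    cor(lower_triangle(fst), lower_triangle(nei), method = "spearman")
  }, numeric(1))
  expect_gt(median(cors), 0.9)
})

test_that("outlier trimming removes exactly the upper tail, per pair, monotonically", {
  set.seed(27)
  lf <- matrix(rbeta(100 * 1, 1, 20), 100, 1)
  keep <- outlier_trim(lf, 0.98)
  thr <- quantile(lf[, 1], 0.98)
  expect_setequal(keep, which(lf[, 1] <= thr))
  expect_equal(length(keep), 98)
  # quantile 1 keeps everything
  expect_equal(outlier_trim(lf, 1), 1:100)
  # more pairs only shrink the retained set
  lf2 <- cbind(lf, rbeta(100, 1, 20))
  expect_true(all(outlier_trim(lf2, 0.98) %in% keep))
})
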