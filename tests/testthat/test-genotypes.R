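test_that("binomial genotype likelihoods match direct evaluation", {
  # no reads: flat triple
  expect_equal(genotype_likelihoods_from_counts(0, 0, 0.3), c(1, 1, 1))
  # 2 reference reads at e = 0.01: proportional to (0.9801, 0.25, 1e-4)
  trip <- genotype_likelihoods_from_counts(2, 0, 0.01)
  expect_equal(trip / trip[1], c(0.9801, 0.25, 0.0001) / 0.9801, tolerance = 1e-12)
  # balanced reads: heterozygote maximal
  trip <- genotype_likelihoods_from_counts(5, 5, 0.01)
  expect_equal(which.max(trip), 2L)
  # error-free limit
  trip0 <- genotype_likelihoods_from_counts(3, 0, 0)
  expect_equal(trip0, c(1, 0.125, 0))
})

test_that("presence filter applies the 90% threshold with boundary kept", {
  n <- 140
  L <- 3
  ref <- matrix(1, n, L)
  ref[127:140, 2] <- 0 # 126/140 = 0.9 exactly -> retained
  ref[126:140, 3] <- 0 # 125/140 < 0.9 -> removed
  tab <- gl_from_counts(ref, matrix(0, n, L))
  kept <- filter_presence(tab, 0.9)
  expect_equal(kept$locus_id, tab$locus_id[1:2])
  expect_equal(n_loci(filter_presence(tab, 0)), 3)
  all_missing <- gl_from_counts(matrix(0, 4, 2), matrix(0, 4, 2))
  expect_warning(filter_presence(all_missing, 0.5), "no loci")
})

test_that("biallelic filter drops multiallelic records only", {
  ref <- matrix(2, 4, 5)
  tab <- gl_from_counts(ref, ref)
  tab$n_alt_alleles <- c(1L, 2L, 1L, 3L, 1L)
  kept <- filter_biallelic(tab)
  expect_equal(n_loci(kept), 3)
  expect_equal(kept$locus_id, tab$locus_id[c(1, 3, 5)])
  expect_equal(n_loci(filter_biallelic(kept)), 3) # idempotent on biallelic input
})

test_that("MAF filter keeps the 5% boundary and drops below it", {
  # deep coverage makes the counts-based frequency essentially exact
  n <- 100
  make_col <- function(n_alt_carriers) {
    g <- c(rep(1, n_alt_carriers), rep(0, n - n_alt_carriers))
    list(ref = 30 - 15 * g, alt = 15 * g)
  }
  cols <- lapply(c(6, 10, 100), make_col) # q = 0.03, 0.05, 0.5
  ref <- do.call(cbind, lapply(cols, `[[`, "ref"))
  alt <- do.call(cbind, lapply(cols, `[[`, "alt"))
  tab <- gl_from_counts(ref, alt, 0.001)
  kept <- filter_maf(tab, 0.05)
  expect_equal(kept$locus_id, tab$locus_id[2:3])
})

test_that("per-contig thinning keeps exactly one SNP per contig, reproducibly", {
  ref <- matrix(2, 5, 30)
  tab <- gl_from_counts(ref, ref, contig = rep(sprintf("c%02d", 1:10), each = 3))
  t1 <- thin_one_snp_per_contig(tab, seed = 7)
  t2 <- thin_one_snp_per_contig(tab, seed = 7)
  expect_equal(n_loci(t1), 10)
  expect_equal(sort(unique(t1$contig_id)), sprintf("c%02d", 1:10))
  expect_identical(t1$locus_id, t2$locus_id)
  # singleton contigs are always kept
  solo <- gl_from_counts(ref[, 1:3], ref[, 1:3], contig = c("a", "b", "c"))
  expect_equal(thin_one_snp_per_contig(solo, 1)$locus_id, solo$locus_id)
})

test_that("dosage estimates obey their structural identities", {
  cfg <- sim_config(
    n_complexes = 2, leks_per_complex = 2, individuals_per_lek = 8,
    n_loci = 60, seed = 31
  )
  truth <- simulate_hierarchical_frequencies(cfg)
  tab <- simulate_reads(truth, cfg)
  dm <- estimate_dosages(tab, mcmc_settings(n_steps = 2000, burn_in = 500, seed = 2))
  expect_true(all(dm$dosage >= 0 & dm$dosage <= 2))
  psum <- dm$genotype_probs[, , 1] + dm$genotype_probs[, , 2] + dm$genotype_probs[, , 3]
  expect_lt(max(abs(psum - 1)), 1e-9)
  expect_lt(max(abs(
    dm$dosage - (dm$genotype_probs[, , 2] + 2 * dm$genotype_probs[, , 3])
  )), 1e-9)
  expect_true(all(dm$allele_freq_posterior_mean >= 0 &
    dm$allele_freq_posterior_mean <= 1))
})

test_that("no-read individuals get the prior-mean dosage 2*qbar", {
  # one individual with zero reads at a locus where others pin q near 0.5
  n <- 40
  ref <- matrix(0, n, 1)
  alt <- matrix(0, n, 1)
  ref[2:n] <- 25
  alt[2:n] <- 25 # strong heterozygote signal, q ~ 0.5
  ref[seq(2, n, by = 2)] <- 50
  alt[seq(2, n, by = 2)] <- 0 # half hom-ref
  alt[seq(3, n, by = 2)] <- 50
  ref[seq(3, n, by = 2)] <- 0 # half hom-alt
  tab <- gl_from_counts(ref, alt)
  dm <- estimate_dosages(tab, mcmc_settings(seed = 4))
  qbar <- dm$allele_freq_posterior_mean[1]
  expect_equal(dm$dosage[1, 1], 2 * qbar, tolerance = 0.05)
})

test_that("deep coverage recovers genotypes nearly exactly", {
  cfg <- sim_config(
    n_complexes = 1, leks_per_complex = 2, individuals_per_lek = 10,
    n_loci = 40, mean_coverage = 60, coverage_sd = 1, seed = 77
  )
  truth <- simulate_hierarchical_frequencies(cfg)
  tab <- simulate_reads(truth, cfg)
  dm <- estimate_dosages(tab, mcmc_settings(n_steps = 2000, burn_in = 500, seed = 3))
  covered <- tab$depth >= 50
  expect_lt(max(abs(dm$dosage[covered] - truth$genotypes[covered])), 0.01)
})

test_that("independent chains agree on the posterior allele frequency", {
  cfg <- sim_config(
    n_complexes = 5, leks_per_complex = 2, individuals_per_lek = 14,
    n_loci = 120, seed = 55
  )
  truth <- simulate_hierarchical_frequencies(cfg)
  tab <- simulate_reads(truth, cfg)
  d1 <- estimate_dosages(tab, mcmc_settings(seed = 101))
  d2 <- estimate_dosages(tab, mcmc_settings(seed = 202))
  expect_lt(
    max(abs(d1$allele_freq_posterior_mean - d2$allele_freq_posterior_mean)),
    0.02
  )
})

test_that("mcmc settings reject a burn-in at least as long as the run", {
  expect_error(mcmc_settings(n_steps = 1000, burn_in = 1000), "burn_in")
})
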