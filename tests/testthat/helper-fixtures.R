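# Small in-code fixtures shared across tests.

# gl_table built directly from read-count matrices
gl_from_counts <- function(ref, alt, error_rate = 0.01, contig = NULL) {
  ref <- as.matrix(ref)
  alt <- as.matrix(alt)
  lik <- genotype_likelihoods_from_counts(ref, alt, error_rate)
  gl_table(
    likelihoods = lik,
    has_read = (ref + alt) > 0,
    contig_id = contig %||% sprintf("ctg_%03d", seq_len(ncol(ref)))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# two clearly separated Gaussian score clusters
two_blob_scores <- function(n_per = 20, sep = 10, seed = 1) {
  set.seed(seed)
  rbind(
    cbind(rnorm(n_per), rnorm(n_per)),
    cbind(rnorm(n_per) + sep, rnorm(n_per) + sep)
  )
}

# compact hierarchical simulation reused by several structure tests
small_hier_truth <- function(seed, n_loci = 1500, individuals_per_lek = 10,
                             f_complex = 0.02, f_lek = 0.005) {
  simulate_hierarchical_frequencies(sim_config(
    n_complexes = 5, leks_per_complex = 2,
    individuals_per_lek = individuals_per_lek, n_loci = n_loci,
    f_complex = f_complex, f_lek = f_lek, ibd_strength = 0.05,
    seed = seed
  ))
}
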