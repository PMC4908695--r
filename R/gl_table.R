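#' Genotype likelihood table
#'
#' Per-individual, per-locus likelihoods of the three diploid genotypes at
#' biallelic SNPs, in the order hom-reference, heterozygote, hom-alternate,
#' stored as an individuals x loci x 3 array on the linear scale (arbitrary
#' common scaling per cell is allowed). Cells without any read carry a flat
#' triple and `has_read = FALSE`.
#'
#' @param likelihoods individuals x loci x 3 nonnegative array.
#' @param has_read individuals x loci logical matrix.
#' @param contig_id character vector, one contig label per locus.
#' @param locus_id character vector of locus names.
#' @param n_alt_alleles integer vector: alternate allele count per locus
#'   (biallelic = 1).
#' @param individuals character vector of individual ids.
#' @param ref_allele,alt_allele per-locus allele labels (default "A"/"C").
#' @return A `gl_table` object.
#' @export
gl_table <- function(likelihoods, has_read, contig_id, locus_id = NULL,
                     n_alt_alleles = NULL, individuals = NULL,
                     ref_allele = NULL, alt_allele = NULL) {
  d <- dim(likelihoods)
  if (length(d) != 3 || d[3] != 3) stop("likelihoods must be individuals x loci x 3")
  if (any(likelihoods < 0)) stop("likelihoods must be nonnegative")
  if (!all(dim(has_read) == d[1:2])) stop("has_read must match likelihood dimensions")
  if (length(contig_id) != d[2]) stop("one contig_id per locus required")
  if (is.null(locus_id)) locus_id <- sprintf("snp_%06d", seq_len(d[2]))
  if (is.null(n_alt_alleles)) n_alt_alleles <- rep(1L, d[2])
  if (is.null(individuals)) individuals <- sprintf("ind_%03d", seq_len(d[1]))
  tot <- likelihoods[, , 1] + likelihoods[, , 2] + likelihoods[, , 3]
  if (any(tot <= 0)) stop("a likelihood triple is all zero")
  if (is.null(ref_allele)) ref_allele <- rep("A", d[2])
  if (is.null(alt_allele)) alt_allele <- rep("C", d[2])
  structure(
    list(
      likelihoods = likelihoods,
      has_read = has_read,
      contig_id = as.character(contig_id),
      locus_id = as.character(locus_id),
      n_alt_alleles = as.integer(n_alt_alleles),
      individuals = as.character(individuals),
      ref_allele = as.character(ref_allele),
      alt_allele = as.character(alt_allele)
    ),
    class = "gl_table"
  )
}

#' @export
print.gl_table <- function(x, ...) {
  cat(sprintf(
    "gl_table: %d individuals x %d loci (%d contigs); call rate %.3f\n",
    n_individuals(x), n_loci(x), length(unique(x$contig_id)), mean(x$has_read)
  ))
  invisible(x)
}

#' @rdname gl_table
#' @param x a `gl_table`.
#' @export
n_loci <- function(x) UseMethod("n_loci")
#' @export
n_loci.gl_table <- function(x) dim(x$likelihoods)[2]
#' @export
n_loci.dosage_matrix <- function(x) ncol(x$dosage)

#' @rdname gl_table
#' @export
n_individuals <- function(x) UseMethod("n_individuals")
#' @export
n_individuals.gl_table <- function(x) dim(x$likelihoods)[1]
#' @export
n_individuals.dosage_matrix <- function(x) nrow(x$dosage)

# locus subset preserving order; keeps optional depth matrices in sync
subset_loci <- function(x, keep) {
  stopifnot(inherits(x, "gl_table"))
  out <- gl_table(
    likelihoods = x$likelihoods[, keep, , drop = FALSE],
    has_read = x$has_read[, keep, drop = FALSE],
    contig_id = x$contig_id[keep],
    locus_id = x$locus_id[keep],
    n_alt_alleles = x$n_alt_alleles[keep],
    individuals = x$individuals,
    ref_allele = x$ref_allele[keep],
    alt_allele = x$alt_allele[keep]
  )
  for (extra in c("depth", "true_alt_count")) {
    if (!is.null(x[[extra]])) out[[extra]] <- x[[extra]][, keep, drop = FALSE]
  }
  out
}

#' Binomial-read genotype likelihoods
#'
#' Likelihood of each diploid genotype g in \{0, 1, 2\} given `ref_reads`
#' reference and `alt_reads` alternate reads under a symmetric per-read error
#' model: L(g) = pi_g^alt * (1 - pi_g)^ref with
#' pi_g = (g/2)(1 - e) + (1 - g/2) e. The binomial coefficient is constant
#' across genotypes and dropped. With zero reads all three likelihoods are 1.
#'
#' @param ref_reads,alt_reads nonnegative counts (scalars, vectors or
#'   matrices of matching shape).
#' @param error_rate per-read miscall probability in `[0, 0.5)`.
#' @return An array with a trailing dimension of length 3 (genotypes 0, 1, 2).
#' @export
genotype_likelihoods_from_counts <- function(ref_reads, alt_reads, error_rate = 0.01) {
  if (any(ref_reads < 0) || any(alt_reads < 0)) stop("read counts must be nonnegative")
  error_rate <- check_prob(error_rate, "error_rate", 0, 0.5 - 1e-12)
  pis <- c(error_rate, 0.5, 1 - error_rate)
  shape <- if (is.matrix(ref_reads)) dim(ref_reads) else length(ref_reads)
  out <- array(0, c(prod(shape), 3))
  r <- as.numeric(ref_reads)
  a <- as.numeric(alt_reads)
  for (g in 1:3) {
    # log-scale for depth robustness; 0^0 := 1 at the e = 0 boundary
    la <- if (pis[g] > 0) a * log(pis[g]) else ifelse(a == 0, 0, -Inf)
    lr <- if (pis[g] < 1) r * log1p(-pis[g]) else ifelse(r == 0, 0, -Inf)
    out[, g] <- exp(la + lr)
  }
  # renormalize each triple by its max so deep coverage cannot underflow
  mx <- pmax(out[, 1], out[, 2], out[, 3])
  out <- out / mx
  if (is.matrix(ref_reads)) {
    array(out, c(dim(ref_reads), 3))
  } else if (length(r) == 1) {
    c(out)
  } else {
    array(out, c(length(r), 3))
  }
}

#' Filter loci by read-presence fraction
#'
#' Retains loci at which at least `min_fraction` of individuals have one or
#' more reads — the "SNPs called only when 90% of individuals had at least
#' one read" rule.
#'
#' @param table a [gl_table()].
#' @param min_fraction presence threshold (default 0.9); the boundary is kept
#'   (`>=`).
#' @return Filtered `gl_table`, locus order preserved.
#' @export
filter_presence <- function(table, min_fraction = 0.9) {
  stopifnot(inherits(table, "gl_table"))
  frac <- colMeans(table$has_read)
  keep <- frac >= min_fraction
  if (!any(keep)) warning("no loci pass the presence filter")
  subset_loci(table, keep)
}

#' Keep only biallelic loci
#'
#' Drops loci with more than one alternate allele.
#' @param table a [gl_table()].
#' @export
filter_biallelic <- function(table) {
  stopifnot(inherits(table, "gl_table"))
  subset_loci(table, table$n_alt_alleles <= 1L)
}

#' Filter loci by minor allele frequency
#'
#' Removes loci whose minor allele frequency is strictly below `min_maf`
#' (the boundary is retained). For a `gl_table` the frequency is the simple
#' likelihood-weighted estimate: mean posterior dosage under a flat genotype
#' prior, divided by 2. For a `dosage_matrix` the posterior-mean allele
#' frequency is used.
#'
#' @param x a [gl_table()] or `dosage_matrix`.
#' @param min_maf minimum minor allele frequency (default 0.05).
#' @return Object of the same class with failing loci removed.
#' @export
filter_maf <- function(x, min_maf = 0.05) {
  UseMethod("filter_maf")
}

#' @export
filter_maf.gl_table <- function(x, min_maf = 0.05) {
  q <- counts_based_freq(x)
  keep <- pmin(q, 1 - q) >= min_maf
  subset_loci(x, keep)
}

#' @export
filter_maf.dosage_matrix <- function(x, min_maf = 0.05) {
  q <- x$allele_freq_posterior_mean
  keep <- pmin(q, 1 - q) >= min_maf
  subset_dosage(x, keep)
}

# flat-prior posterior mean dosage / 2, averaged over individuals with reads
counts_based_freq <- function(table) {
  lk <- table$likelihoods
  tot <- lk[, , 1] + lk[, , 2] + lk[, , 3]
  post_dose <- (lk[, , 2] + 2 * lk[, , 3]) / tot
  has <- table$has_read
  num <- colSums(post_dose * has)
  den <- pmax(colSums(has), 1)
  num / (2 * den)
}

#' Thin to one SNP per contig
#'
#' For contigs carrying more than one SNP, selects a single SNP uniformly at
#' random (deterministic given `seed`), increasing independence among loci.
#'
#' @param table a [gl_table()].
#' @param seed integer seed for the random choice.
#' @export
thin_one_snp_per_contig <- function(table, seed = 1L) {
  stopifnot(inherits(table, "gl_table"))
  with_seed(seed, {
    idx <- seq_len(n_loci(table))
    chosen <- vapply(
      split(idx, factor(table$contig_id, levels = unique(table$contig_id))),
      function(ix) if (length(ix) == 1) ix else ix[sample.int(length(ix), 1)],
      integer(1)
    )
    subset_loci(table, sort(unname(chosen)))
  })
}
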