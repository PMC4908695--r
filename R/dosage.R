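#' MCMC settings for the genotype model
#'
#' Defaults: 10,000 sampling steps after a 6,000-step burn-in, thinning every
#' other step (5,000 retained samples per locus).
#'
#' @param n_steps post-burn-in MCMC steps (> 0).
#' @param burn_in discarded initial steps; must be < `n_steps`.
#' @param thin keep every `thin`-th post-burn-in step (>= 1).
#' @param seed integer master seed; per-locus chain seeds are derived from it.
#' @return An `mcmc_settings` object.
#' @export
mcmc_settings <- function(n_steps = 10000, burn_in = 6000, thin = 2, seed = 1L) {
  n_steps <- check_count(n_steps, "n_steps")
  burn_in <- check_count(burn_in, "burn_in", min = 0)
  thin <- check_count(thin, "thin")
  if (burn_in >= n_steps) stop("`burn_in` must be smaller than `n_steps`")
  structure(
    list(n_steps = n_steps, burn_in = burn_in, thin = thin,
         seed = check_count(seed, "seed", min = 0)),
    class = "mcmc_settings"
  )
}

#' Estimate posterior genotype dosages by per-locus Gibbs sampling
#'
#' Fits, independently at every locus, the hierarchical Bayesian genotype
#' model in which the population allele frequency q acts as the prior on
#' genotypes: q has a flat Beta(1, 1) prior, genotypes follow Hardy-Weinberg
#' proportions given q, and reads enter through the genotype likelihood
#' triple. A conjugate Gibbs sampler alternates (i) sampling each
#' individual's genotype proportional to L_i(g) * HWE(g | q) and (ii)
#' updating q from Beta(1 + sum g, 1 + sum(2 - g)). Genotype probabilities
#' are Rao-Blackwellized averages of the conditional probabilities over the
#' retained iterations, and the composite genotype (dosage) is the posterior
#' mean alternate-allele count, a value in `[0, 2]`. Individuals without
#' reads at a locus have a flat likelihood and so receive a prior-driven
#' dosage near `2 * qbar`.
#'
#' Loci are independent; each locus gets its own chain seed derived from
#' `settings$seed`, so results do not depend on execution order.
#'
#' @param table a filtered biallelic [gl_table()].
#' @param settings an [mcmc_settings()].
#' @return A `dosage_matrix`: list with `dosage` (individuals x loci),
#'   `genotype_probs` (individuals x loci x 3), `allele_freq_posterior_mean`
#'   (per locus), plus individual and locus ids.
#' @export
estimate_dosages <- function(table, settings = mcmc_settings()) {
  stopifnot(inherits(table, "gl_table"), inherits(settings, "mcmc_settings"))
  L <- n_loci(table)
  locus_seeds <- with_seed(
    settings$seed,
    floor(runif(L, 0, 2^48))
  )
  fit <- .gibbs_dosage(
    as.numeric(table$likelihoods), n_individuals(table), L,
    settings$n_steps, settings$burn_in, settings$thin, locus_seeds
  )
  dimnames(fit$dosage) <- list(table$individuals, table$locus_id)
  structure(
    list(
      dosage = fit$dosage,
      genotype_probs = fit$probs,
      allele_freq_posterior_mean = as.numeric(fit$qbar),
      individuals = table$individuals,
      locus_id = table$locus_id,
      contig_id = table$contig_id,
      settings = settings
    ),
    class = "dosage_matrix"
  )
}

#' @export
print.dosage_matrix <- function(x, ...) {
  cat(sprintf(
    "dosage_matrix: %d individuals x %d loci; mean qbar = %.3f\n",
    nrow(x$dosage), ncol(x$dosage), mean(x$allele_freq_posterior_mean)
  ))
  invisible(x)
}

subset_dosage <- function(x, keep) {
  stopifnot(inherits(x, "dosage_matrix"))
  if (is.logical(keep)) keep <- which(keep)
  x$dosage <- x$dosage[, keep, drop = FALSE]
  x$genotype_probs <- x$genotype_probs[, keep, , drop = FALSE]
  x$allele_freq_posterior_mean <- x$allele_freq_posterior_mean[keep]
  x$locus_id <- x$locus_id[keep]
  if (!is.null(x$contig_id)) x$contig_id <- x$contig_id[keep]
  x
}

# Coerce a plain numeric matrix (e.g. true genotypes) into the dosage
# container so that downstream ordination / differentiation functions can be
# run directly on simulation truth. Genotype probabilities are the
# point-mass triples of the (possibly fractional) dosages.
#' Treat a genotype matrix as a dosage matrix
#' @param g individuals x loci matrix with values in `[0, 2]`.
#' @return A `dosage_matrix`.
#' @export
as_dosage_matrix <- function(g) {
  if (inherits(g, "dosage_matrix")) return(g)
  g <- as.matrix(g)
  if (any(g < 0 | g > 2)) stop("dosages must lie in [0, 2]")
  probs <- array(0, c(nrow(g), ncol(g), 3))
  # decompose dosage d as P(het) = frac toward nearest states
  p2 <- pmax(g - 1, 0)
  p1 <- g - 2 * p2
  probs[, , 2] <- p1
  probs[, , 3] <- p2
  probs[, , 1] <- 1 - p1 - p2
  structure(
    list(
      dosage = g,
      genotype_probs = probs,
      allele_freq_posterior_mean = colMeans(g) / 2,
      individuals = rownames(g) %||% sprintf("ind_%03d", seq_len(nrow(g))),
      locus_id = colnames(g) %||% sprintf("snp_%06d", seq_len(ncol(g)))
    ),
    class = "dosage_matrix"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write dosages and a per-locus summary
#'
#' @param x a `dosage_matrix`.
#' @param dosage_path TSV output (individuals x loci).
#' @param summary_path optional CSV with per-locus posterior allele frequency,
#'   MAF and call-rate-free locus id bookkeeping.
#' @export
write_dosage_tsv <- function(x, dosage_path, summary_path = NULL) {
  stopifnot(inherits(x, "dosage_matrix"))
  df <- data.frame(individual = x$individuals, x$dosage, check.names = FALSE)
  write.table(df, dosage_path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(summary_path)) {
    q <- x$allele_freq_posterior_mean
    write.csv(
      data.frame(locus = x$locus_id, qbar = q, maf = pmin(q, 1 - q)),
      summary_path,
      row.names = FALSE, quote = FALSE
    )
  }
  invisible(dosage_path)
}
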