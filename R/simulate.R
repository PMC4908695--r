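#' Simulation configuration for a hierarchical lek sampling design
#'
#' Defines a two-level island-model population structure — lek complexes, each
#' containing several leks — together with a sequencing model for reduced-
#' representation (GBS-style) read data. Defaults emulate a study design of
#' 140 males sampled from 10 leks in 5 lek complexes, genotyped at thousands
#' of biallelic SNPs with mean per-locus per-individual coverage 5.7X
#' (sd 1.7 across loci).
#'
#' Differentiation follows the Balding–Nichols parameterization: complex-level
#' allele frequencies are Beta-distributed around the ancestral frequency with
#' variance `f_complex * p * (1 - p)`, and lek-level frequencies likewise
#' around their complex frequency with coefficient `f_lek`, so the two
#' coefficients are interpretable directly as expected F_ST at each level.
#'
#' @param n_complexes number of lek complexes.
#' @param leks_per_complex leks within each complex.
#' @param individuals_per_lek diploid males sampled per lek.
#' @param n_loci number of biallelic SNP loci.
#' @param ancestral_maf_range interval in (0, 0.5] from which ancestral minor
#'   allele frequencies are drawn uniformly (allele orientation randomized).
#' @param f_complex complex-level differentiation coefficient in `[0, 1)`.
#' @param f_lek lek-level differentiation coefficient in `[0, 1)`.
#' @param ibd_strength latitudinal allele-frequency gradient coefficient
#'   (frequency shift per standardized latitude unit); 0 disables the cline.
#' @param mean_coverage mean reads per locus per individual (> 0).
#' @param coverage_sd standard deviation of the per-locus coverage rate.
#' @param error_rate per-read miscall probability in `[0, 0.5)`.
#' @param missing_locus_fraction_target anticipated fraction of
#'   individual-by-locus cells without reads; used for validation summaries
#'   only — missingness itself arises mechanistically from sampled depth 0.
#' @param seed integer seed; identical seed and config give bitwise-identical
#'   output.
#' @return A validated `sim_config` object (a list).
#' @export
sim_config <- function(n_complexes = 5, leks_per_complex = 2,
                       individuals_per_lek = 14, n_loci = 27866,
                       ancestral_maf_range = c(0.05, 0.5),
                       f_complex = 0.02, f_lek = 0.005,
                       ibd_strength = 0.05,
                       mean_coverage = 5.7, coverage_sd = 1.7,
                       error_rate = 0.01,
                       missing_locus_fraction_target = 0.03,
                       seed = 1L) {
  cfg <- list(
    n_complexes = check_count(n_complexes, "n_complexes"),
    leks_per_complex = check_count(leks_per_complex, "leks_per_complex"),
    individuals_per_lek = check_count(individuals_per_lek, "individuals_per_lek"),
    n_loci = check_count(n_loci, "n_loci"),
    ancestral_maf_range = ancestral_maf_range,
    f_complex = check_prob(f_complex, "f_complex", 0, 1 - 1e-12),
    f_lek = check_prob(f_lek, "f_lek", 0, 1 - 1e-12),
    ibd_strength = check_prob(ibd_strength, "ibd_strength", 0, Inf),
    mean_coverage = check_prob(mean_coverage, "mean_coverage", 1e-12, Inf),
    coverage_sd = check_prob(coverage_sd, "coverage_sd", 0, Inf),
    error_rate = check_prob(error_rate, "error_rate", 0, 0.5 - 1e-12),
    missing_locus_fraction_target =
      check_prob(missing_locus_fraction_target, "missing_locus_fraction_target", 0, 1 - 1e-12),
    seed = check_count(seed, "seed", min = 0)
  )
  if (length(cfg$ancestral_maf_range) != 2 ||
    cfg$ancestral_maf_range[1] <= 0 || cfg$ancestral_maf_range[2] > 0.5 ||
    cfg$ancestral_maf_range[1] > cfg$ancestral_maf_range[2]) {
    stop("`ancestral_maf_range` must be an interval within (0, 0.5]")
  }
  class(cfg) <- "sim_config"
  cfg
}

# Balding-Nichols Beta draw with mean p and variance f*p*(1-p).
# f = 0 is the zero-variance limit (frequency equals the mean exactly);
# p is clamped away from 0/1 so the Beta shape parameters stay positive.
rbeta_bn <- function(n, p, f) {
  p <- pmin(pmax(p, 0.001), 0.999)
  if (f <= 0) {
    return(rep(p, length.out = n))
  }
  scale <- (1 - f) / f
  rbeta(n, p * scale, (1 - p) * scale)
}

#' Simulate hierarchically structured allele frequencies and true genotypes
#'
#' Draws ancestral allele frequencies, then complex-level and lek-level
#' frequencies under the Balding–Nichols model, optionally tilts complex
#' frequencies along a latitudinal cline (isolation by distance), and samples
#' individual genotypes from Hardy–Weinberg proportions at the lek frequency.
#' Lek coordinates are laid out on a local projected (km) grid: complexes are
#' spread along a latitudinal axis with longitudinal scatter, and leks scatter
#' within a few km of their complex center, emulating a <15 km complex radius
#' and tens-of-km between-complex spacing.
#'
#' @param config a [sim_config()].
#' @return A `truth_record` list with elements `freq_ancestral` (per locus),
#'   `freq_complex` (complex x locus), `freq_lek` (lek x locus), `genotypes`
#'   (individuals x loci, values 0/1/2), `metadata` (data.frame: individual,
#'   lek, complex, lek_x, lek_y, lek_lat, lek_lon), and the `config`.
#' @export
simulate_hierarchical_frequencies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    nc <- config$n_complexes
    nl <- nc * config$leks_per_complex
    ni <- nl * config$individuals_per_lek
    L <- config$n_loci

    # ancestral frequencies: uniform MAF, random allele orientation
    maf <- runif(L, config$ancestral_maf_range[1], config$ancestral_maf_range[2])
    flip <- runif(L) < 0.5
    p_anc <- ifelse(flip, 1 - maf, maf)

    # geography: complexes strung south-to-north ~35 km apart, leks within ~5 km
    complex_y <- seq(0, by = 35, length.out = nc) + rnorm(nc, 0, 5)
    complex_x <- rnorm(nc, 0, 12)
    lek_complex <- rep(seq_len(nc), each = config$leks_per_complex)
    lek_x <- complex_x[lek_complex] + rnorm(nl, 0, 4)
    lek_y <- complex_y[lek_complex] + rnorm(nl, 0, 4)

    # complex-level frequencies; latitudinal cline applied to the complex means
    # (a single complex, or zero spread, has no cline)
    lat_std <- if (nc > 1 && sd(complex_y) > 0) {
      as.numeric(scale(complex_y))
    } else {
      rep(0, nc)
    }
    freq_complex <- matrix(0, nc, L)
    for (ci in seq_len(nc)) {
      mean_ci <- p_anc + config$ibd_strength * lat_std[ci]
      mean_ci <- pmin(pmax(mean_ci, 0.001), 0.999)
      freq_complex[ci, ] <- rbeta_bn(L, mean_ci, config$f_complex)
    }
    freq_complex <- pmin(pmax(freq_complex, 0.001), 0.999)

    freq_lek <- matrix(0, nl, L)
    for (li in seq_len(nl)) {
      freq_lek[li, ] <- rbeta_bn(L, freq_complex[lek_complex[li], ], config$f_lek)
    }
    freq_lek <- pmin(pmax(freq_lek, 0.001), 0.999)

    ind_lek <- rep(seq_len(nl), each = config$individuals_per_lek)
    genotypes <- matrix(0L, ni, L)
    for (li in seq_len(nl)) {
      rows <- which(ind_lek == li)
      # HWE: genotype = sum of two Bernoulli(q) allele draws
      genotypes[rows, ] <- matrix(
        rbinom(length(rows) * L, 2L, rep(freq_lek[li, ], each = length(rows))),
        length(rows), L
      )
    }

    lek_names <- sprintf("lek_%02d", seq_len(nl))
    complex_names <- sprintf("complex_%d", seq_len(nc))
    metadata <- data.frame(
      individual = sprintf("ind_%03d", seq_len(ni)),
      lek = lek_names[ind_lek],
      complex = complex_names[lek_complex[ind_lek]],
      lek_x = lek_x[ind_lek],
      lek_y = lek_y[ind_lek],
      # equirectangular inverse about a reference point in central Nevada
      lek_lat = 39.5 + lek_y[ind_lek] / 111.2,
      lek_lon = -116.2 + lek_x[ind_lek] / (111.2 * cos(39.5 * pi / 180)),
      stringsAsFactors = FALSE
    )
    rownames(genotypes) <- metadata$individual

    structure(
      list(
        freq_ancestral = p_anc,
        freq_complex = freq_complex,
        freq_lek = freq_lek,
        genotypes = genotypes,
        metadata = metadata,
        lek_complex = lek_complex,
        config = config
      ),
      class = "truth_record"
    )
  })
}

#' Simulate read counts and genotype likelihoods from true genotypes
#'
#' Coverage model: each locus has a rate drawn from Normal(mean_coverage,
#' coverage_sd) truncated at 0; each individual's depth at that locus is
#' Poisson with that rate, so the realized per-locus mean depth has
#' approximately the configured mean and sd across loci. Alternate-read counts
#' are Binomial(depth, pi_g) with pi_g = (g/2)(1-e) + (1-g/2)e for true
#' genotype g and error rate e. Cells with depth 0 carry a flat likelihood
#' triple and are flagged as having no read.
#'
#' @param truth a `truth_record` from [simulate_hierarchical_frequencies()].
#' @param config the same [sim_config()] used to build `truth`.
#' @return A [gl_table()] with attached read depth matrix (`depth` element).
#' @export
simulate_reads <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "truth_record"))
  with_seed(derive_seed(config$seed, "reads"), {
    g <- truth$genotypes
    ni <- nrow(g)
    L <- ncol(g)
    locus_rate <- pmax(rnorm(L, config$mean_coverage, config$coverage_sd), 0)
    depth <- matrix(rpois(ni * L, rep(locus_rate, each = ni)), ni, L)
    pi_g <- (g / 2) * (1 - config$error_rate) + (1 - g / 2) * config$error_rate
    alt <- matrix(rbinom(ni * L, depth, pi_g), ni, L)
    ref <- depth - alt

    lik <- genotype_likelihoods_from_counts(ref, alt, config$error_rate)
    # spread loci across contigs: ~70% singleton contigs, rest share
    contig <- sprintf("contig_%06d", cumsum(runif(L) < 0.7) + 1L)

    tab <- gl_table(
      likelihoods = lik,
      has_read = depth > 0,
      contig_id = contig,
      locus_id = sprintf("snp_%06d", seq_len(L)),
      n_alt_alleles = rep(1L, L),
      individuals = rownames(g)
    )
    tab$depth <- depth
    tab$true_alt_count <- alt
    tab
  })
}

#' Simulate a smooth resistance raster with optional barrier features
#'
#' Generates a positive spatially-autocorrelated random field by smoothing
#' white noise with a separable Gaussian kernel, rescaled linearly to
#' `[1, r_max]`. `roughness` scales the amplitude of the field: 0 gives a
#' constant raster of 1. Barrier line segments, if given, are stored with the
#' raster for later buffering by [apply_barriers()].
#'
#' @param n_rows,n_cols raster dimensions (each >= 2).
#' @param cell_size cell edge length in map units.
#' @param roughness nonnegative field amplitude; 0 = flat.
#' @param barrier_lines optional data.frame with columns x1, y1, x2, y2.
#' @param r_max maximum resistance after rescaling (default 100).
#' @param smooth_cells Gaussian kernel sd in cells (spatial correlation range).
#' @param origin numeric xy of the lower-left corner (map units).
#' @param seed integer seed.
#' @return A [resistance_raster()]; barrier segments attached as
#'   attribute `"barrier_lines"`.
#' @export
simulate_resistance_raster <- function(n_rows, n_cols, cell_size = 1,
                                       roughness = 1, barrier_lines = NULL,
                                       r_max = 100, smooth_cells = 3,
                                       origin = c(0, 0), seed = 1L) {
  n_rows <- check_count(n_rows, "n_rows", 2)
  n_cols <- check_count(n_cols, "n_cols", 2)
  with_seed(seed, {
    if (roughness <= 0) {
      vals <- matrix(1, n_rows, n_cols)
    } else {
      noise <- matrix(rnorm(n_rows * n_cols), n_rows, n_cols)
      sm <- gauss_weights(n_rows, smooth_cells) %*% noise %*%
        t(gauss_weights(n_cols, smooth_cells))
      rng <- range(sm)
      if (diff(rng) < 1e-12) {
        vals <- matrix(1, n_rows, n_cols)
      } else {
        u <- (sm - rng[1]) / diff(rng) # in [0,1]
        vals <- 1 + u * min(roughness, 1) * (r_max - 1)
      }
    }
    ras <- resistance_raster(vals, origin = origin, cell_size = cell_size)
    attr(ras, "barrier_lines") <- barrier_lines
    ras
  })
}

# row-normalized Gaussian smoothing weights; robust for any raster size
gauss_weights <- function(n, sd_cells) {
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  w <- exp(-0.5 * (d / max(sd_cells, 1e-9))^2)
  w / rowSums(w)
}
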