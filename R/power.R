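#' Locus-subsampling design
#'
#' Defaults follow the study design of ten random replicate data sets at each
#' of 21 sizes from 50 to 27,000 SNPs.
#'
#' @param sizes ordered SNP counts (positive, non-decreasing).
#' @param replicates_per_size random replicates per size (default 10).
#' @param seed integer master seed; each size x replicate gets a derived seed.
#' @return A `subsample_design` object.
#' @export
subsample_design <- function(sizes = c(50, 150, 250, 500, 1000, 2000, 3000,
                                       4000, 5000, 6000, 8000, 10000, 12000,
                                       14000, 16000, 18000, 20000, 22000,
                                       24000, 26000, 27000),
                             replicates_per_size = 10, seed = 1L) {
  if (any(sizes < 1) || is.unsorted(sizes)) {
    stop("sizes must be positive and non-decreasing")
  }
  structure(
    list(
      sizes = as.integer(sizes),
      replicates_per_size = check_count(replicates_per_size, "replicates_per_size"),
      seed = check_count(seed, "seed", min = 0)
    ),
    class = "subsample_design"
  )
}

#' Precision of structure estimates as a function of SNP count
#'
#' For every size x replicate, draws that many loci uniformly without
#' replacement, runs PCA (2 axes) plus the Procrustes correlation against
#' lek geography, and DAPC with a priori lek and lek-complex labels; reports
#' the mean and standard deviation of each statistic per size. Replicates at
#' `size == ncol(dosage)` all equal the full-data value. Fully deterministic
#' given the design seed.
#'
#' @param dosage a `dosage_matrix` or individuals x loci matrix.
#' @param coords individuals x 2 matrix of (projected) lek coordinates, one
#'   row per individual.
#' @param lek,complex group labels per individual.
#' @param design a [subsample_design()]; `max(sizes)` must not exceed the
#'   available loci.
#' @param n_pcs_policy function(size, n_individuals) giving the DAPC PC
#'   retention for a subset; the default caps at 20 PCs and never exceeds
#'   the subset size or n - 1. Full alpha-score re-optimization per subset
#'   can be plugged in here when wanted.
#' @return A `power_curve` data.frame: one row per size with mean and sd of
#'   the Procrustes correlation and of the lek- and complex-level correct
#'   assignment proportions.
#' @export
run_subsampling <- function(dosage, coords, lek, complex, design,
                            n_pcs_policy = function(size, n) min(20, n - 1, size)) {
  x <- if (inherits(dosage, "dosage_matrix")) dosage$dosage else as.matrix(dosage)
  L <- ncol(x)
  if (max(design$sizes) > L) stop("subsample size exceeds available loci")
  coords <- as.matrix(coords)
  n <- nrow(x)
  rows <- lapply(design$sizes, function(size) {
    stat <- vapply(seq_len(design$replicates_per_size), function(rep) {
      loci <- with_seed(
        derive_seed(design$seed, sprintf("subsample_%d_%d", size, rep)),
        sample.int(L, size)
      )
      sub <- x[, loci, drop = FALSE]
      pca <- run_pca(sub, n_axes = 2)
      pro <- procrustes_correlation(pca$scores, coords)
      npc <- n_pcs_policy(size, n)
      c(
        procrustes = pro,
        lek = dapc_fit(sub, lek, npc)$reassignment_overall,
        complex = dapc_fit(sub, complex, npc)$reassignment_overall
      )
    }, numeric(3))
    data.frame(
      size = size,
      procrustes_mean = mean(stat["procrustes", ]),
      procrustes_sd = sd(stat["procrustes", ]),
      lek_assign_mean = mean(stat["lek", ]),
      lek_assign_sd = sd(stat["lek", ]),
      complex_assign_mean = mean(stat["complex", ]),
      complex_assign_sd = sd(stat["complex", ])
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("power_curve", "data.frame")
  out
}

#' Smallest SNP count reaching the large-sample plateau
#'
#' For each metric, returns the smallest size whose mean is within
#' `tolerance * |mean at the largest size|` of the largest-size mean.
#'
#' @param curve a `power_curve` from [run_subsampling()].
#' @param tolerance relative tolerance (fraction of the largest-size mean).
#' @param metrics mean columns to scan.
#' @return Named integer vector of plateau sizes, one per metric.
#' @export
plateau_size <- function(curve, tolerance = 0.05,
                         metrics = c("procrustes_mean", "lek_assign_mean",
                                     "complex_assign_mean")) {
  if (nrow(curve) == 0) stop("empty power curve")
  vapply(metrics, function(mc) {
    v <- curve[[mc]]
    ref <- v[nrow(curve)]
    ok <- abs(v - ref) <= tolerance * abs(ref)
    as.integer(curve$size[which(ok)[1]])
  }, integer(1))
}
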