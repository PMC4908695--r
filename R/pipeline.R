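#' Pipeline run configuration
#'
#' Exactly one of `simulation` (a [sim_config()]) or `input_paths` (a named
#' list with `vcf` or `likelihood_table`+`locus_table`, `metadata`, and
#' optionally `raster` and `barriers`) must be supplied. Defaults follow the
#' standard protocol: presence filter 0.9, MAF filter 0.05, 10,000-step MCMC
#' after 6,000 burn-in with thinning 2, 999 permutations for ordination /
#' Mantel / F_ST tests and 1,000 for the pair-sharing test.
#'
#' @param simulation a [sim_config()] or NULL.
#' @param input_paths named list of input file paths or NULL.
#' @param presence_min presence-filter threshold.
#' @param maf_min minor-allele-frequency threshold.
#' @param mcmc list(n_steps, burn_in, thin) for [mcmc_settings()].
#' @param n_perm permutations for Procrustes / PERMANOVA / Mantel / MRM /
#'   F_ST tests.
#' @param n_perm_pair_sharing permutations for the pair-sharing test.
#' @param dapc_n_pcs PCs retained in the a priori DAPC fits; `NULL` selects
#'   by alpha-score over `dapc_candidates`.
#' @param dapc_candidates candidate PC counts for the alpha-score search.
#' @param subsample optional [subsample_design()] to run the power analysis.
#' @param fst_permutations run per-pair F_ST permutation tests? (they
#'   dominate runtime for many leks)
#' @param out_dir output directory (created if missing).
#' @param seed master seed; every stochastic stage receives a seed derived
#'   deterministically from it.
#' @param log_level `"info"` or `"quiet"`.
#' @return A validated `run_config`.
#' @export
run_config <- function(simulation = NULL, input_paths = NULL,
                       presence_min = 0.9, maf_min = 0.05,
                       mcmc = list(n_steps = 10000, burn_in = 6000, thin = 2),
                       n_perm = 999, n_perm_pair_sharing = 1000,
                       dapc_n_pcs = 20, dapc_candidates = NULL,
                       subsample = NULL, fst_permutations = FALSE,
                       out_dir = tempfile("lekscape_run_"), seed = 1L,
                       log_level = c("info", "quiet")) {
  if (is.null(simulation) == is.null(input_paths)) {
    stop("exactly one of `simulation` or `input_paths` must be given")
  }
  if (!is.null(simulation)) stopifnot(inherits(simulation, "sim_config"))
  structure(
    list(
      simulation = simulation, input_paths = input_paths,
      presence_min = presence_min, maf_min = maf_min, mcmc = mcmc,
      n_perm = n_perm, n_perm_pair_sharing = n_perm_pair_sharing,
      dapc_n_pcs = dapc_n_pcs, dapc_candidates = dapc_candidates,
      subsample = subsample, fst_permutations = fst_permutations,
      out_dir = out_dir, seed = check_count(seed, "seed", min = 0),
      log_level = match.arg(log_level)
    ),
    class = "run_config"
  )
}

#' Read and validate pipeline inputs
#'
#' Loads genotype likelihoods (VCF with PL or GL, or the plain likelihood
#' table), the sample metadata CSV, and optionally a resistance raster (ESRI
#' ASCII) and a barrier segment CSV (`x1,y1,x2,y2`). Every genotyped
#' individual must appear in the metadata with lek, complex and coordinates.
#'
#' @param paths named list: `vcf` or (`likelihood_table` and `locus_table`),
#'   `metadata`, optional `raster`, optional `barriers`.
#' @return List: `table` ([gl_table()]), `metadata`, `raster` (or NULL),
#'   `barriers` (or NULL).
#' @export
read_inputs <- function(paths) {
  table <- if (!is.null(paths$vcf)) {
    read_genotype_likelihoods_vcf(paths$vcf)
  } else if (!is.null(paths$likelihood_table)) {
    read_likelihood_table(paths$likelihood_table, paths$locus_table)
  } else {
    stop("no genotype input (need `vcf` or `likelihood_table`)")
  }
  metadata <- read_metadata_csv(paths$metadata)
  missing_ids <- setdiff(table$individuals, metadata$individual)
  if (length(missing_ids)) {
    stop(
      "individuals present in genotypes but absent from metadata: ",
      paste(missing_ids, collapse = ", ")
    )
  }
  metadata <- metadata[match(table$individuals, metadata$individual), ]
  raster <- if (!is.null(paths$raster)) read_esri_ascii(paths$raster) else NULL
  barriers <- if (!is.null(paths$barriers)) {
    barrier_set(read.csv(paths$barriers))
  } else {
    NULL
  }
  list(table = table, metadata = metadata, raster = raster, barriers = barriers)
}

pipeline_log <- function(config, fmt, ...) {
  if (config$log_level != "quiet") message(sprintf(fmt, ...))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order — acquire data (simulate or load),
#' SNP filtering cascade, dosage estimation, ordination suite, differentiation
#' suite, landscape suite, optional subsampling power analysis — writing each
#' stage's artifacts under `config$out_dir` and returning a manifest. Rerunning
#' with an identical config reproduces identical outputs.
#'
#' @param config a [run_config()].
#' @return The run manifest (list), invisibly also written as
#'   `manifest.json` in the output directory.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  manifest <- list(package_version = as.character(utils::packageVersion("lekscape")),
                   master_seed = config$seed, stages = list())

  # --- stage: data -----------------------------------------------------------
  if (!is.null(config$simulation)) {
    pipeline_log(config, "simulating hierarchical truth and reads")
    truth <- simulate_hierarchical_frequencies(config$simulation)
    table <- simulate_reads(truth, config$simulation)
    metadata <- truth$metadata
    raster <- NULL
    barriers <- NULL
    write_metadata_csv(metadata, out("metadata.csv"))
    manifest$stages$data <- list(
      mode = "simulation", seed = config$simulation$seed,
      n_individuals = n_individuals(table), n_loci = n_loci(table),
      missing_fraction = mean(!table$has_read)
    )
  } else {
    pipeline_log(config, "reading inputs")
    inp <- read_inputs(config$input_paths)
    table <- inp$table
    metadata <- inp$metadata
    raster <- inp$raster
    barriers <- inp$barriers
    truth <- NULL
    manifest$stages$data <- list(
      mode = "files", paths = config$input_paths,
      n_individuals = n_individuals(table), n_loci = n_loci(table)
    )
  }

  # --- stage: filtering cascade ---------------------------------------------
  counts <- c(input = n_loci(table))
  table <- filter_presence(table, config$presence_min)
  counts["presence"] <- n_loci(table)
  table <- filter_biallelic(table)
  counts["biallelic"] <- n_loci(table)
  table <- filter_maf(table, config$maf_min)
  counts["maf"] <- n_loci(table)
  table <- thin_one_snp_per_contig(table, seed = derive_seed(config$seed, "thin"))
  counts["thinned"] <- n_loci(table)
  pipeline_log(config, "filter cascade: %s",
               paste(names(counts), counts, sep = "=", collapse = ", "))
  manifest$stages$filters <- as.list(counts)

  # --- stage: dosage estimation ---------------------------------------------
  pipeline_log(config, "estimating dosages (%d loci)", n_loci(table))
  settings <- mcmc_settings(
    n_steps = config$mcmc$n_steps, burn_in = config$mcmc$burn_in,
    thin = config$mcmc$thin, seed = derive_seed(config$seed, "mcmc")
  )
  dosage <- estimate_dosages(table, settings)
  write_dosage_tsv(dosage, out("dosage.tsv"), out("locus_summary.csv"))
  manifest$stages$dosage <- list(
    seed = settings$seed, n_steps = settings$n_steps,
    burn_in = settings$burn_in, thin = settings$thin,
    mean_qbar = mean(dosage$allele_freq_posterior_mean)
  )

  # --- stage: ordination suite ----------------------------------------------
  pipeline_log(config, "ordination suite")
  coords <- project_coords(metadata$lek_lat, metadata$lek_lon)
  pca <- run_pca(dosage, n_axes = 2)
  pro <- procrustes_permutation_test(
    pca$scores, coords,
    n_perm = config$n_perm, seed = derive_seed(config$seed, "procrustes")
  )
  pair_lek <- pair_sharing_distance_test(
    pca$scores, metadata$lek,
    n_perm = config$n_perm_pair_sharing, seed = derive_seed(config$seed, "pair_lek")
  )
  pair_complex <- pair_sharing_distance_test(
    pca$scores, metadata$complex,
    n_perm = config$n_perm_pair_sharing, seed = derive_seed(config$seed, "pair_cpx")
  )
  perma_lek <- permanova(pca$scores, metadata$lek,
    n_perm = config$n_perm, seed = derive_seed(config$seed, "permanova_lek")
  )
  perma_complex <- permanova(pca$scores, metadata$complex,
    n_perm = config$n_perm, seed = derive_seed(config$seed, "permanova_cpx")
  )
  npc <- config$dapc_n_pcs
  if (is.null(npc)) {
    cands <- config$dapc_candidates %||%
      unique(pmin(seq(5, 40, by = 5), n_individuals(table) - 1))
    npc <- optimize_a_score(dosage, metadata$lek, cands,
      seed = derive_seed(config$seed, "ascore")
    )$optimal_n_pcs
  }
  npc <- min(npc, n_individuals(table) - 1, n_loci(table))
  dapc_lek <- dapc_fit(dosage, metadata$lek, npc)
  dapc_complex <- dapc_fit(dosage, metadata$complex, npc)
  rda <- rda_fit(dosage, cbind(lat = metadata$lek_lat, lon = metadata$lek_lon))
  utils::write.csv(
    data.frame(individual = metadata$individual, pca$scores,
               lek = metadata$lek, complex = metadata$complex),
    out("pca_scores.csv"),
    row.names = FALSE
  )
  ord_summary <- list(
    pca_variance_fractions = pca$axis_variance_fraction,
    procrustes_t = pro$observed, procrustes_p = pro$p_value,
    pair_sharing_p_lek = pair_lek$p_value,
    pair_sharing_p_complex = pair_complex$p_value,
    permanova_R2_lek = perma_lek$R2, permanova_p_lek = perma_lek$test$p_value,
    permanova_R2_complex = perma_complex$R2,
    permanova_p_complex = perma_complex$test$p_value,
    dapc_n_pcs = npc,
    dapc_assignment_lek = dapc_lek$reassignment_overall,
    dapc_assignment_complex = dapc_complex$reassignment_overall,
    rda_variance_fractions = rda$axis_variance_fraction
  )
  jsonlite::write_json(ord_summary, out("ordination.json"),
    auto_unbox = TRUE, digits = NA
  )
  manifest$stages$ordination <- ord_summary

  # --- stage: differentiation suite -----------------------------------------
  pipeline_log(config, "differentiation suite")
  lek_levels <- unique(metadata$lek)
  fst_lek <- fst_matrix(dosage, metadata$lek, lek_levels)
  nei_lek <- nei_matrix(dosage, metadata$lek, lek_levels)
  nj <- neighbor_joining(nei_lek)
  write_pairwise_csv(fst_lek, out("fst_lek.csv"))
  write_pairwise_csv(nei_lek, out("nei_d_lek.csv"))
  writeLines(nj$newick, out("nj_lek.nwk"))
  fst_p <- NULL
  if (isTRUE(config$fst_permutations)) {
    pairs <- utils::combn(lek_levels, 2)
    fst_p <- apply(pairs, 2, function(pr) {
      fst_permutation_test(dosage, metadata$lek, pr,
        n_perm = config$n_perm,
        seed = derive_seed(config$seed, paste0("fst_", paste(pr, collapse = "_")))
      )$p_value
    })
    names(fst_p) <- apply(pairs, 2, paste, collapse = "|")
  }
  manifest$stages$differentiation <- list(
    mean_fst_lek = mean(lower_triangle(fst_lek)),
    mean_nei_d_lek = mean(lower_triangle(nei_lek)),
    fst_permutation_p = fst_p
  )

  # --- stage: landscape suite -----------------------------------------------
  pipeline_log(config, "landscape suite")
  lek_coords <- unique(data.frame(
    lek = metadata$lek,
    x = coords[, "x"], y = coords[, "y"]
  ))
  lek_coords <- lek_coords[match(lek_levels, lek_coords$lek), ]
  if (is.null(raster)) {
    pad <- 10
    extent <- c(
      min(lek_coords$x) - pad, max(lek_coords$x) + pad,
      min(lek_coords$y) - pad, max(lek_coords$y) + pad
    )
    cell <- max((extent[2] - extent[1]) / 80, (extent[4] - extent[3]) / 80)
    raster <- simulate_resistance_raster(
      n_rows = ceiling((extent[4] - extent[3]) / cell),
      n_cols = ceiling((extent[2] - extent[1]) / cell),
      cell_size = cell, roughness = 1,
      origin = c(extent[1], extent[3]),
      seed = derive_seed(config$seed, "raster")
    )
  }
  geo <- geographic_distances(
    as.matrix(lek_coords[, c("x", "y")]),
    mode = "projected", labels = lek_levels
  )
  lcd <- least_cost_distances(raster, lek_coords[, c("x", "y")], lek_levels)
  mantel_geo <- mantel_test(nei_lek, geo,
    n_perm = config$n_perm, seed = derive_seed(config$seed, "mantel_geo")
  )
  mrm_habitat <- mrm(nei_lek, list(distance = geo, habitat = lcd),
    n_perm = config$n_perm, seed = derive_seed(config$seed, "mrm_habitat")
  )
  write_pairwise_csv(geo, out("geographic_distance.csv"))
  write_pairwise_csv(lcd, out("least_cost_distance.csv"))
  write_esri_ascii(raster, out("resistance.asc"))
  landscape_summary <- list(
    mantel_R2_distance = mantel_geo$R2, mantel_p_distance = mantel_geo$test$p_value,
    mrm_R2_distance_habitat = mrm_habitat$R2,
    mrm_p_distance_habitat = mrm_habitat$test$p_value
  )
  if (!is.null(barriers)) {
    for (perm_mode in c("permeable", "low_permeable")) {
      b <- barriers
      b$permeability <- perm_mode
      ras_b <- apply_barriers(raster, b)
      lcd_b <- least_cost_distances(ras_b, lek_coords[, c("x", "y")], lek_levels)
      fit_b <- mrm(nei_lek, list(distance = geo, barrier = lcd_b),
        n_perm = config$n_perm,
        seed = derive_seed(config$seed, paste0("mrm_", perm_mode))
      )
      landscape_summary[[paste0("mrm_R2_", perm_mode)]] <- fit_b$R2
      landscape_summary[[paste0("mrm_p_", perm_mode)]] <- fit_b$test$p_value
    }
  }
  jsonlite::write_json(landscape_summary, out("landscape.json"),
    auto_unbox = TRUE, digits = NA
  )
  manifest$stages$landscape <- landscape_summary

  # --- stage: power analysis -------------------------------------------------
  if (!is.null(config$subsample)) {
    pipeline_log(config, "subsampling power analysis")
    curve <- run_subsampling(
      dosage, coords, metadata$lek, metadata$complex, config$subsample
    )
    utils::write.csv(curve, out("power_curve.csv"), row.names = FALSE)
    manifest$stages$power <- list(
      sizes = config$subsample$sizes,
      plateau = as.list(plateau_size(curve))
    )
  }

  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
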