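#' Write a genotype likelihood table as VCF
#'
#' Minimal VCF 4.2 with GT (most likely genotype; `./.` when the individual
#' has no read) and phred-scaled PL fields, ploidy 2, one record per locus.
#' Positions are assigned sequentially within each contig.
#'
#' @param table a [gl_table()].
#' @param path output path (plain text).
#' @export
write_vcf <- function(table, path) {
  stopifnot(inherits(table, "gl_table"))
  lk <- table$likelihoods
  n <- n_individuals(table)
  L <- n_loci(table)
  pos <- stats::ave(seq_len(L), table$contig_id, FUN = seq_along) * 10L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=lekscape",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=PL,Number=G,Type=Integer,Description=\"Phred-scaled genotype likelihoods\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", table$individuals), collapse = "\t")
  ), con)
  gts <- c("0/0", "0/1", "1/1")
  for (j in seq_len(L)) {
    trip <- lk[, j, ]
    mx <- pmax(trip[, 1], trip[, 2], trip[, 3])
    pl <- round(-10 * log10(pmin(pmax(trip / mx, 1e-300), 1)))
    pl <- pmin(pl, 9999)
    gt <- gts[max.col(trip, ties.method = "first")]
    gt[!table$has_read[, j]] <- "./."
    sample_fields <- paste0(gt, ":", pl[, 1], ",", pl[, 2], ",", pl[, 3])
    writeLines(paste(c(
      table$contig_id[j], pos[j], table$locus_id[j],
      table$ref_allele[j], table$alt_allele[j], ".", "PASS", ".",
      "GT:PL", sample_fields
    ), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read genotype likelihoods from VCF
#'
#' Accepts both the phred-scaled PL dialect and the log10 GL dialect,
#' normalizing each triple to the linear scale (common scaling per cell is
#' irrelevant downstream). Multiallelic records keep their first three
#' likelihood entries and an `n_alt_alleles > 1` flag so that
#' [filter_biallelic()] can drop them. Cells whose likelihood triple is flat
#' (all equal), or with missing PL/GL, are marked as having no read.
#'
#' @param path VCF file path (uncompressed or gzipped).
#' @return A [gl_table()].
#' @export
read_genotype_likelihoods_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- v@fix
  fmt_has <- function(tag) any(grepl(tag, v@gt[, "FORMAT"], fixed = TRUE))
  if (fmt_has("PL")) {
    raw <- vcfR::extract.gt(v, element = "PL")
    to_linear <- function(x) 10^(-x / 10)
  } else if (fmt_has("GL")) {
    raw <- vcfR::extract.gt(v, element = "GL")
    to_linear <- function(x) 10^x
  } else {
    stop("VCF carries neither PL nor GL FORMAT fields")
  }
  L <- nrow(raw)
  n <- ncol(raw)
  lik <- array(1, c(n, L, 3))
  has_read <- matrix(FALSE, n, L)
  for (j in seq_len(L)) {
    parts <- strsplit(raw[j, ], ",", fixed = TRUE)
    for (i in seq_len(n)) {
      p <- suppressWarnings(as.numeric(parts[[i]]))
      if (length(p) >= 3 && all(is.finite(p[1:3]))) {
        trip <- to_linear(p[1:3])
        trip <- trip / max(trip)
        lik[i, j, ] <- trip
        has_read[i, j] <- diff(range(trip)) > 0
      }
    }
  }
  alt <- fx[, "ALT"]
  gl_table(
    likelihoods = lik,
    has_read = has_read,
    contig_id = fx[, "CHROM"],
    locus_id = ifelse(is.na(fx[, "ID"]) | fx[, "ID"] == ".",
      paste0(fx[, "CHROM"], "_", fx[, "POS"]), fx[, "ID"]
    ),
    n_alt_alleles = lengths(strsplit(alt, ",", fixed = TRUE)),
    individuals = colnames(raw),
    ref_allele = fx[, "REF"],
    alt_allele = vapply(strsplit(alt, ",", fixed = TRUE), `[`, character(1), 1)
  )
}

#' Write / read the plain genotype-likelihood table format
#'
#' A TSV with one row per individual and three columns per locus
#' (`<locus>.L0`, `.L1`, `.L2`, linear scale) plus a companion locus CSV
#' (locus, contig, n_alt, ref, alt). A flat likelihood triple marks a cell
#' without reads.
#'
#' @param table a [gl_table()].
#' @param path TSV path for the likelihoods.
#' @param locus_path CSV path for the locus metadata.
#' @export
write_likelihood_table <- function(table, path, locus_path) {
  stopifnot(inherits(table, "gl_table"))
  lk <- table$likelihoods
  n <- n_individuals(table)
  L <- n_loci(table)
  wide <- matrix(aperm(lk, c(1, 3, 2)), n, 3 * L)
  colnames(wide) <- paste0(rep(table$locus_id, each = 3), ".L", 0:2)
  df <- data.frame(individual = table$individuals, wide, check.names = FALSE)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  write.csv(
    data.frame(
      locus = table$locus_id, contig = table$contig_id,
      n_alt = table$n_alt_alleles, ref = table$ref_allele,
      alt = table$alt_allele
    ),
    locus_path,
    row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' @rdname write_likelihood_table
#' @export
read_likelihood_table <- function(path, locus_path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  loci <- read.csv(locus_path, colClasses = c(
    locus = "character", contig = "character"
  ))
  individuals <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  L <- ncol(m) / 3
  if (L != nrow(loci)) stop("likelihood table and locus metadata disagree")
  lik <- aperm(array(m, c(nrow(m), 3, L)), c(1, 3, 2))
  flat <- abs(lik[, , 1] - lik[, , 2]) < 1e-12 & abs(lik[, , 2] - lik[, , 3]) < 1e-12
  gl_table(
    likelihoods = lik,
    has_read = !flat,
    contig_id = loci$contig,
    locus_id = loci$locus,
    n_alt_alleles = loci$n_alt,
    individuals = as.character(individuals),
    ref_allele = loci$ref,
    alt_allele = loci$alt
  )
}

#' Write / read sample metadata
#'
#' CSV with columns individual, lek, complex, lek_lat, lek_lon (plus any
#' projected lek_x / lek_y columns present).
#'
#' @param metadata data.frame as in a `truth_record`'s `metadata`.
#' @param path CSV path.
#' @export
write_metadata_csv <- function(metadata, path) {
  write.csv(metadata, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_metadata_csv
#' @export
read_metadata_csv <- function(path) {
  md <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("individual", "lek", "complex", "lek_lat", "lek_lon")
  missing_cols <- setdiff(need, names(md))
  if (length(missing_cols)) {
    stop("metadata is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  md
}

#' Project latitude/longitude to local planar km coordinates
#'
#' Equirectangular projection about the centroid: x is east-west km, y is
#' north-south km. Adequate for the tens-of-km extents of a lek study area.
#'
#' @param lat,lon numeric degree vectors.
#' @return Matrix with columns x, y (km).
#' @export
project_coords <- function(lat, lon) {
  lat0 <- mean(lat)
  lon0 <- mean(lon)
  cbind(
    x = (lon - lon0) * 111.195 * cos(lat0 * pi / 180),
    y = (lat - lat0) * 111.195
  )
}
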