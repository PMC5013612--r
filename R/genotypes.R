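#' Genotype tables
#'
#' The central container is a `genotype_table`: a samples x SNPs matrix of
#' alt-allele dosages (0, 1, 2 or NA) together with per-SNP metadata
#' (scaffold, 0-based position, alleles, RAD-locus id) and per-sample
#' metadata (population, collection year). The raw VCF GT strings are kept
#' alongside the dosage matrix so that phased haplotypes can be extracted
#' later without re-reading the file.
#'
#' All internal coordinates are 0-based half-open; VCF positions (1-based)
#' are converted on read and restored on write.
#'
#' @name genotype_table
NULL

#' Construct a genotype table
#'
#' @param calls integer matrix (n_samples x n_snps) of alt-allele dosages in
#'   \{0, 1, 2, NA\}.
#' @param snps data.frame with columns snp_id, scaffold, chromosome, pos
#'   (0-based), ref, alt, locus_id.
#' @param samples data.frame with columns sample_id, population, year.
#' @param gt optional character matrix of raw VCF GT strings (same shape as
#'   `calls`), needed for haplotype extraction.
#' @return an object of class `genotype_table`.
#' @export
genotype_table <- function(calls, snps, samples, gt = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (nrow(calls) != nrow(samples) || ncol(calls) != nrow(snps)) {
    stop("calls matrix must be (n_samples x n_snps)")
  }
  if (any(!calls %in% c(0L, 1L, 2L, NA_integer_))) {
    stop("dosages must be 0, 1, 2 or NA")
  }
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample ids")
  if (anyDuplicated(paste(snps$scaffold, snps$pos))) {
    stop("duplicate (scaffold, pos) in SNP table")
  }
  if (any(snps$pos < 0)) stop("SNP positions must be >= 0")
  if (!is.null(gt)) {
    gt <- as.matrix(gt)
    if (!all(dim(gt) == dim(calls))) stop("gt matrix shape mismatch")
  }
  snps$snp_id <- as.character(snps$snp_id)
  if (is.null(snps$chromosome)) snps$chromosome <- NA_character_
  if (is.null(snps$locus_id)) snps$locus_id <- NA_character_
  rownames(calls) <- samples$sample_id
  colnames(calls) <- snps$snp_id
  structure(list(calls = calls, snps = snps, samples = samples, gt = gt),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d samples x %d SNPs (%d scaffolds, %s)\n",
              nrow(x$calls), ncol(x$calls),
              length(unique(x$snps$scaffold)),
              if (is.null(x$gt)) "dosages only" else "GT strings kept"))
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) dim(x$calls)

#' Subset a genotype table
#'
#' @param g genotype table.
#' @param snp_idx logical or integer index over SNPs (default: all).
#' @param sample_idx logical or integer index over samples (default: all).
#' @return subset genotype table.
#' @export
subset_genotypes <- function(g, snp_idx = NULL, sample_idx = NULL) {
  if (is.null(snp_idx)) snp_idx <- seq_len(ncol(g$calls))
  if (is.null(sample_idx)) sample_idx <- seq_len(nrow(g$calls))
  genotype_table(
    calls = g$calls[sample_idx, snp_idx, drop = FALSE],
    snps = g$snps[snp_idx, , drop = FALSE],
    samples = g$samples[sample_idx, , drop = FALSE],
    gt = if (is.null(g$gt)) NULL else g$gt[sample_idx, snp_idx, drop = FALSE]
  )
}

# dosage from a GT string vector; anything with a missing allele -> NA
.gt_to_dosage <- function(gt) {
  gt <- sub(":.*", "", gt)
  a <- substr(gt, 1, 1)
  b <- substr(gt, 3, 3)
  out <- ifelse(a == "." | b == "." | is.na(gt), NA_integer_,
                (a == "1") + (b == "1"))
  as.integer(out)
}

#' Read genotypes from a VCF and a sample metadata file
#'
#' Biallelic SNP records are converted to alt-allele dosages; `./.` becomes
#' NA. Multi-allelic records are skipped (a message reports the count).
#' Phase separators in the GT strings are preserved for later haplotype
#' extraction. RAD-locus ids are taken from an optional `LOC=` INFO key.
#'
#' @param path VCF file (4.x, GT field required).
#' @param metadata_path tab-separated metadata with header
#'   `sample_id  population  year`; every VCF sample must appear.
#' @return a [genotype_table()].
#' @export
read_genotypes <- function(path, metadata_path) {
  meta <- read_sample_metadata(metadata_path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v, getINFO = TRUE),
                       stringsAsFactors = FALSE)
  gt_raw <- vcfR::extract.gt(v, element = "GT", convertNA = FALSE)
  vcf_samples <- colnames(gt_raw)

  missing_meta <- setdiff(vcf_samples, meta$sample_id)
  if (length(missing_meta)) {
    stop("sample(s) in VCF absent from metadata: ",
         paste(missing_meta, collapse = ", "))
  }
  meta <- meta[match(vcf_samples, meta$sample_id), , drop = FALSE]

  biallelic <- !grepl(",", fix$ALT, fixed = TRUE) & fix$ALT != "." &
    nchar(fix$REF) == 1 & nchar(fix$ALT) == 1
  n_skip <- sum(!biallelic)
  if (n_skip > 0) {
    message(n_skip, " non-biallelic record(s) skipped")
  }
  fix <- fix[biallelic, , drop = FALSE]
  gt_raw <- gt_raw[biallelic, , drop = FALSE]

  info <- if ("INFO" %in% colnames(fix)) fix$INFO else rep(NA, nrow(fix))
  loc <- rep(NA_character_, nrow(fix))
  has_loc <- grepl("(^|;)LOC=", info)
  loc[has_loc] <- sub(".*(^|;)LOC=([^;]+).*", "\\2", info[has_loc])

  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[
    is.na(ids) | ids == "."]

  snps <- data.frame(
    snp_id = ids, scaffold = fix$CHROM, chromosome = NA_character_,
    pos = as.numeric(fix$POS) - 1, ref = fix$REF, alt = fix$ALT,
    locus_id = loc, stringsAsFactors = FALSE
  )
  gt_mat <- t(gt_raw)               # samples x snps
  gt_mat[is.na(gt_mat)] <- "./."    # vcfR reads missing GT fields as NA
  calls <- matrix(.gt_to_dosage(gt_mat), nrow = nrow(gt_mat))
  genotype_table(calls, snps, meta, gt = gt_mat)
}

#' Read a sample metadata TSV
#'
#' @param path tab-separated file with header `sample_id  population  year`.
#' @param year_range plausible calendar-year range for validation.
#' @return data.frame of sample records.
#' @export
read_sample_metadata <- function(path, year_range = c(1950, 2100)) {
  meta <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  need <- c("sample_id", "population", "year")
  if (!all(need %in% names(meta))) {
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample ids in metadata")
  if (any(meta$year < year_range[1] | meta$year > year_range[2])) {
    stop("metadata year outside plausible range")
  }
  meta[need]
}

#' Write sample metadata
#' @param samples sample data.frame.
#' @param path output path.
#' @export
write_sample_metadata <- function(samples, path) {
  utils::write.table(samples[c("sample_id", "population", "year")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a scaffold ordering table
#'
#' Tab-separated with header `scaffold  chromosome  rank  length`, giving the
#' assignment of scaffolds to chromosomes, their order within each
#' chromosome, and their lengths in bp.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_scaffold_order <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("scaffold", "chromosome", "rank", "length")
  if (!all(need %in% names(df))) {
    stop("scaffold order table must have columns: ",
         paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$scaffold)) stop("scaffold listed twice")
  df[need]
}

#' Assign chromosomes to SNPs from a scaffold ordering table
#'
#' @param g genotype table.
#' @param scaffold_order data.frame from [read_scaffold_order()].
#' @return genotype table with the `chromosome` column filled (scaffolds not
#'   in the table are left as NA, i.e. unplaced).
#' @export
assign_chromosomes <- function(g, scaffold_order) {
  idx <- match(g$snps$scaffold, scaffold_order$scaffold)
  g$snps$chromosome <- scaffold_order$chromosome[idx]
  g
}

#' Write a genotype table as VCF 4.2
#'
#' GT strings are written verbatim when present (preserving phase),
#' otherwise unphased genotypes are reconstructed from dosages.
#'
#' @param g genotype table.
#' @param path output path (plain text).
#' @export
write_genotypes <- function(g, path) {
  ord <- order(g$snps$scaffold, g$snps$pos)
  snps <- g$snps[ord, , drop = FALSE]
  if (is.null(g$gt)) {
    gt <- matrix(c("0/0", "0/1", "1/1")[g$calls + 1L], nrow = nrow(g$calls))
    gt[is.na(g$calls)] <- "./."
  } else {
    gt <- g$gt
  }
  gt <- gt[, ord, drop = FALSE]
  info <- ifelse(is.na(snps$locus_id), ".",
                 paste0("LOC=", snps$locus_id))
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=LOC,Number=1,Type=String,Description=\"RAD locus id\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", g$samples$sample_id), collapse = "\t")
  )
  body <- paste(snps$scaffold, as.integer(snps$pos) + 1L, snps$snp_id,
                snps$ref, snps$alt, ".", "PASS", info, "GT",
                sep = "\t")
  gt_lines <- apply(gt, 2, paste, collapse = "\t")
  writeLines(c(header, paste(body, gt_lines, sep = "\t")), path)
  invisible(path)
}
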