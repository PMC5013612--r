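#' Phased haplotype sets
#'
#' A `haplotype_set` holds the phased binary haplotypes of one population and
#' time stratum over a single scaffold: a (2 x n_individuals) x n_snps matrix
#' with entries 0, 1 or NA, columns ordered by position. Phasing is taken as
#' given (the simulator emits truth phase; real data are phased upstream).
#'
#' @name haplotype_set
NULL

#' Construct a haplotype set
#'
#' @param h matrix of \{0, 1, NA\}, rows = haplotypes (even count), columns
#'   ordered by increasing position.
#' @param snps SNP metadata restricted to one scaffold, same order as the
#'   columns of `h`.
#' @param stratum label, conventionally "pre" or "post".
#' @param population population label.
#' @return object of class `haplotype_set`.
#' @export
haplotype_set <- function(h, snps, stratum, population = NA_character_) {
  h <- as.matrix(h)
  storage.mode(h) <- "integer"
  if (ncol(h) != nrow(snps)) stop("haplotype/SNP shape mismatch")
  if (nrow(h) %% 2 != 0) stop("haplotype row count must be even")
  if (any(!h %in% c(0L, 1L, NA_integer_))) stop("haplotypes must be 0/1/NA")
  if (length(unique(snps$scaffold)) > 1) {
    stop("a haplotype set spans a single scaffold")
  }
  if (is.unsorted(snps$pos, strictly = TRUE)) {
    stop("SNP positions must be strictly increasing")
  }
  structure(list(h = h, snps = snps, stratum = stratum,
                 population = population),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("haplotype_set: %d haplotypes x %d SNPs (%s, %s, %s)\n",
              nrow(x$h), ncol(x$h), x$population, x$stratum,
              if (nrow(x$snps)) x$snps$scaffold[1] else "empty"))
  invisible(x)
}

# split "0|1" style GT strings of one sample into two allele vectors
.split_phased <- function(gt, sample_id) {
  gt <- sub(":.*", "", gt)
  miss <- is.na(gt) | gt %in% c("./.", ".|.", ".")
  called <- which(!miss)
  if (any(!grepl("|", gt[called], fixed = TRUE))) {
    stop("unphased genotype for sample ", sample_id,
         "; haplotype extraction requires '|' separators")
  }
  a <- rep(NA_integer_, length(gt))
  b <- rep(NA_integer_, length(gt))
  a1 <- substr(gt[called], 1, 1)
  a2 <- substr(gt[called], 3, 3)
  a[called] <- ifelse(a1 == ".", NA_integer_, as.integer(a1 == "1"))
  b[called] <- ifelse(a2 == ".", NA_integer_, as.integer(a2 == "1"))
  list(a, b)
}

#' Extract phased haplotypes for one population, stratum and scaffold
#'
#' Two haplotype rows are produced per individual. Rows with fewer than
#' `min_call_rate` of their sites called are dropped (both rows of an
#' all-missing individual disappear). Remaining missing sites stay NA and are
#' treated as homozygosity-breaking during EHH computation.
#'
#' @param g genotype table carrying raw GT strings.
#' @param population population label to select.
#' @param years calendar years forming the stratum.
#' @param scaffold scaffold name.
#' @param stratum label stored on the result ("pre"/"post").
#' @param min_call_rate minimum fraction of called sites for a haplotype row
#'   to be retained (default 0.3).
#' @return a [haplotype_set()].
#' @export
extract_haplotypes <- function(g, population, years, scaffold,
                               stratum = NA_character_,
                               min_call_rate = 0.3) {
  if (is.null(g$gt)) stop("genotype table has no GT strings; read from VCF")
  samp <- which(g$samples$population == population &
                  g$samples$year %in% years)
  if (length(samp) == 0) stop("no samples for population/stratum")
  snp_idx <- which(g$snps$scaffold == scaffold)
  snp_idx <- snp_idx[order(g$snps$pos[snp_idx])]
  if (length(snp_idx) == 0) stop("no SNPs on scaffold ", scaffold)
  snps <- g$snps[snp_idx, , drop = FALSE]

  rows <- vector("list", 2 * length(samp))
  for (i in seq_along(samp)) {
    ab <- .split_phased(g$gt[samp[i], snp_idx], g$samples$sample_id[samp[i]])
    rows[[2 * i - 1]] <- ab[[1]]
    rows[[2 * i]] <- ab[[2]]
  }
  h <- do.call(rbind, rows)
  call_rate <- rowMeans(!is.na(h))
  keep <- call_rate >= min_call_rate
  # missingness is per genotype, so the two rows of an individual share a
  # call rate; an individual is retained only if both its rows pass
  pair_ok <- keep[seq(1, length(keep), 2)] & keep[seq(2, length(keep), 2)]
  h <- h[rep(pair_ok, each = 2), , drop = FALSE]
  haplotype_set(h, snps, stratum = stratum, population = population)
}
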