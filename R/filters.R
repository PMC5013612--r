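#' SNP filtering
#'
#' Order-explicit, composable filters reproducing a RAD-seq quality-control
#' chain: removal of X-linked scaffolds, of putative confounded paralogues
#' (RAD loci with excess observed heterozygosity), of low call-rate SNPs, and
#' of low minor-allele-frequency SNPs. Each filter returns the reduced table
#' plus a report recording counts and thresholds; reports chain so that
#' `n_after` of one step equals `n_before` of the next.
#'
#' All thresholds are strict as printed: heterozygosity must exceed the
#' cutoff to flag a locus, MAF strictly below the cutoff to drop a SNP,
#' call rate strictly below the minimum fraction to drop a SNP.
#'
#' @name filters
NULL

.filter_report <- function(step, n_before, n_after, params) {
  stopifnot(n_after <= n_before)
  list(step_name = step, n_before = n_before, n_after = n_after,
       params = params)
}

#' Remove SNPs on X-linked scaffolds
#'
#' @param g genotype table.
#' @param x_scaffolds character vector of scaffold names assigned to the X
#'   chromosome.
#' @return list(genotypes, report).
#' @export
filter_x_scaffolds <- function(g, x_scaffolds) {
  keep <- !(g$snps$scaffold %in% x_scaffolds)
  list(genotypes = subset_genotypes(g, snp_idx = keep),
       report = .filter_report("x_scaffolds", length(keep), sum(keep),
                               list(n_x_scaffolds = length(x_scaffolds))))
}

#' Observed heterozygosity per SNP
#'
#' Fraction of called genotypes that are heterozygous; NA when no genotype
#' is called.
#'
#' @param g genotype table.
#' @return numeric vector, one value per SNP.
#' @export
observed_heterozygosity <- function(g) {
  colMeans(g$calls == 1L, na.rm = TRUE)
}

#' Remove RAD loci with excess heterozygosity (confounded paralogues)
#'
#' If any SNP on a RAD locus has observed heterozygosity above `het_max`,
#' every SNP of that locus is removed. SNPs without a locus id are judged
#' individually.
#'
#' @param g genotype table.
#' @param het_max heterozygosity threshold (strict >; default 0.5).
#' @return list(genotypes, report).
#' @export
filter_paralog_loci <- function(g, het_max = 0.5) {
  het <- observed_heterozygosity(g)
  bad_snp <- !is.na(het) & het > het_max
  loc <- g$snps$locus_id
  bad_loci <- unique(loc[bad_snp & !is.na(loc)])
  drop <- bad_snp | (!is.na(loc) & loc %in% bad_loci)
  list(genotypes = subset_genotypes(g, snp_idx = !drop),
       report = .filter_report("paralog_loci", length(drop), sum(!drop),
                               list(het_max = het_max)))
}

#' Remove SNPs with low call rate
#'
#' @param g genotype table.
#' @param min_fraction minimum fraction of the targeted samples in which a
#'   SNP must be called (SNPs strictly below are removed).
#' @param sample_idx optional logical/integer index restricting the samples
#'   over which call rate is computed (e.g. one population or time stratum);
#'   default: all samples.
#' @return list(genotypes, report).
#' @export
filter_call_rate <- function(g, min_fraction, sample_idx = NULL) {
  stopifnot(min_fraction > 0, min_fraction <= 1)
  if (is.null(sample_idx)) sample_idx <- seq_len(nrow(g$calls))
  sub <- g$calls[sample_idx, , drop = FALSE]
  if (nrow(sub) == 0) stop("call-rate filter over an empty sample subset")
  rate <- colMeans(!is.na(sub))
  keep <- rate >= min_fraction
  list(genotypes = subset_genotypes(g, snp_idx = keep),
       report = .filter_report("call_rate", length(keep), sum(keep),
                               list(min_fraction = min_fraction,
                                    n_samples = nrow(sub))))
}

#' Minor allele frequency per SNP
#'
#' Computed over called alleles pooled across the given samples.
#'
#' @param g genotype table.
#' @param sample_idx optional sample subset (default all).
#' @return numeric vector of MAF values (NA where nothing is called).
#' @export
minor_allele_frequency <- function(g, sample_idx = NULL) {
  if (is.null(sample_idx)) sample_idx <- seq_len(nrow(g$calls))
  sub <- g$calls[sample_idx, , drop = FALSE]
  n_called <- colSums(!is.na(sub))
  f <- colSums(sub, na.rm = TRUE) / (2 * n_called)
  f[n_called == 0] <- NA
  pmin(f, 1 - f)
}

#' Remove SNPs with minor allele frequency below a threshold
#'
#' @param g genotype table.
#' @param maf_min threshold (strict <; SNPs with MAF exactly `maf_min` are
#'   retained).
#' @return list(genotypes, report).
#' @export
filter_maf <- function(g, maf_min) {
  stopifnot(maf_min >= 0, maf_min <= 0.5)
  maf <- minor_allele_frequency(g)
  keep <- is.na(maf) | maf >= maf_min
  # SNPs with no called genotype carry no frequency information; they are
  # left to the call-rate filter rather than silently removed here
  list(genotypes = subset_genotypes(g, snp_idx = keep),
       report = .filter_report("maf", length(keep), sum(keep),
                               list(maf_min = maf_min)))
}

#' Run the standard filter chain
#'
#' Applies, in order: X-scaffold removal, paralogue-locus removal, call-rate
#' filtering over all samples, and the MAF filter.
#'
#' @param g genotype table.
#' @param x_scaffolds scaffolds assigned to X (may be empty).
#' @param het_max paralogue heterozygosity cutoff (default 0.5).
#' @param min_call_fraction call-rate minimum over all samples (default 1/3).
#' @param maf_min MAF cutoff (default 0.01).
#' @return list(genotypes, reports = list of filter reports).
#' @export
filter_chain <- function(g, x_scaffolds = character(), het_max = 0.5,
                         min_call_fraction = 1 / 3, maf_min = 0.01) {
  r1 <- filter_x_scaffolds(g, x_scaffolds)
  r2 <- filter_paralog_loci(r1$genotypes, het_max)
  r3 <- filter_call_rate(r2$genotypes, min_call_fraction)
  r4 <- filter_maf(r3$genotypes, maf_min)
  list(genotypes = r4$genotypes,
       reports = list(r1$report, r2$report, r3$report, r4$report))
}
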