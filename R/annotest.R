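#' Annotation randomization test
#'
#' Asks how often a randomly placed pair of regions would contain genes with
#' target functional annotations, as a null reference for the annotation
#' content of observed candidate regions. Each draw samples two distinct
#' SNPs uniformly without replacement, centers a fixed-width window on each
#' (clipped at scaffold ends), and scores the pair.
#'
#' Two scoring criteria are available. The default, lax criterion scores a
#' hit when at least one window of the pair overlaps at least one gene
#' carrying any target term. The strict criterion requires the pair's genes
#' to collectively carry at least two distinct target terms (mirroring an
#' observed pair that contained both an immune-response and a cell-death
#' annotation). Gene membership is any overlap with the window, using the
#' same half-open interval convention as the scan.
#'
#' @name annotest
NULL

#' Region-pair randomization test
#'
#' @param snps data.frame with columns scaffold, pos (>= 2 rows; typically a
#'   genotype table's SNP metadata).
#' @param genes gene annotation data frame (see [read_gene_annotation()]).
#' @param target_terms character vector of GO labels counted as targets.
#' @param n_draws number of random pairs (default 1000).
#' @param width window width in bp centered on each SNP (default 2e5).
#' @param seed optional integer; when given, results are reproducible and
#'   the caller's RNG state is untouched.
#' @param scaffold_lengths optional named vector for right clipping.
#' @param strict use the two-distinct-terms criterion (default FALSE).
#' @return list(n_draws, target_terms, fraction_hit, empirical_p, strict).
#'   `empirical_p` is the fraction of draws meeting or exceeding the
#'   observed pair's criterion, i.e. `fraction_hit` under the chosen
#'   criterion.
#' @export
randomization_test <- function(snps, genes, target_terms, n_draws = 1000,
                               width = 2e5, seed = NULL,
                               scaffold_lengths = NULL, strict = FALSE) {
  if (nrow(snps) < 2) stop("need at least 2 SNPs to draw pairs")
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    }
    set.seed(seed)
  }
  gene_terms <- lapply(genes$go_terms, function(tt) {
    intersect(tt, target_terms)
  })
  n_terms <- lengths(gene_terms)
  # per-scaffold gene lookup keeps each draw cheap
  by_scaf <- split(seq_len(nrow(genes)), genes$scaffold)

  draw_terms <- function(scaf, pos) {
    start <- max(0, pos - width / 2)
    end <- pos + width / 2
    if (!is.null(scaffold_lengths) && !is.na(scaffold_lengths[scaf])) {
      end <- min(end, scaffold_lengths[[scaf]])
    }
    idx <- by_scaf[[scaf]]
    if (is.null(idx)) return(character())
    hit <- idx[genes$start[idx] < end & genes$end[idx] > start &
                 n_terms[idx] > 0]
    unique(unlist(gene_terms[hit]))
  }

  hits <- logical(n_draws)
  for (d in seq_len(n_draws)) {
    pick <- sample.int(nrow(snps), 2)
    terms <- unique(c(draw_terms(snps$scaffold[pick[1]], snps$pos[pick[1]]),
                      draw_terms(snps$scaffold[pick[2]], snps$pos[pick[2]])))
    hits[d] <- if (strict) length(terms) >= 2 else length(terms) >= 1
  }
  frac <- mean(hits)
  list(n_draws = n_draws, target_terms = target_terms,
       fraction_hit = frac, empirical_p = frac, strict = strict)
}
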