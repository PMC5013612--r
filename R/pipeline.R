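#' End-to-end scan pipeline
#'
#' Orchestrates the full temporal selection scan from a single
#' configuration: genotype and metadata input, the filter chain,
#' per-population stratum filtering, LD pruning and allele-frequency-change
#' scanning, cross-population candidate-region intersection, the phased Rsb
#' contrast, the Fisher composite window statistic, the annotation
#' randomization test, and the temporal estimates (Jorde-Ryman Ne, per-SNP
#' selection coefficients, region mean s). Writes per-stage tables plus a
#' JSON manifest of thresholds and SNP counts.
#'
#' @name cli_pipeline
NULL

#' Build a run configuration
#'
#' @param vcf,metadata,scaffold_order,annotation input file paths
#'   (`annotation` may be NULL to skip the randomization test).
#' @param populations named list: for each population, a list with
#'   `pre_years`, `post_years`, `ne` and optionally `min_call_pre` /
#'   `min_call_post` (default 1/3 each).
#' @param x_scaffolds scaffolds to drop as X-linked (default: scaffolds with
#'   chromosome "X" in the ordering table).
#' @param het_max,maf_min,min_call_fraction genome-wide filter thresholds
#'   (defaults 0.5, 0.01, 1/3).
#' @param prune_snps,prune_bp,prune_r2 LD pruning limits (20, 50000, 0.99).
#' @param top_fraction,flank scan parameters (0.025, 1e5).
#' @param window composite window width (1e5).
#' @param rsb_maf,rsb_min_snps Rsb MAF floor (0.05) and minimum SNPs per
#'   scaffold (10).
#' @param generation_time years per generation (2).
#' @param run_rsb,run_composite,run_temporal,run_annotest stage switches.
#' @param n_draws,target_terms randomization-test settings.
#' @param seed RNG seed for the randomization test.
#' @param out_dir optional output directory; when NULL nothing is written.
#' @return a `run_config` list.
#' @export
run_config <- function(vcf, metadata, scaffold_order, annotation = NULL,
                       populations,
                       x_scaffolds = NULL,
                       het_max = 0.5, maf_min = 0.01,
                       min_call_fraction = 1 / 3,
                       prune_snps = 20, prune_bp = 50000, prune_r2 = 0.99,
                       top_fraction = 0.025, flank = 1e5,
                       window = 1e5,
                       rsb_maf = 0.05, rsb_min_snps = 10,
                       generation_time = 2,
                       run_rsb = TRUE, run_composite = TRUE,
                       run_temporal = TRUE, run_annotest = TRUE,
                       n_draws = 1000,
                       target_terms = c("immune response", "cell death",
                                       "cell proliferation"),
                       seed = 1, out_dir = NULL) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Read or write a run configuration as YAML
#'
#' @param path YAML file.
#' @param cfg a `run_config`.
#' @return `read_run_config` returns a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path, precision = 15)
  invisible(path)
}

#' Run the full pipeline
#'
#' @param cfg a [run_config()] or the path to its YAML form.
#' @return list with elements filter chain reports, per-population scan
#'   tables and regions, candidate regions, Rsb tables, composite window
#'   table, annotation randomization result, temporal estimates, and the
#'   manifest.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  g <- read_genotypes(cfg$vcf, cfg$metadata)
  scaf_order <- read_scaffold_order(cfg$scaffold_order)
  g <- assign_chromosomes(g, scaf_order)
  scaffold_lengths <- stats::setNames(scaf_order$length,
                                      scaf_order$scaffold)
  x_scaf <- cfg$x_scaffolds
  if (is.null(x_scaf)) {
    x_scaf <- scaf_order$scaffold[scaf_order$chromosome %in% c("X", "chrX")]
  }

  chain <- filter_chain(g, x_scaffolds = x_scaf, het_max = cfg$het_max,
                        min_call_fraction = cfg$min_call_fraction,
                        maf_min = cfg$maf_min)
  gf <- chain$genotypes

  pops <- names(cfg$populations)
  scans <- list()
  region_lists <- list()
  rsb_tables <- list()
  prune_reports <- list()

  for (p in pops) {
    pc <- cfg$populations[[p]]
    min_pre <- if (!is.null(pc$min_call_pre)) pc$min_call_pre else 1 / 3
    min_post <- if (!is.null(pc$min_call_post)) pc$min_call_post else 1 / 3
    pre_idx <- which(gf$samples$population == p &
                       gf$samples$year %in% pc$pre_years)
    post_idx <- which(gf$samples$population == p &
                        gf$samples$year %in% pc$post_years)
    gp <- filter_call_rate(gf, min_pre, pre_idx)$genotypes
    gp <- filter_call_rate(gp, min_post, post_idx)$genotypes
    pruned <- ld_prune(gp, max_snp_dist = cfg$prune_snps,
                       max_bp = cfg$prune_bp, r2_max = cfg$prune_r2,
                       sample_idx = c(pre_idx, post_idx))
    prune_reports[[p]] <- pruned$report
    scans[[p]] <- scan_population(pruned$genotypes, p,
                                  pc$pre_years, pc$post_years,
                                  top_fraction = cfg$top_fraction,
                                  flank = cfg$flank,
                                  scaffold_lengths = scaffold_lengths)
    region_lists[[p]] <- scans[[p]]$regions

    if (isTRUE(cfg$run_rsb)) {
      rsb_tables[[p]] <- .pipeline_rsb(gf, p, pc, cfg)
    }
  }

  regions <- intersect_populations(
    region_lists, scan_records = lapply(scans, `[[`, "records"),
    flank = cfg$flank
  )

  composite <- NULL
  region_p <- NULL
  if (isTRUE(cfg$run_composite)) {
    stat_tables <- list()
    for (p in pops) {
      rec <- scans[[p]]$records
      stat_tables[[paste0(p, ".afchange")]] <-
        data.frame(scaffold = rec$scaffold, pos = rec$pos,
                   value = rec$delta_abs)
      if (isTRUE(cfg$run_rsb) && !is.null(rsb_tables[[p]]) &&
          nrow(rsb_tables[[p]])) {
        rt <- rsb_tables[[p]]
        # a sweep after the epidemic drives rsb_raw negative; the composite
        # ranks evidence of post-epidemic sweeps, hence the sign flip
        stat_tables[[paste0(p, ".rsb")]] <-
          data.frame(scaffold = rt$scaffold, pos = rt$pos,
                     value = -rt$rsb_std)
      }
    }
    composite <- composite_scan(stat_tables, scaffold_lengths,
                                width = cfg$window)
    if (nrow(regions)) {
      region_p <- region_combined_p(composite, regions)
    }
  }

  annot <- NULL
  genes <- NULL
  if (isTRUE(cfg$run_annotest) && !is.null(cfg$annotation)) {
    genes <- read_gene_annotation(cfg$annotation)
    annot <- randomization_test(
      snps = gf$snps, genes = genes, target_terms = cfg$target_terms,
      n_draws = cfg$n_draws, width = 2 * cfg$flank,
      scaffold_lengths = scaffold_lengths, seed = cfg$seed
    )
  }

  temporal <- NULL
  if (isTRUE(cfg$run_temporal)) {
    temporal <- list(ne = list(), fits = list(), region_s = list())
    for (p in pops) {
      pc <- cfg$populations[[p]]
      gp <- filter_call_rate(
        gf, 1 / 3, which(gf$samples$population == p))$genotypes
      temporal$ne[[p]] <- tryCatch(
        jorde_ryman_ne_genotypes(gp, p, pc$pre_years, pc$post_years,
                                 gen_time = cfg$generation_time),
        error = function(e) NULL, warning = function(w) NULL
      )
      if (nrow(regions)) {
        in_regions <- .iv_overlaps_any(
          data.frame(scaffold = gp$snps$scaffold, start = gp$snps$pos,
                     end = gp$snps$pos + 1), regions)
        gr <- subset_genotypes(gp, snp_idx = in_regions)
        if (ncol(gr$calls) > 0) {
          temporal$fits[[p]] <- estimate_s_genotypes(
            gr, p, years = sort(unique(c(pc$pre_years, pc$post_years))),
            ne = pc$ne, gen_time = cfg$generation_time
          )
          temporal$region_s[[p]] <- lapply(seq_len(nrow(regions)),
            function(k) {
              region_mean_s(temporal$fits[[p]], regions[k, , drop = FALSE])
            })
        }
      }
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("devilscan")),
    thresholds = cfg[c("het_max", "maf_min", "min_call_fraction",
                       "prune_snps", "prune_bp", "prune_r2",
                       "top_fraction", "flank", "window", "rsb_maf",
                       "rsb_min_snps", "generation_time", "seed")],
    n_snps_input = ncol(g$calls),
    filter_chain = chain$reports,
    prune = prune_reports,
    n_candidate_regions = nrow(regions),
    region_combined_p = region_p
  )

  result <- list(genotypes_filtered = gf, scans = scans,
                 regions = regions, rsb = rsb_tables,
                 composite = composite, region_combined_p = region_p,
                 annotation_test = annot, temporal = temporal,
                 manifest = manifest)

  if (!is.null(cfg$out_dir)) .write_pipeline_outputs(result, cfg)
  result
}

# Rsb for one population: stratum call-rate and scaffold-size filters, then
# haplotype extraction and the pooled standardized contrast
.pipeline_rsb <- function(gf, p, pc, cfg) {
  pre_idx <- which(gf$samples$population == p &
                     gf$samples$year %in% pc$pre_years)
  post_idx <- which(gf$samples$population == p &
                      gf$samples$year %in% pc$post_years)
  gp <- filter_call_rate(gf, 1 / 3, pre_idx)$genotypes
  gp <- filter_call_rate(gp, 1 / 3, post_idx)$genotypes
  counts <- table(gp$snps$scaffold)
  big <- names(counts)[counts >= cfg$rsb_min_snps]
  pre_sets <- list()
  post_sets <- list()
  for (scaf in big) {
    pre_h <- tryCatch(
      extract_haplotypes(gp, p, pc$pre_years, scaf, stratum = "pre"),
      error = function(e) NULL)
    post_h <- tryCatch(
      extract_haplotypes(gp, p, pc$post_years, scaf, stratum = "post"),
      error = function(e) NULL)
    if (is.null(pre_h) || is.null(post_h)) next
    if (nrow(pre_h$h) < 4 || nrow(post_h$h) < 4) next
    pre_sets[[scaf]] <- pre_h
    post_sets[[scaf]] <- post_h
  }
  if (!length(pre_sets)) return(NULL)
  suppressMessages(rsb(pre_sets, post_sets, maf_min = cfg$rsb_maf))
}

.write_pipeline_outputs <- function(result, cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$out_dir, f)
  for (p in names(result$scans)) {
    utils::write.table(result$scans[[p]]$records,
                       out(sprintf("scan_%s.tsv", p)), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(result$rsb[[p]])) {
      utils::write.table(result$rsb[[p]], out(sprintf("rsb_%s.tsv", p)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  if (nrow(result$regions)) {
    write_intervals(result$regions[c("scaffold", "start", "end")],
                    out("candidate_regions.bed"))
  } else {
    writeLines(character(), out("candidate_regions.bed"))
  }
  if (!is.null(result$composite)) {
    utils::write.table(result$composite, out("composite_windows.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- result$manifest
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, force = TRUE)
  invisible(NULL)
}
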