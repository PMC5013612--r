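#' Forward Wright-Fisher simulator with linked selection
#'
#' Generates temporally sampled, multi-population SNP datasets with known
#' ground truth, emulating the structure of a RAD-seq temporal selection
#' study: several small populations drawing on shared standing variation, a
#' selected standing variant with linked neutral markers under
#' recombination, sparse marker density, pre- and post-epidemic samples, and
#' heavy per-genotype missingness.
#'
#' The model: an ancestral diploid pool evolves neutrally for a burn-in
#' period (building linkage disequilibrium from an initially
#' linkage-equilibrium pool; no new mutations, so all variation is
#' standing). Each population is then founded from the pool and iterates
#' discrete Wright-Fisher generations - multiplicative (genic) selection at
#' one selected site once its epidemic starts, crossover recombination
#' between adjacent markers with probability min(0.5, rate x distance), free
#' recombination across scaffold boundaries. Diploid individuals are sampled
#' without replacement at scheduled years and genotypes are masked i.i.d. to
#' mimic RAD-seq missingness.
#'
#' @name synthetic_data
NULL

#' Simulation configuration
#'
#' Defaults mirror the study design that motivates the package: three
#' populations with effective sizes 34, 37 and 26, a 2-year generation time,
#' roughly one SNP per 33 kb, a shared standing variant near frequency 0.2
#' under strong selection (s = 0.5) after each population's epidemic starts,
#' about 4-6 generations between the pre and post samples, and per-genotype
#' call rates of roughly 55-70%. The genome itself is scaled down (30
#' scaffolds of 1.5 Mb) so that replicated simulations are cheap.
#'
#' @param n_scaffolds,scaffold_length genome layout (defaults 30 x 1.5 Mb).
#' @param snp_spacing mean SNP spacing in bp (default 33000).
#' @param populations character vector of population names.
#' @param ne effective diploid sizes per population (defaults 34, 37, 26).
#' @param ancestral_ne diploid size of the shared ancestral pool (50; small,
#'   reflecting the very low genome-wide diversity and long-range LD of the
#'   study system).
#' @param burnin_generations neutral burn-in generations (25).
#' @param epidemic_years per-population year the epidemic (selection)
#'   starts; each population is founded from the shared ancestral pool at
#'   this year, so the standing variant enters every sweep at the pool
#'   frequency.
#' @param sampling per-population list of list(year, n) sampling events;
#'   years must map to whole generations after the population's epidemic
#'   year.
#' @param generation_time years per generation (2).
#' @param sel_coeff per-population selection coefficient of the favored
#'   allele (default 0.5 everywhere; 0 gives a neutral genome).
#' @param selected_scaffold,selected_pos where the selected SNP is placed
#'   (the nearest simulated SNP is used).
#' @param p0_selected target standing frequency of the favored allele at
#'   the end of burn-in (0.2); the SNP nearest `selected_pos` with minor
#'   frequency within 0.05 of the target is chosen.
#' @param recomb_rate per-bp per-generation crossover rate (1e-8).
#' @param missing_rate per-population per-genotype missingness
#'   probabilities (defaults 0.31, 0.44, 0.36).
#' @param gene_spacing,gene_length annotation layout (one gene every 150 kb,
#'   20 kb long).
#' @param p_target_term probability a gene carries a target GO term
#'   (default 0.095, which makes about a quarter of random region pairs
#'   contain a target-term gene under the default gene layout).
#' @param target_terms GO labels treated as targets.
#' @param ensure_selected_gene place target-term genes inside the selected
#'   region (TRUE).
#' @param phased write phased ("|") GT strings (TRUE).
#' @param seed integer RNG seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_scaffolds = 30, scaffold_length = 1.5e6,
                       snp_spacing = 33000,
                       populations = c("Freycinet", "Narawntapu",
                                       "WestPencilPine"),
                       ne = c(34, 37, 26),
                       ancestral_ne = 50, burnin_generations = 25,
                       epidemic_years = c(2000, 2002, 2004),
                       sampling = NULL,
                       generation_time = 2,
                       sel_coeff = c(0.5, 0.5, 0.5),
                       selected_scaffold = 1, selected_pos = 1e6,
                       p0_selected = 0.2,
                       recomb_rate = 1e-8,
                       missing_rate = c(0.31, 0.44, 0.36),
                       gene_spacing = 1.5e5, gene_length = 2e4,
                       p_target_term = 0.095,
                       target_terms = c("immune response", "cell death",
                                        "cell proliferation"),
                       ensure_selected_gene = TRUE,
                       phased = TRUE, seed = 1) {
  n_pop <- length(populations)
  if (is.null(sampling)) {
    # pre sample at epidemic onset; post stratum combines two collection
    # years, as temporal studies do to raise stratum sample sizes
    post_years <- list(c(2012, 2014), c(2010, 2012), c(2012, 2014))
    sampling <- lapply(seq_len(n_pop), function(i) {
      n_tp <- min(25, ne[i])
      c(list(list(year = epidemic_years[i], n = n_tp)),
        lapply(post_years[[i]], function(y) list(year = y, n = n_tp)))
    })
    names(sampling) <- populations
  }
  cfg <- list(
    n_scaffolds = n_scaffolds, scaffold_length = scaffold_length,
    snp_spacing = snp_spacing, populations = populations,
    ne = rep_len(ne, n_pop), ancestral_ne = ancestral_ne,
    burnin_generations = burnin_generations,
    epidemic_years = rep_len(epidemic_years, n_pop),
    sampling = sampling, generation_time = generation_time,
    sel_coeff = rep_len(sel_coeff, n_pop),
    selected_scaffold = selected_scaffold, selected_pos = selected_pos,
    p0_selected = p0_selected, recomb_rate = recomb_rate,
    missing_rate = rep_len(missing_rate, n_pop),
    gene_spacing = gene_spacing, gene_length = gene_length,
    p_target_term = p_target_term, target_terms = target_terms,
    ensure_selected_gene = ensure_selected_gene,
    phased = phased, seed = seed
  )
  stopifnot(all(cfg$ne > 0), cfg$ancestral_ne > 0,
            cfg$scaffold_length > 0, cfg$generation_time > 0)
  for (i in seq_len(n_pop)) {
    yrs <- vapply(cfg$sampling[[i]], `[[`, numeric(1), "year")
    g <- (yrs - cfg$epidemic_years[i]) / cfg$generation_time
    if (any(g != round(g)) || any(g < 0)) {
      stop("sampling years must map to whole generations after the ",
           "population's epidemic year")
    }
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Deterministic genic-selection trajectory
#'
#' Iterates p' = p(1+s)/(1+ps) with no drift.
#'
#' @param p0 starting frequency in \[0, 1\].
#' @param s selection coefficient.
#' @param generations number of steps.
#' @return numeric vector of length generations + 1 (including p0).
#' @export
expected_trajectory <- function(p0, s, generations) {
  stopifnot(p0 >= 0, p0 <= 1, generations >= 0)
  p <- numeric(generations + 1)
  p[1] <- p0
  for (g in seq_len(generations)) {
    p[g + 1] <- p[g] * (1 + s) / (1 + p[g] * s)
  }
  p
}

# one generation: m gametes from a (2N x L) pool; w = per-individual
# fitness; rprob = crossover probability between adjacent columns
.make_gametes <- function(pool, w, m, rprob) {
  n_ind <- nrow(pool) / 2
  par <- sample.int(n_ind, m, replace = TRUE,
                    prob = if (is.null(w)) NULL else w)
  A <- pool[2 * par - 1, , drop = FALSE]
  B <- pool[2 * par, , drop = FALSE]
  L <- ncol(pool)
  if (L > 1) {
    X <- matrix(stats::runif(m * (L - 1)) <
                  matrix(rprob, m, L - 1, byrow = TRUE), m, L - 1)
    cc <- matrix(0L, m, L)
    acc <- integer(m)
    for (j in 2:L) {
      acc <- acc + X[, j - 1]
      cc[, j] <- acc
    }
    choice <- (matrix(stats::rbinom(m, 1, 0.5), m, L) + cc) %% 2
  } else {
    choice <- matrix(stats::rbinom(m, 1, 0.5), m, 1)
  }
  gam <- A
  gam[choice == 1] <- B[choice == 1]
  gam
}

#' Run the forward simulation
#'
#' @param cfg a [sim_config()].
#' @return list with elements
#'   `genotypes` (a [genotype_table()] with phased GT strings),
#'   `genes` (annotation data frame as from [read_gene_annotation()]),
#'   `scaffold_order` (scaffold/chromosome/rank/length table),
#'   `truth` (selected SNP, selected interval, per-population selected-site
#'   trajectories, and per-generation allele-frequency records).
#' @export
simulate_dataset <- function(cfg) {
  set.seed(cfg$seed)
  scafs <- sprintf("scaffold_%02d", seq_len(cfg$n_scaffolds))

  # candidate marker positions: Poisson process at three times the target
  # density; after burn-in the panel is thinned back to `snp_spacing` among
  # sites still segregating, so the emitted dataset has the intended
  # density of usable markers
  raw_spacing <- cfg$snp_spacing / 3
  pos_list <- lapply(scafs, function(s) {
    p <- cumsum(stats::rexp(ceiling(2 * cfg$scaffold_length / raw_spacing),
                            rate = 1 / raw_spacing))
    sort(unique(round(p[p < cfg$scaffold_length])))
  })
  scaffold <- rep(scafs, lengths(pos_list))
  pos <- unlist(pos_list)
  L <- length(pos)

  # crossover probabilities between adjacent markers; 0.5 across scaffolds
  rprob <- numeric(max(L - 1, 0))
  if (L > 1) {
    same <- scaffold[-1] == scaffold[-L]
    rprob <- ifelse(same, pmin(0.5, cfg$recomb_rate * diff(pos)), 0.5)
  }

  # ancestral pool at linkage equilibrium, then neutral burn-in; minor
  # allele frequencies follow a neutral-like SFS (density ~ 1/p) so most
  # standing variants are rare, as in real SNP panels
  u <- stats::runif(L)
  minor0 <- 0.02 * (0.5 / 0.02)^u
  flip <- stats::runif(L) < 0.5
  p_init <- ifelse(flip, 1 - minor0, minor0)
  pool <- matrix(stats::rbinom(2 * cfg$ancestral_ne * L, 1,
                               rep(p_init, each = 2 * cfg$ancestral_ne)),
                 nrow = 2 * cfg$ancestral_ne)
  for (g in seq_len(cfg$burnin_generations)) {
    pool <- .make_gametes(pool, NULL, 2 * cfg$ancestral_ne, rprob)
  }
  pool_freq <- colMeans(pool)

  # thin to the target marker density among sites that survived burn-in
  n_target <- round(cfg$n_scaffolds * cfg$scaffold_length /
                      cfg$snp_spacing)
  elig <- which(pmin(pool_freq, 1 - pool_freq) >= 0.02)
  if (length(elig) > n_target) elig <- sort(sample(elig, n_target))
  pool <- pool[, elig, drop = FALSE]
  pool_freq <- pool_freq[elig]
  scaffold <- scaffold[elig]
  pos <- pos[elig]
  L <- length(pos)
  if (L > 1) {
    same <- scaffold[-1] == scaffold[-L]
    rprob <- ifelse(same, pmin(0.5, cfg$recomb_rate * diff(pos)), 0.5)
  } else {
    rprob <- numeric(0)
  }

  # pick the selected SNP: nearest to the configured position with minor
  # frequency within 0.1 of the target standing frequency
  on_scaf <- which(scaffold == scafs[cfg$selected_scaffold])
  minor <- pmin(pool_freq, 1 - pool_freq)
  cand <- on_scaf[abs(minor[on_scaf] - cfg$p0_selected) <= 0.05]
  sel_idx <- if (length(cand)) {
    cand[which.min(abs(pos[cand] - cfg$selected_pos))]
  } else {
    on_scaf[which.min(abs(minor[on_scaf] - cfg$p0_selected))]
  }
  # the favored allele is whichever allele sits near the target frequency
  favored <- if (abs(pool_freq[sel_idx] - cfg$p0_selected) <=
                 abs(1 - pool_freq[sel_idx] - cfg$p0_selected)) 1L else 0L

  n_pop <- length(cfg$populations)
  sample_rows <- list()
  meta_rows <- list()
  trajectories <- vector("list", n_pop)
  names(trajectories) <- cfg$populations
  freq_records <- vector("list", n_pop)
  names(freq_records) <- cfg$populations

  for (i in seq_len(n_pop)) {
    ne <- cfg$ne[i]
    s <- cfg$sel_coeff[i]
    pop <- .make_gametes(pool, NULL, 2 * ne, rprob)  # founders
    sched <- cfg$sampling[[i]]
    yrs <- vapply(sched, `[[`, numeric(1), "year")
    ns <- vapply(sched, `[[`, numeric(1), "n")
    if (any(ns > ne)) {
      stop("sample size exceeds the population size at a time point")
    }
    gens <- (yrs - cfg$epidemic_years[i]) / cfg$generation_time
    last_gen <- max(gens)
    traj <- numeric(last_gen + 1)
    freqs <- matrix(NA_real_, last_gen + 1, L)
    record <- function(gen, pop_mat) {
      f <- colMeans(pop_mat)
      freqs[gen + 1, ] <<- f
      traj[gen + 1] <<- if (favored == 1L) f[sel_idx] else 1 - f[sel_idx]
    }
    record(0, pop)
    take_sample <- function(gen, pop_mat) {
      for (k in which(gens == gen)) {
        ids <- sample.int(ne, ns[k])
        rows <- as.vector(rbind(2 * ids - 1, 2 * ids))
        sample_rows[[length(sample_rows) + 1]] <<- pop_mat[rows, ,
                                                           drop = FALSE]
        meta_rows[[length(meta_rows) + 1]] <<- data.frame(
          sample_id = sprintf("%s_%d_e%d_%03d", cfg$populations[i],
                              yrs[k], k, seq_len(ns[k])),
          population = cfg$populations[i], year = yrs[k],
          stringsAsFactors = FALSE
        )
      }
    }
    take_sample(0, pop)
    if (last_gen >= 1) {
      for (gen in seq_len(last_gen)) {
        w <- if (s != 0) {
          dos <- pop[seq(1, 2 * ne, 2), sel_idx] + pop[seq(2, 2 * ne, 2),
                                                       sel_idx]
          if (favored == 0L) dos <- 2 - dos
          (1 + s)^dos
        } else NULL
        pop <- .make_gametes(pop, w, 2 * ne, rprob)
        record(gen, pop)
        take_sample(gen, pop)
      }
    }
    trajectories[[i]] <- traj
    freq_records[[i]] <- freqs
  }

  meta <- do.call(rbind, meta_rows)
  hap <- do.call(rbind, sample_rows)
  n_samp <- nrow(meta)
  a <- hap[seq(1, 2 * n_samp, 2), , drop = FALSE]
  b <- hap[seq(2, 2 * n_samp, 2), , drop = FALSE]

  # per-genotype missingness, i.i.d. within each population
  miss_rate <- cfg$missing_rate[match(meta$population, cfg$populations)]
  miss <- matrix(stats::runif(n_samp * L) < miss_rate, n_samp, L)
  sep <- if (cfg$phased) "|" else "/"
  gt <- matrix(paste0(a, sep, b), n_samp, L)
  gt[miss] <- "./."
  calls <- a + b
  calls[miss] <- NA_integer_

  snps <- data.frame(
    snp_id = sprintf("snp_%05d", seq_len(L)), scaffold = scaffold,
    chromosome = NA_character_, pos = pos, ref = "A", alt = "C",
    locus_id = sprintf("loc_%05d", seq_len(L)), stringsAsFactors = FALSE
  )
  g <- genotype_table(calls, snps, meta, gt = gt)

  scaffold_order <- data.frame(
    scaffold = scafs,
    chromosome = paste0("chr", ((seq_along(scafs) - 1) %% 3) + 1),
    rank = seq_along(scafs), length = cfg$scaffold_length,
    stringsAsFactors = FALSE
  )
  g <- assign_chromosomes(g, scaffold_order)

  genes <- .simulate_annotation(cfg, scafs, pos[sel_idx],
                                scafs[cfg$selected_scaffold])
  truth <- list(
    selected_snp = snps$snp_id[sel_idx],
    selected_scaffold = scaffold[sel_idx],
    selected_pos = pos[sel_idx],
    selected_interval = intervals(scaffold[sel_idx],
                                  max(0, pos[sel_idx] - 1e5),
                                  min(cfg$scaffold_length,
                                      pos[sel_idx] + 1e5)),
    favored_allele = favored,
    p0_realized = if (favored == 1L) pool_freq[sel_idx] else
      1 - pool_freq[sel_idx],
    sel_coeff = cfg$sel_coeff,
    ne = cfg$ne,
    trajectories = trajectories,
    freq_records = freq_records,
    ancestral_haplotypes = pool
  )
  list(genotypes = g, genes = genes, scaffold_order = scaffold_order,
       truth = truth)
}

# gene annotation tiling with configurable target-term density
.simulate_annotation <- function(cfg, scafs, sel_pos, sel_scaf) {
  rows <- list()
  gid <- 0
  for (s in scafs) {
    starts <- seq(0, cfg$scaffold_length - cfg$gene_length,
                  by = cfg$gene_spacing)
    for (st in starts) {
      gid <- gid + 1
      has_target <- stats::runif(1) < cfg$p_target_term
      terms <- if (has_target) {
        sample(cfg$target_terms, 1)
      } else {
        "housekeeping"
      }
      rows[[gid]] <- data.frame(
        scaffold = s, start = st, end = st + cfg$gene_length,
        gene_id = sprintf("gene_%04d", gid), stringsAsFactors = FALSE
      )
      rows[[gid]]$go_terms <- list(terms)
    }
  }
  genes <- do.call(rbind, rows)
  if (cfg$ensure_selected_gene) {
    on_sel <- which(genes$scaffold == sel_scaf)
    near <- on_sel[which.min(abs((genes$start[on_sel] +
                                    genes$end[on_sel]) / 2 - sel_pos))]
    genes$go_terms[[near]] <- c("immune response", "cell death")
    # keep the gene inside the selected interval
    genes$start[near] <- max(0, sel_pos - cfg$gene_length / 2)
    genes$end[near] <- genes$start[near] + cfg$gene_length
  }
  genes
}

#' Write a simulated dataset to disk
#'
#' Emits a plain-text VCF 4.2 with phased GT, a metadata TSV, a scaffold
#' ordering TSV, a BED6+ gene annotation and a JSON truth file.
#'
#' @param sim output of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return named character vector of file paths.
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    vcf = file.path(dir, "genotypes.vcf"),
    metadata = file.path(dir, "samples.tsv"),
    scaffold_order = file.path(dir, "scaffolds.tsv"),
    annotation = file.path(dir, "genes.bed"),
    truth = file.path(dir, "truth.json")
  )
  write_genotypes(sim$genotypes, paths["vcf"])
  write_sample_metadata(sim$genotypes$samples, paths["metadata"])
  utils::write.table(sim$scaffold_order, paths["scaffold_order"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_gene_annotation(sim$genes, paths["annotation"])
  truth <- sim$truth
  # bulky; regenerate by re-running the seed
  truth$freq_records <- NULL
  truth$ancestral_haplotypes <- NULL
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Simulate independent allele-frequency trajectories
#'
#' Unlinked loci under pure Wright-Fisher drift plus genic selection, with
#' binomial sampling of alleles at scheduled generations. Used for
#' calibrating the temporal estimators.
#'
#' @param n_loci number of independent loci.
#' @param ne effective number of diploids.
#' @param s selection coefficient (applied to every locus).
#' @param times sampling times in generations (first must be 0).
#' @param n_alleles alleles sampled per locus per time point (scalar or
#'   vector along `times`).
#' @param p0 initial frequencies (scalar, or vector along loci, or NULL to
#'   draw from U(0.1, 0.9)).
#' @return list(alt_counts = loci x times matrix, totals, p_true = latent
#'   frequencies at each time).
#' @export
simulate_trajectories <- function(n_loci, ne, s, times, n_alleles,
                                  p0 = NULL) {
  stopifnot(times[1] == 0, !is.unsorted(times, strictly = TRUE))
  if (is.null(p0)) p0 <- stats::runif(n_loci, 0.1, 0.9)
  p0 <- rep_len(p0, n_loci)
  n_alleles <- rep_len(n_alleles, length(times))
  n2 <- 2 * ne
  p <- p0
  counts <- matrix(0L, n_loci, length(times))
  ptrue <- matrix(0, n_loci, length(times))
  for (k in seq_along(times)) {
    if (k > 1) {
      for (g in seq_len(times[k] - times[k - 1])) {
        psel <- p * (1 + s) / (1 + p * s)
        p <- stats::rbinom(n_loci, n2, psel) / n2
      }
    }
    ptrue[, k] <- p
    counts[, k] <- stats::rbinom(n_loci, n_alleles[k], p)
  }
  list(alt_counts = counts,
       totals = matrix(rep(n_alleles, each = n_loci), n_loci),
       p_true = ptrue)
}
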