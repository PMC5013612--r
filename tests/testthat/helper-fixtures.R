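# In-code fixtures and independent oracles shared across test files.

# genotype table from a dosage matrix; one scaffold unless given
toy_genotypes <- function(calls, pos = NULL, scaffold = NULL,
                          locus_id = NULL, populations = NULL,
                          years = NULL, gt = NULL) {
  n <- nrow(calls); m <- ncol(calls)
  if (is.null(pos)) pos <- seq(0, by = 1000, length.out = m)
  if (is.null(scaffold)) scaffold <- rep("sc1", m)
  if (is.null(populations)) populations <- rep("popA", n)
  if (is.null(years)) years <- rep(2000, n)
  snps <- data.frame(
    snp_id = sprintf("s%03d", seq_len(m)), scaffold = scaffold,
    chromosome = NA_character_, pos = pos, ref = "A", alt = "C",
    locus_id = if (is.null(locus_id)) NA_character_ else locus_id,
    stringsAsFactors = FALSE
  )
  samples <- data.frame(
    sample_id = sprintf("ind%03d", seq_len(n)),
    population = populations, year = years, stringsAsFactors = FALSE
  )
  genotype_table(calls, snps, samples, gt = gt)
}

# haplotype set from a 0/1/NA matrix
toy_haplotypes <- function(h, pos = NULL, stratum = "pre",
                           scaffold = "sc1") {
  m <- ncol(h)
  if (is.null(pos)) pos <- seq(0, by = 1000, length.out = m)
  snps <- data.frame(
    snp_id = sprintf("s%03d", seq_len(m)), scaffold = scaffold,
    chromosome = NA_character_, pos = pos, ref = "A", alt = "C",
    locus_id = NA_character_, stringsAsFactors = FALSE
  )
  haplotype_set(h, snps, stratum = stratum)
}

# a small hand-readable VCF: 3 samples x 3 records (one multi-allelic)
write_toy_vcf <- function(dir = tempfile("vcf")) {
  dir.create(dir)
  vcf <- file.path(dir, "toy.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "sampA", "sampB", "sampC", sep = "\t"),
    paste("sc1", "101", "snp1", "A", "C", ".", "PASS", "LOC=l1", "GT",
          "0|1", "1|1", "./.", sep = "\t"),
    paste("sc1", "5001", "snp2", "G", "T", ".", "PASS", "LOC=l2", "GT",
          "0|0", "0|1", "1|1", sep = "\t"),
    paste("sc1", "9001", "bad", "G", "T,A", ".", "PASS", ".", "GT",
          "0/1", "0/2", "1/1", sep = "\t")
  ), vcf)
  meta <- file.path(dir, "meta.tsv")
  writeLines(c("sample_id\tpopulation\tyear",
               "sampA\tpopA\t2000", "sampB\tpopA\t2000",
               "sampC\tpopB\t2010"), meta)
  list(vcf = vcf, metadata = meta)
}

# O(n^2 L) pairwise-identity EHHS oracle; NA breaks identity for the pair
brute_ehhs <- function(H, pos, focal) {
  n <- nrow(H)
  hh_int <- function(cols) {
    cnt <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      a <- H[i, cols]; b <- H[j, cols]
      if (!anyNA(a) && !anyNA(b) && all(a == b)) cnt <- cnt + 1
    }
    2 * cnt / (n * (n - 1))
  }
  h0 <- hh_int(focal)
  vapply(seq_along(pos), function(x) {
    cols <- if (x <= focal) x:focal else focal:x
    hh_int(cols) / h0
  }, numeric(1))
}

# exhaustive hidden-path likelihood for tiny Wright-Fisher HMMs
brute_wf_loglik <- function(traj, s, ne) {
  n2 <- 2 * ne
  states <- 0:n2
  trans <- wf_transition_matrix(ne, s)
  gaps <- diff(traj$times)
  step <- lapply(gaps, function(g) {
    M <- diag(n2 + 1)
    for (k in seq_len(g)) M <- M %*% trans
    M
  })
  emis <- function(i, k) {
    stats::dbinom(traj$alt_counts[i], traj$totals[i], k / n2)
  }
  paths <- do.call(expand.grid, rep(list(states), length(traj$times)))
  tot <- 0
  for (r in seq_len(nrow(paths))) {
    k <- as.numeric(paths[r, ])
    pr <- (1 / (n2 + 1)) * emis(1, k[1])
    for (i in seq_along(gaps)) {
      pr <- pr * step[[i]][k[i] + 1, k[i + 1] + 1] * emis(i + 1, k[i + 1])
    }
    tot <- tot + pr
  }
  log(tot)
}

# per-bp membership oracle for interval intersection (small fixtures only)
brute_intersect <- function(interval_lists, scaffolds, max_len) {
  out <- NULL
  for (scaf in scaffolds) {
    cover <- rep(TRUE, max_len)
    for (df in interval_lists) {
      c1 <- rep(FALSE, max_len)
      sub <- df[df$scaffold == scaf, , drop = FALSE]
      for (r in seq_len(nrow(sub))) {
        if (sub$end[r] >= 1) {
          c1[(sub$start[r] + 1):min(sub$end[r], max_len)] <- TRUE
        }
      }
      cover <- cover & c1
    }
    if (any(cover)) {
      rr <- rle(cover)
      ends <- cumsum(rr$lengths)
      starts <- ends - rr$lengths
      keep <- rr$values
      out <- rbind(out, data.frame(scaffold = scaf, start = starts[keep],
                                   end = ends[keep]))
    }
  }
  if (is.null(out)) intervals() else out[order(out$scaffold, out$start), ]
}

# standard per-population stratum setup used by pipeline-level tests
default_pop_strata <- function() {
  list(Freycinet = list(pre = 2000, post = c(2012, 2014)),
       Narawntapu = list(pre = 2002, post = c(2010, 2012)),
       WestPencilPine = list(pre = 2004, post = c(2012, 2014)))
}

# scan + cross-population intersection on a simulated dataset; returns the
# per-population merged windows and the intersected candidate regions
run_scan_stages <- function(sim) {
  gf <- filter_chain(sim$genotypes)$genotypes
  lens <- stats::setNames(sim$scaffold_order$length,
                          sim$scaffold_order$scaffold)
  strata <- default_pop_strata()
  region_lists <- list()
  panel <- list()
  sel_frac <- c()
  for (p in names(strata)) {
    pre_idx <- which(gf$samples$population == p &
                       gf$samples$year %in% strata[[p]]$pre)
    post_idx <- which(gf$samples$population == p &
                        gf$samples$year %in% strata[[p]]$post)
    gp <- filter_call_rate(gf, 1 / 3, pre_idx)$genotypes
    gp <- filter_call_rate(gp, 1 / 3, post_idx)$genotypes
    pr <- ld_prune(gp, sample_idx = c(pre_idx, post_idx))
    sc <- scan_population(pr$genotypes, p, strata[[p]]$pre,
                          strata[[p]]$post, scaffold_lengths = lens)
    region_lists[[p]] <- sc$regions
    rec <- sc$records[!is.na(sc$records$quantile), ]
    panel[[p]] <- rec[c("scaffold", "pos")]
    sel_frac <- c(sel_frac, mean(rec$selected))
  }
  list(region_lists = region_lists,
       regions = intersect_populations(region_lists),
       panel = panel, sel_frac = sel_frac,
       scaffold_lengths = lens,
       genome_bp = sum(sim$scaffold_order$length))
}

overlaps_truth <- function(regions, sim) {
  nrow(regions) > 0 &&
    any(suppressWarnings(
      devilscan:::.iv_overlaps_any(regions, sim$truth$selected_interval)))
}
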