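#' Allele-frequency-change scan
#'
#' Per-population scan for SNPs whose allele frequency changed most between a
#' pre-epidemic and a post-epidemic time stratum. SNPs are LD-pruned,
#' ranked by absolute frequency change, and a flanking window is drawn
#' around each SNP in the top quantile; candidate regions are where the
#' merged windows of every population overlap.
#'
#' Empirical quantiles use the mid-rank convention rank/(N+1) with ties
#' averaged, so quantiles are strictly inside (0, 1) and downstream log
#' transforms stay finite.
#'
#' @name afchange
NULL

#' Alt-allele frequencies
#'
#' @param g genotype table.
#' @param sample_idx optional sample subset (default all).
#' @return numeric vector: (sum of dosages) / (2 x called genotypes); NA for
#'   SNPs with no called genotype in the subset.
#' @export
allele_frequencies <- function(g, sample_idx = NULL) {
  if (is.null(sample_idx)) sample_idx <- seq_len(nrow(g$calls))
  sub <- g$calls[sample_idx, , drop = FALSE]
  if (nrow(sub) == 0) stop("empty sample subset")
  n_called <- colSums(!is.na(sub))
  f <- colSums(sub, na.rm = TRUE) / (2 * n_called)
  f[n_called == 0] <- NA
  unname(f)
}

#' Genotypic LD: squared dosage correlation
#'
#' The unphased genotype-correlation measure of linkage disequilibrium:
#' squared Pearson correlation of alt-allele dosages over jointly called
#' samples.
#'
#' @param a,b integer dosage vectors of equal length (NA = missing).
#' @return r-squared in \[0, 1\], or NA when fewer than two samples are
#'   jointly called or either vector is monomorphic among them.
#' @export
ld_r2_genotypic <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2) return(NA_real_)
  a <- a[ok]; b <- b[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0) return(NA_real_)
  stats::cor(a, b)^2
}

#' LD-prune a genotype table
#'
#' Single left-to-right pass per scaffold over position-sorted SNPs: whenever
#' a retained SNP and a later SNP within `max_snp_dist` SNPs (original
#' ordering) and `max_bp` base pairs have dosage r-squared strictly above
#' `r2_max`, the later SNP is removed (the leftmost member of a violating
#' pair always survives).
#'
#' @param g genotype table.
#' @param max_snp_dist maximum SNP-index separation considered (default 20).
#' @param max_bp maximum bp separation considered (default 50000).
#' @param r2_max r-squared threshold (strict >; default 0.99).
#' @param sample_idx optional sample subset over which r-squared is computed.
#' @return list(genotypes, removed = character vector of removed snp_ids,
#'   report).
#' @export
ld_prune <- function(g, max_snp_dist = 20, max_bp = 50000, r2_max = 0.99,
                     sample_idx = NULL) {
  ord <- order(g$snps$scaffold, g$snps$pos)
  g <- subset_genotypes(g, snp_idx = ord)
  if (is.null(sample_idx)) sample_idx <- seq_len(nrow(g$calls))
  calls <- g$calls[sample_idx, , drop = FALSE]
  n <- ncol(calls)
  removed <- logical(n)
  scaf <- g$snps$scaffold
  pos <- g$snps$pos
  for (i in seq_len(n)) {
    if (removed[i]) next
    j_max <- min(n, i + max_snp_dist)
    for (j in seq_len(j_max - i)) {
      jj <- i + j
      if (scaf[jj] != scaf[i]) break
      if (pos[jj] - pos[i] > max_bp) break
      if (removed[jj]) next
      r2 <- ld_r2_genotypic(calls[, i], calls[, jj])
      if (!is.na(r2) && r2 > r2_max) removed[jj] <- TRUE
    }
  }
  list(genotypes = subset_genotypes(g, snp_idx = !removed),
       removed = g$snps$snp_id[removed],
       report = .filter_report("ld_prune", n, sum(!removed),
                               list(max_snp_dist = max_snp_dist,
                                    max_bp = max_bp, r2_max = r2_max)))
}

#' Mid-rank empirical quantiles
#'
#' rank/(N+1) with ties averaged; values are strictly inside (0, 1).
#'
#' @param x numeric vector (NAs allowed; their quantile is NA).
#' @return numeric vector of quantiles.
#' @export
midrank_quantiles <- function(x) {
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x)
  # collapse floating-point noise so genuine ties (e.g. equal frequency
  # changes computed from relabeled alleles) rank identically
  out[ok] <- rank(signif(x[ok], 12), ties.method = "average") / (sum(ok) + 1)
  out
}

#' Scan one population for extreme allele-frequency change
#'
#' Computes pre- and post-stratum frequencies, ranks SNPs by absolute
#' frequency change, selects the top `top_fraction` by mid-rank quantile,
#' draws a `flank`-bp window on either side of each selected SNP (clipped to
#' scaffold bounds), and merges overlapping windows.
#'
#' @param g genotype table; stratum-specific call-rate filtering and LD
#'   pruning are expected to have been applied already.
#' @param population population label.
#' @param pre_years,post_years calendar years forming the two strata.
#' @param top_fraction selected upper tail of |delta| (default 0.025).
#' @param flank half-window in bp (default 1e5).
#' @param scaffold_lengths optional named vector of scaffold lengths used to
#'   clip windows on the right; windows are always clipped at 0.
#' @return list(records = per-SNP data.frame with freq_pre, freq_post,
#'   delta_signed, delta_abs, quantile, selected; regions = merged interval
#'   data.frame of windows around selected SNPs).
#' @export
scan_population <- function(g, population, pre_years, post_years,
                            top_fraction = 0.025, flank = 1e5,
                            scaffold_lengths = NULL) {
  pre_idx <- which(g$samples$population == population &
                     g$samples$year %in% pre_years)
  post_idx <- which(g$samples$population == population &
                      g$samples$year %in% post_years)
  if (length(pre_idx) == 0 || length(post_idx) == 0) {
    stop("empty pre or post stratum for population ", population)
  }
  freq_pre <- allele_frequencies(g, pre_idx)
  freq_post <- allele_frequencies(g, post_idx)
  delta <- freq_post - freq_pre
  if (sum(!is.na(delta)) < 40) {
    stop("fewer than 40 SNPs with defined frequency change; ",
         "quantiles would be meaningless")
  }
  q <- midrank_quantiles(abs(delta))
  records <- data.frame(
    snp_id = g$snps$snp_id, scaffold = g$snps$scaffold, pos = g$snps$pos,
    freq_pre = freq_pre, freq_post = freq_post,
    delta_signed = delta, delta_abs = abs(delta), quantile = q,
    stringsAsFactors = FALSE
  )
  records$selected <- !is.na(q) & q > 1 - top_fraction
  sel <- records[records$selected, , drop = FALSE]
  regions <- snp_windows(sel, flank = flank,
                         scaffold_lengths = scaffold_lengths)
  list(records = records, regions = regions)
}

#' Flanking windows around SNPs
#'
#' @param snps data.frame with columns scaffold, pos.
#' @param flank half-width in bp.
#' @param scaffold_lengths optional named vector for right clipping.
#' @return merged interval data frame.
#' @export
snp_windows <- function(snps, flank = 1e5, scaffold_lengths = NULL) {
  if (nrow(snps) == 0) return(intervals())
  start <- pmax(0, snps$pos - flank)
  end <- snps$pos + flank
  if (!is.null(scaffold_lengths)) {
    len <- scaffold_lengths[snps$scaffold]
    end <- ifelse(is.na(len), end, pmin(end, len))
  }
  merge_intervals(intervals(snps$scaffold, start, end))
}

#' Intersect candidate windows across populations
#'
#' @param interval_lists named list (one merged interval set per population).
#' @param scan_records optional named list of per-population scan record
#'   tables; when given, the selected SNPs whose windows support each region
#'   are attached.
#' @param flank flank used when attaching supporting SNPs (default 1e5).
#' @return data.frame of candidate regions; when `scan_records` is given, a
#'   list-column `support` maps population -> supporting snp_ids.
#' @export
intersect_populations <- function(interval_lists, scan_records = NULL,
                                  flank = 1e5) {
  regions <- intersect_interval_sets(interval_lists)
  if (!is.null(scan_records) && nrow(regions) > 0) {
    regions$support <- lapply(seq_len(nrow(regions)), function(i) {
      reg <- regions[i, , drop = FALSE]
      lapply(scan_records, function(rec) {
        sel <- rec[rec$selected, , drop = FALSE]
        if (nrow(sel) == 0) return(character())
        win <- intervals(sel$scaffold, pmax(0, sel$pos - flank),
                         sel$pos + flank)
        sel$snp_id[.iv_overlaps_any(win, reg)]
      })
    })
  }
  regions
}

#' Mean absolute frequency change in sliding windows
#'
#' @param records scan record table (from [scan_population()]).
#' @param window window width in bp (default 2e5).
#' @param step step in bp (default 5e4).
#' @param scaffold_lengths optional named vector bounding the tiling; when
#'   absent, tiling extends to the last SNP on each scaffold.
#' @return data.frame scaffold, start, end, n_snps, mean_delta_abs (NA for
#'   empty windows).
#' @export
sliding_window_mean_delta <- function(records, window = 2e5, step = 5e4,
                                      scaffold_lengths = NULL) {
  out <- lapply(split(records, records$scaffold), function(rec) {
    scaf <- rec$scaffold[1]
    limit <- if (!is.null(scaffold_lengths) &&
                 !is.na(scaffold_lengths[scaf])) {
      scaffold_lengths[[scaf]]
    } else {
      max(rec$pos) + 1
    }
    starts <- seq(0, max(0, limit - 1), by = step)
    ends <- pmin(starts + window, limit)
    stats <- vapply(seq_along(starts), function(k) {
      inside <- rec$pos >= starts[k] & rec$pos < ends[k] &
        !is.na(rec$delta_abs)
      c(sum(inside),
        if (any(inside)) mean(rec$delta_abs[inside]) else NA_real_)
    }, numeric(2))
    data.frame(scaffold = scaf, start = starts, end = ends,
               n_snps = stats[1, ], mean_delta_abs = stats[2, ],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Expected cross-population window overlap under independence
#'
#' Analytic expectation of the number of base pairs covered by candidate
#' windows of every population when the populations evolve independently,
#' conditional on the shared marker panel: at genome position x the chance
#' that population i covers x is `1 - (1 - f_i)^k_i(x)`, where `f_i` is the
#' fraction of its panel SNPs selected and `k_i(x)` counts its panel SNPs
#' within one flank of x; the per-position product is integrated over the
#' genome. Used as the null reference for false candidate regions.
#'
#' @param panel_positions list (one per population) of data frames with
#'   columns scaffold, pos: the SNPs that entered the ranking.
#' @param selected_fractions per-population fraction of panel SNPs in the
#'   selected tail (typically ~0.025).
#' @param scaffold_lengths named vector of scaffold lengths.
#' @param flank window half-width in bp (default 1e5).
#' @return expected overlapped base pairs.
#' @export
expected_false_overlap <- function(panel_positions, selected_fractions,
                                   scaffold_lengths, flank = 1e5) {
  tot <- 0
  for (scaf in names(scaffold_lengths)) {
    len <- scaffold_lengths[[scaf]]
    brk <- sort(unique(c(0, len, unlist(lapply(panel_positions,
      function(pp) {
        p <- pp$pos[pp$scaffold == scaf]
        c(pmax(0, p - flank), pmin(len, p + flank + 1))
      })))))
    brk <- brk[brk >= 0 & brk <= len]
    if (length(brk) < 2) next
    mid <- (utils::head(brk, -1) + utils::tail(brk, -1)) / 2
    w <- diff(brk)
    pr <- rep(1, length(mid))
    for (i in seq_along(panel_positions)) {
      p <- sort(panel_positions[[i]]$pos[
        panel_positions[[i]]$scaffold == scaf])
      k <- findInterval(mid + flank, p) - findInterval(mid - flank - 1, p)
      pr <- pr * (1 - (1 - selected_fractions[i])^k)
    }
    tot <- tot + sum(pr * w)
  }
  tot
}

#' LD decay curve
#'
#' Mean genotypic r-squared in distance bins, over all SNP pairs on the same
#' scaffold within `max_dist` bp, restricted to SNPs with MAF at or above
#' `maf_min` in the chosen samples.
#'
#' @param g genotype table.
#' @param maf_min MAF floor for included SNPs (default 0.05).
#' @param max_dist maximum pair distance in bp (default 2e5).
#' @param n_bins number of equal-width distance bins (default 20).
#' @param sample_idx optional sample subset.
#' @return data.frame bin_start, bin_end, bin_mid, mean_r2, n_pairs.
#' @export
ld_decay_curve <- function(g, maf_min = 0.05, max_dist = 2e5, n_bins = 20,
                           sample_idx = NULL) {
  if (is.null(sample_idx)) sample_idx <- seq_len(nrow(g$calls))
  maf <- minor_allele_frequency(g, sample_idx)
  keep <- !is.na(maf) & maf >= maf_min
  g <- subset_genotypes(g, snp_idx = keep)
  breaks <- seq(0, max_dist, length.out = n_bins + 1)
  sums <- numeric(n_bins)
  counts <- integer(n_bins)
  for (scaf in unique(g$snps$scaffold)) {
    idx <- which(g$snps$scaffold == scaf)
    idx <- idx[order(g$snps$pos[idx])]
    if (length(idx) < 2) next
    pos <- g$snps$pos[idx]
    for (ii in seq_len(length(idx) - 1)) {
      for (jj in (ii + 1):length(idx)) {
        d <- pos[jj] - pos[ii]
        if (d > max_dist) break
        r2 <- ld_r2_genotypic(g$calls[sample_idx, idx[ii]],
                              g$calls[sample_idx, idx[jj]])
        if (is.na(r2)) next
        b <- min(n_bins, max(1L, ceiling(d / max_dist * n_bins)))
        sums[b] <- sums[b] + r2
        counts[b] <- counts[b] + 1L
      }
    }
  }
  data.frame(bin_start = breaks[-length(breaks)], bin_end = breaks[-1],
             bin_mid = (breaks[-1] + breaks[-length(breaks)]) / 2,
             mean_r2 = ifelse(counts > 0, sums / counts, NA_real_),
             n_pairs = counts)
}
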