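test_that("allele frequencies handle missingness and empty columns", {
  g <- toy_genotypes(cbind(c(0L, 1L, 2L), c(2L, 2L, NA), c(NA, NA, NA)))
  f <- allele_frequencies(g)
  expect_equal(f, c(0.5, 1.0, NA))
})

test_that("genotypic r2 equals the direct squared-correlation oracle", {
  expect_equal(ld_r2_genotypic(c(0L, 1L, 2L, 0L), c(0L, 1L, 2L, 0L)), 1.0)
  expect_equal(ld_r2_genotypic(c(0L, 0L, 2L, 2L), c(0L, 2L, 0L, 2L)), 0.0)
  expect_true(is.na(ld_r2_genotypic(c(0L, 0L, 0L), c(0L, 1L, 2L))))

  set.seed(21)
  for (rep in 1:20) {
    a <- sample(0:2, 50, TRUE)
    b <- sample(0:2, 50, TRUE)
    a[sample(50, 5)] <- NA
    b[sample(50, 5)] <- NA
    ok <- !is.na(a) & !is.na(b)
    if (var(a[ok]) == 0 || var(b[ok]) == 0) next
    expect_equal(ld_r2_genotypic(a, b), cor(a[ok], b[ok])^2,
                 tolerance = 1e-12)
  }
})

test_that("LD pruning keeps the leftmost of near-duplicate pairs", {
  set.seed(8)
  base <- sample(0:2, 30, TRUE)
  # duplicates 10 kb apart: second removed
  g <- toy_genotypes(cbind(base, base), pos = c(0, 10000))
  r <- ld_prune(g)
  expect_equal(r$genotypes$snps$snp_id, "s001")
  expect_equal(r$removed, "s002")

  # duplicates 60 kb apart: both kept (beyond the 50 kb limit)
  g2 <- toy_genotypes(cbind(base, base), pos = c(0, 60000))
  expect_equal(nrow(ld_prune(g2)$genotypes$snps), 2)

  # 50 kb exceeded by 1 bp: kept
  g3 <- toy_genotypes(cbind(base, base), pos = c(0, 50001))
  expect_equal(nrow(ld_prune(g3)$genotypes$snps), 2)

  # r2 exactly at the threshold is kept (strict >)
  a <- c(rep(0L, 10), rep(2L, 10))
  b <- a; b[1] <- 1L
  r2 <- ld_r2_genotypic(a, b)
  g4 <- toy_genotypes(cbind(a, b), pos = c(0, 1000))
  expect_equal(nrow(ld_prune(g4, r2_max = r2)$genotypes$snps), 2)
  expect_equal(nrow(ld_prune(g4, r2_max = r2 - 1e-9)$genotypes$snps), 1)

  # chain of three mutually identical SNPs: one survivor
  g5 <- toy_genotypes(cbind(base, base, base), pos = c(0, 1e4, 2e4))
  expect_equal(ld_prune(g5)$genotypes$snps$snp_id, "s001")
})

test_that("no violating pair survives pruning (exhaustive post-check)", {
  set.seed(31)
  m <- 60
  calls <- matrix(sample(0:2, 40 * m, TRUE), 40, m)
  # plant clusters of duplicated columns
  for (k in c(5, 20, 41)) {
    calls[, k + 1] <- calls[, k]
    calls[, k + 2] <- calls[, k]
  }
  pos <- sort(sample(1:2e6, m))
  g <- toy_genotypes(calls, pos = pos)
  pruned <- ld_prune(g)$genotypes
  m2 <- ncol(pruned$calls)
  for (i in seq_len(m2 - 1)) {
    for (j in (i + 1):min(m2, i + 20)) {
      if (pruned$snps$pos[j] - pruned$snps$pos[i] > 50000) break
      r2 <- ld_r2_genotypic(pruned$calls[, i], pruned$calls[, j])
      expect_false(!is.na(r2) && r2 > 0.99)
    }
  }
})

test_that("mid-rank quantiles stay inside (0,1) and rank the top 2.5% exactly", {
  q <- midrank_quantiles(1:1000)
  expect_true(all(q > 0 & q < 1))
  expect_equal(sum(q > 0.975), 25)  # 1000 SNPs, top 2.5% -> 25 selected
  # ties share the averaged rank
  expect_equal(midrank_quantiles(c(1, 2, 2, 3)),
               c(1, 2.5, 2.5, 4) / 5)
})

test_that("scan selects the top tail and clips windows at scaffold bounds", {
  set.seed(12)
  n_snp <- 80
  pre <- matrix(sample(0:2, 10 * n_snp, TRUE), 10, n_snp)
  post <- pre
  post[, 40] <- 2L  # engineered large change at SNP 40
  calls <- rbind(pre, post)
  pos <- seq(20000, by = 25000, length.out = n_snp)
  g <- toy_genotypes(calls, pos = pos,
                     populations = rep("popA", 20),
                     years = rep(c(2000, 2012), each = 10))
  res <- scan_population(g, "popA", 2000, 2012, top_fraction = 0.025,
                         flank = 1e5,
                         scaffold_lengths = c(sc1 = 2e6))
  # the 79 unchanged SNPs tie at delta 0 with mid-rank quantile ~0.49;
  # only the engineered SNP exceeds the 0.975 cutoff
  expect_equal(sum(res$records$selected), 1)
  expect_true(res$records$selected[40])
  expect_equal(res$records$delta_abs, abs(res$records$delta_signed))
  # window around SNP 40 at pos 995000
  w <- res$regions
  expect_true(any(w$start <= 895000 & w$end >= 1095000))

  # left clip: SNP at 20000 -> [0, 120000)
  sel <- data.frame(scaffold = "sc1", pos = 20000)
  expect_equal(snp_windows(sel, 1e5, c(sc1 = 2e6)),
               intervals("sc1", 0, 120000))
  # right clip
  selr <- data.frame(scaffold = "sc1", pos = 1.95e6)
  expect_equal(snp_windows(selr, 1e5, c(sc1 = 2e6)),
               intervals("sc1", 1.85e6, 2e6))
})

test_that("scan refuses fewer than 40 informative SNPs", {
  calls <- matrix(sample(0:2, 200, TRUE), 10, 20)
  g <- toy_genotypes(calls, years = rep(c(2000, 2012), each = 5))
  expect_error(scan_population(g, "popA", 2000, 2012), "40")
})

test_that("absolute frequency change is invariant under allele relabeling", {
  set.seed(3)
  calls <- matrix(sample(c(0:2, NA), 400, TRUE), 10, 40)
  g <- toy_genotypes(calls, years = rep(c(2000, 2012), each = 5))
  flip <- seq(1, 40, 2)
  calls2 <- calls
  calls2[, flip] <- 2L - calls2[, flip]
  g2 <- toy_genotypes(calls2, years = rep(c(2000, 2012), each = 5))
  r1 <- scan_population(g, "popA", 2000, 2012)
  r2 <- scan_population(g2, "popA", 2000, 2012)
  expect_equal(r1$records$delta_abs, r2$records$delta_abs)
  expect_equal(r1$records$quantile, r2$records$quantile)
})

test_that("interval intersection matches the per-bp oracle and is commutative", {
  expect_equal(
    intersect_interval_sets(list(intervals("s1", 0, 2e5),
                                 intervals("s1", 1.5e5, 3.5e5),
                                 intervals("s1", 1.8e5, 3.8e5))),
    intervals("s1", 1.8e5, 2e5)
  )
  expect_equal(nrow(intersect_interval_sets(
    list(intervals("s1", 0, 100), intervals("s1", 200, 300)))), 0)

  set.seed(17)
  for (rep in 1:5) {
    lists <- lapply(1:3, function(k) {
      n <- sample(3:8, 1)
      start <- sample(0:90000, n)
      intervals(sample(c("sA", "sB"), n, TRUE), start,
                start + sample(5000:30000, n, TRUE))
    })
    got <- intersect_interval_sets(lists)
    oracle <- brute_intersect(lists, c("sA", "sB"), 130000)
    expect_equal(got$scaffold, oracle$scaffold)
    expect_equal(got$start, oracle$start)
    expect_equal(got$end, oracle$end)
    # commutativity
    got_rev <- intersect_interval_sets(rev(lists))
    expect_equal(got, got_rev)
  }
})

test_that("lowering the selected fraction never adds candidate regions", {
  sim <- simulate_dataset(sim_config(seed = 6, n_scaffolds = 4,
                                     scaffold_length = 1e6))
  gf <- filter_chain(sim$genotypes)$genotypes
  strata <- default_pop_strata()
  lens <- stats::setNames(sim$scaffold_order$length,
                          sim$scaffold_order$scaffold)
  region_cover <- function(top) {
    lists <- lapply(names(strata), function(p) {
      scan_population(gf, p, strata[[p]]$pre, strata[[p]]$post,
                      top_fraction = top, scaffold_lengths = lens)$regions
    })
    intersect_populations(lists)
  }
  wide <- region_cover(0.05)
  narrow <- region_cover(0.01)
  if (nrow(narrow) > 0) {
    expect_true(all(suppressWarnings(
      devilscan:::.iv_overlaps_any(narrow, wide))))
  } else {
    succeed()
  }
})

test_that("sliding-window mean |delta| matches hand computation", {
  records <- data.frame(
    scaffold = "sc1", pos = c(10000, 60000, 150000, 260000, 410000),
    delta_abs = c(0.1, 0.3, 0.5, 0.2, 0.4)
  )
  win <- sliding_window_mean_delta(records, window = 2e5, step = 5e4,
                                   scaffold_lengths = c(sc1 = 5e5))
  w1 <- win[win$start == 0, ]        # SNPs at 10k, 60k, 150k
  expect_equal(w1$mean_delta_abs, mean(c(0.1, 0.3, 0.5)))
  expect_equal(w1$n_snps, 3)
  w2 <- win[win$start == 100000, ]   # SNPs at 150k, 260k
  expect_equal(w2$mean_delta_abs, mean(c(0.5, 0.2)))
  # empty window
  w_empty <- win[win$start == 450000, ]
  expect_true(is.na(w_empty$mean_delta_abs))
  expect_equal(w_empty$n_snps, 0)
})

test_that("LD decay curve: duplicated columns give bin means of 1", {
  set.seed(2)
  base1 <- sample(0:2, 40, TRUE)
  base2 <- sample(0:2, 40, TRUE)
  calls <- cbind(base1, base1, base2, base2)
  g <- toy_genotypes(calls, pos = c(0, 30000, 200000, 290000))
  curve <- ld_decay_curve(g, maf_min = 0.05, max_dist = 1e5, n_bins = 10)
  with_pairs <- curve[curve$n_pairs > 0, ]
  expect_equal(with_pairs$mean_r2[with_pairs$bin_end %in%
                                    c(30000, 90000)], c(1, 1))
  # single usable SNP -> empty curve
  g1 <- toy_genotypes(matrix(sample(0:2, 40, TRUE), 40, 1))
  expect_true(all(ld_decay_curve(g1)$n_pairs == 0))
})
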