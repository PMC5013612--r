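test_that("EHHS is 1 at the focal site and for identical haplotypes", {
  h <- toy_haplotypes(matrix(rep(c(0L, 1L), each = 10), 4, 10,
                             byrow = TRUE)[c(1, 2, 1, 2), ])
  # two distinct haplotypes, each duplicated: polymorphic focal, identical
  # extension -> EHHS stays at its focal value 1 everywhere
  curve <- ehhs(h, 5)
  expect_equal(curve$ehhs, rep(1, 10))
  expect_equal(curve$ehhs[curve$offset == 0], 1)
})

test_that("EHHS matches the brute-force pairwise-identity oracle", {
  set.seed(19)
  maxd <- 0
  for (rep in 1:25) {
    n <- sample(seq(6, 32, 2), 1)
    L <- sample(6:64, 1)
    H <- matrix(rbinom(n * L, 1, runif(1, 0.3, 0.7)), n, L)
    H[matrix(runif(n * L) < 0.12, n, L)] <- NA
    pos <- sort(sample(1:500000, L))
    hs <- toy_haplotypes(H, pos = pos)
    focal <- sample(seq_len(L), 1)
    a <- H[, focal]
    if (length(unique(a[!is.na(a)])) < 2) next
    curve <- ehhs(hs, focal, trunc = 0)
    oracle <- brute_ehhs(H, pos, focal)
    ours <- curve$ehhs[match(pos - pos[focal], curve$offset)]
    d <- abs(ours - oracle)
    maxd <- max(maxd, d[!is.na(d)])
  }
  expect_lt(maxd, 1e-12)
})

test_that("EHHS is invariant to row permutation and allele relabeling", {
  set.seed(23)
  H <- matrix(rbinom(8 * 12, 1, 0.5), 8, 12)
  hs <- toy_haplotypes(H)
  curve <- ehhs(hs, 6)
  hs_perm <- toy_haplotypes(H[sample(8), ])
  expect_equal(ehhs(hs_perm, 6), curve)
  hs_flip <- toy_haplotypes(1L - H)
  expect_equal(ehhs(hs_flip, 6), curve)
})

test_that("EHHS curves are non-increasing away from the focal SNP", {
  set.seed(29)
  H <- matrix(rbinom(12 * 20, 1, 0.5), 12, 20)
  hs <- toy_haplotypes(H)
  curve <- ehhs(hs, 10, trunc = 0)
  left <- curve$ehhs[curve$offset <= 0]
  right <- curve$ehhs[curve$offset >= 0]
  expect_true(all(diff(left) >= 0))    # increases toward the focal site
  expect_true(all(diff(right) <= 0))
})

test_that("iES integrates the curve by trapezoids", {
  # constant 1 over +-5000 bp -> area 10000
  flat <- data.frame(offset = c(-5000, 0, 5000), ehhs = c(1, 1, 1))
  expect_equal(ies(flat), 10000)
  # single point -> 0
  expect_equal(ies(data.frame(offset = 0, ehhs = 1)), 0)
  # piecewise-linear toy, hand trapezoid sum:
  # [-2000,0]: (0.4+1)/2*2000 = 1400 ; [0,1000]: (1+0.8)/2*1000 = 900 ;
  # [1000,4000]: (0.8+0.1)/2*3000 = 1350 ; total 3650
  toy <- data.frame(offset = c(-2000, 0, 1000, 4000),
                    ehhs = c(0.4, 1, 0.8, 0.1))
  expect_equal(ies(toy), 3650)
})

test_that("introducing a mismatch into a homozygous flank lowers iES", {
  # two haplotype classes, three copies each, fully homozygous flanks
  H <- rbind(rep(0L, 16), rep(1L, 16))[rep(1:2, 3), ]
  hs <- toy_haplotypes(H)
  base <- ies(ehhs(hs, 8))
  H2 <- H
  H2[1, 12] <- 1L - H2[1, 12]
  hs2 <- toy_haplotypes(H2)
  expect_lt(ies(ehhs(hs2, 8)), base)
})

test_that("identical strata give rsb_raw 0 and rsb_std has median 0", {
  set.seed(5)
  H <- matrix(rbinom(10 * 30, 1, 0.5), 10, 30)
  pre <- toy_haplotypes(H, stratum = "pre")
  post <- toy_haplotypes(H, stratum = "post")
  tab <- rsb(pre, post)
  ok <- !is.na(tab$rsb_raw)
  expect_true(any(ok))
  expect_equal(tab$rsb_raw[ok], rep(0, sum(ok)))

  # different strata: median of standardized scores is 0 by construction
  set.seed(6)
  H2 <- matrix(rbinom(10 * 30, 1, 0.5), 10, 30)
  tab2 <- rsb(pre, toy_haplotypes(H2, stratum = "post"))
  expect_equal(median(tab2$rsb_std, na.rm = TRUE), 0)
})

test_that("rsb is antisymmetric under exchanging the strata", {
  set.seed(7)
  H1 <- matrix(rbinom(12 * 25, 1, 0.5), 12, 25)
  H2 <- matrix(rbinom(12 * 25, 1, 0.5), 12, 25)
  pre <- toy_haplotypes(H1, stratum = "pre")
  post <- toy_haplotypes(H2, stratum = "post")
  fwd <- rsb(pre, post)
  rev <- rsb(post, pre)
  expect_equal(fwd$rsb_raw, -rev$rsb_raw)
})

test_that("SNPs below the MAF floor in either stratum are excluded", {
  H1 <- cbind(rep(0:1, 5), c(1L, rep(0L, 9)), rep(0:1, 5))
  H2 <- cbind(rep(0:1, 5), rep(0:1, 5), rep(0:1, 5))
  tab <- rsb(toy_haplotypes(H1), toy_haplotypes(H2), maf_min = 0.2)
  expect_true(is.na(tab$rsb_raw[2]))   # maf 0.1 pre < 0.2
})

test_that("a post-stratum sweep concentrates in the lower rsb_std tail", {
  # simulate linked neutral variation; sweep only in the post stratum
  sim_pair <- function(seed, sweep_post) {
    cfg <- sim_config(
      seed = seed, n_scaffolds = 3, scaffold_length = 1e6,
      populations = "A", ne = 40, epidemic_years = 2000,
      sel_coeff = if (sweep_post) 0.8 else 0,
      missing_rate = 0, selected_scaffold = 2, selected_pos = 5e5,
      sampling = list(A = list(list(year = 2000, n = 20),
                               list(year = 2012, n = 20)))
    )
    sim <- simulate_dataset(cfg)
    g <- sim$genotypes
    scafs <- unique(g$snps$scaffold)
    pre <- lapply(scafs, function(s) {
      extract_haplotypes(g, "A", 2000, s, stratum = "pre")
    })
    post <- lapply(scafs, function(s) {
      extract_haplotypes(g, "A", 2012, s, stratum = "post")
    })
    tab <- suppressMessages(rsb(pre, post))
    ti <- sim$truth$selected_interval
    near <- tab$scaffold == ti$scaffold &
      tab$pos >= ti$start & tab$pos < ti$end
    list(tab = tab, near = near)
  }
  # pool several replicates; swept-region SNPs should sit low
  lows <- c()
  for (sd in 1:4) {
    r <- sim_pair(sd, TRUE)
    vals <- r$tab$rsb_std[r$near & !is.na(r$tab$rsb_std)]
    if (length(vals)) lows <- c(lows, vals)
  }
  # the genome-wide median of rsb_std is 0 by construction, so a negative
  # median inside the swept region places it in the lower tail; the
  # mirrored direction is covered by the antisymmetry property above
  expect_true(length(lows) > 3)
  expect_lt(median(lows), 0)
})
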