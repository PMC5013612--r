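# small fast configuration shared by simulator tests
tiny_cfg <- function(seed, ...) {
  sim_config(seed = seed, n_scaffolds = 2, scaffold_length = 5e5, ...)
}

test_that("the deterministic trajectory matches hand iteration", {
  expect_equal(expected_trajectory(0.3, 0, 5), rep(0.3, 6))
  expect_equal(expected_trajectory(0, 0.5, 3), rep(0, 4))
  expect_equal(expected_trajectory(1, 0.5, 3), rep(1, 4))
  # p0 = 0.2, s = 0.5: p1 = 0.3/1.1, p2, p3 iterated by hand
  p1 <- 0.2 * 1.5 / (1 + 0.2 * 0.5)
  p2 <- p1 * 1.5 / (1 + p1 * 0.5)
  p3 <- p2 * 1.5 / (1 + p2 * 0.5)
  expect_equal(expected_trajectory(0.2, 0.5, 3), c(0.2, p1, p2, p3))
  expect_equal(p1, 0.27272727272727, tolerance = 1e-10)
})

test_that("same config and seed give byte-identical output", {
  d1 <- tempfile(); d2 <- tempfile()
  write_sim_dataset(simulate_dataset(tiny_cfg(99)), d1)
  write_sim_dataset(simulate_dataset(tiny_cfg(99)), d2)
  for (f in c("genotypes.vcf", "samples.tsv", "genes.bed")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  d3 <- tempfile()
  write_sim_dataset(simulate_dataset(tiny_cfg(100)), d3)
  expect_false(identical(readLines(file.path(d1, "genotypes.vcf")),
                         readLines(file.path(d3, "genotypes.vcf"))))
})

test_that("each generation carries exactly 2 Ne haplotypes per population", {
  sim <- simulate_dataset(tiny_cfg(1))
  for (p in names(sim$truth$freq_records)) {
    fr <- sim$truth$freq_records[[p]]
    ne <- sim$truth$ne[match(p, names(sim$truth$freq_records))]
    # frequencies are multiples of 1/(2 ne): counts conserved at 2 ne
    counts <- fr * 2 * ne
    expect_equal(counts, round(counts), tolerance = 1e-9)
  }
})

test_that("trajectories stay in [0,1] and truth localizes the selected SNP", {
  sim <- simulate_dataset(tiny_cfg(2))
  for (tr in sim$truth$trajectories) {
    expect_true(all(tr >= 0 & tr <= 1))
  }
  snp <- sim$genotypes$snps[
    sim$genotypes$snps$snp_id == sim$truth$selected_snp, ]
  expect_equal(snp$scaffold, sim$truth$selected_scaffold)
  expect_equal(snp$pos, sim$truth$selected_pos)
  expect_true(abs(sim$truth$p0_realized - 0.2) <= 0.05 + 1e-9)
})

test_that("without recombination sampled haplotypes descend intact", {
  cfg <- sim_config(seed = 31, n_scaffolds = 1, scaffold_length = 5e5,
                    recomb_rate = 0, missing_rate = 0)
  sim <- simulate_dataset(cfg)
  pool <- sim$truth$ancestral_haplotypes
  pool_keys <- unique(apply(pool, 1, paste, collapse = ""))
  g <- sim$genotypes
  # reconstruct each sampled haplotype from the phased GT strings
  for (i in seq_len(min(nrow(g$calls), 30))) {
    a <- as.integer(substr(g$gt[i, ], 1, 1))
    b <- as.integer(substr(g$gt[i, ], 3, 3))
    expect_true(paste(a, collapse = "") %in% pool_keys)
    expect_true(paste(b, collapse = "") %in% pool_keys)
  }
})

test_that("a monomorphic site stays monomorphic (no mutation)", {
  set.seed(8)
  sim <- simulate_trajectories(50, 30, 0.5, c(0, 3, 6), 40,
                               p0 = rep(c(0, 1), 25))
  expect_true(all(sim$p_true[seq(1, 50, 2), ] == 0))
  expect_true(all(sim$p_true[seq(2, 50, 2), ] == 1))
})

test_that("neutral zero-generation sampling shows no frequency change", {
  cfg <- sim_config(
    seed = 12, n_scaffolds = 1, scaffold_length = 5e5,
    populations = "A", ne = 200, sel_coeff = 0, epidemic_years = 2000,
    missing_rate = 0,
    sampling = list(A = list(list(year = 2000, n = 190),
                             list(year = 2000, n = 190)))
  )
  sim <- simulate_dataset(cfg)
  tr <- sim$truth$trajectories[["A"]]
  expect_equal(length(tr), 1)  # both samples drawn from generation 0
  g <- sim$genotypes
  e1 <- grepl("_e1_", g$samples$sample_id)
  f1 <- allele_frequencies(g, which(e1))
  f2 <- allele_frequencies(g, which(!e1))
  # two near-exhaustive samples of the same generation agree closely
  expect_lt(mean(abs(f1 - f2), na.rm = TRUE), 0.02)
})

test_that("the selected site tracks the deterministic recursion in the mean", {
  # one population, Ne 30, s 0.3, 6 generations; the mean realized rise
  # over replicates should match the drift-free recursion within 0.05
  reps <- 150
  ends <- numeric(reps)
  dets <- numeric(reps)
  for (r in seq_len(reps)) {
    cfg <- sim_config(
      seed = 4000 + r, n_scaffolds = 1, scaffold_length = 4e5,
      populations = "A", ne = 30, sel_coeff = 0.3, epidemic_years = 2000,
      missing_rate = 0,
      sampling = list(A = list(list(year = 2000, n = 10),
                               list(year = 2012, n = 10)))
    )
    sim <- simulate_dataset(cfg)
    tr <- sim$truth$trajectories[["A"]]
    ends[r] <- tr[length(tr)]
    dets[r] <- tail(expected_trajectory(tr[1], 0.3, 6), 1)
  }
  expect_lt(abs(mean(ends) - mean(dets)), 0.05)
})

test_that("neutral drift variance matches Wright-Fisher theory", {
  set.seed(55)
  ne <- 30; t <- 6; p0 <- 0.4
  sim <- simulate_trajectories(4000, ne, 0, c(0, t), 2 * ne, p0 = p0)
  v_obs <- var(sim$p_true[, 2])
  v_exp <- p0 * (1 - p0) * (1 - (1 - 1 / (2 * ne))^t)
  expect_lt(abs(v_obs - v_exp) / v_exp, 0.15)
})

test_that("oversampling a population is a hard error", {
  cfg <- sim_config(seed = 1, n_scaffolds = 1, scaffold_length = 3e5,
                    populations = "A", ne = 20, epidemic_years = 2000,
                    sampling = list(A = list(list(year = 2000, n = 21))))
  expect_error(simulate_dataset(cfg), "sample size exceeds")
})

test_that("written datasets expose the documented file set", {
  d <- tempfile()
  paths <- write_sim_dataset(simulate_dataset(tiny_cfg(3)), d)
  expect_true(all(file.exists(paths)))
  truth <- jsonlite::read_json(paths[["truth"]])
  expect_true(all(c("selected_snp", "selected_interval", "trajectories")
                  %in% names(truth)))
})
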