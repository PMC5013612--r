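test_that("transition matrix rows sum to 1 with absorbing boundaries", {
  for (s in c(-0.3, 0, 0.5)) {
    m <- wf_transition_matrix(10, s)
    expect_equal(rowSums(m), rep(1, 21), tolerance = 1e-12)
    expect_equal(m[1, 1], 1)        # loss is absorbing
    expect_equal(m[21, 21], 1)      # fixation is absorbing
  }
})

test_that("forward likelihood equals exhaustive path enumeration at ne=2", {
  set.seed(13)
  for (rep in 1:6) {
    counts <- rbinom(3, 12, runif(1, 0.2, 0.8))
    traj <- trajectory_data(c(0, 2, 3), counts, rep(12, 3))
    s <- runif(1, -0.3, 0.8)
    expect_equal(wf_loglikelihood(traj, s, 2),
                 brute_wf_loglik(traj, s, 2), tolerance = 1e-10)
  }
})

test_that("neutrality fits static data better than strong selection", {
  traj <- trajectory_data(c(0, 3, 6), c(30, 30, 30), c(60, 60, 60))
  expect_gt(wf_loglikelihood(traj, 0, 30),
            wf_loglikelihood(traj, 0.5, 30))
})

test_that("strictly rising frequencies give a positive MLE", {
  traj <- trajectory_data(c(0, 3, 6), c(10, 25, 38), c(40, 40, 40))
  fit <- estimate_s(traj, ne = 30)
  expect_gt(fit$s_hat, 0)
  expect_true(fit$ci_low <= fit$s_hat && fit$s_hat <= fit$ci_high)
})

test_that("the fit is deterministic for identical inputs", {
  traj <- trajectory_data(c(0, 2, 4), c(8, 15, 22), c(40, 40, 40))
  f1 <- estimate_s(traj, ne = 25)
  f2 <- estimate_s(traj, ne = 25)
  expect_identical(f1, f2)
})

test_that("impossible observations are rejected", {
  expect_error(trajectory_data(c(0, 2), c(5, 50), c(40, 40)), "total")
  expect_error(trajectory_data(0, 5, 40), "2 time points")
  expect_error(trajectory_data(c(0, 1.5), c(5, 6), c(40, 40)), "whole")
})

test_that("per-SNP fits always report the increasing allele", {
  # alt allele falls: the fit flips labels so s_hat describes the riser
  calls_pre <- matrix(2L, 10, 1)
  calls_post <- matrix(0L, 10, 1)
  g <- toy_genotypes(rbind(calls_pre, calls_post),
                     years = rep(c(2000, 2012), each = 10))
  fits <- suppressWarnings(
    estimate_s_genotypes(g, "popA", ne = 30, gen_time = 2))
  expect_equal(fits$increasing_allele, "ref")
  expect_gt(fits$s_hat, 0)
})

test_that("region mean s summarizes fits inside the region", {
  fits <- data.frame(snp_id = c("a", "b", "c"), scaffold = "sc1",
                     pos = c(100, 200, 9000), s_hat = c(0.1, 0.3, 0.9))
  region <- intervals("sc1", 0, 1000)
  got <- region_mean_s(fits, region)
  expect_equal(got$mean_s, 0.2)
  expect_equal(got$min_s, 0.1)
  expect_equal(got$max_s, 0.3)
  expect_equal(got$n_snps, 2)
  # single SNP region
  one <- region_mean_s(fits, intervals("sc1", 8000, 10000))
  expect_equal(one$mean_s, 0.9)
  # empty region
  expect_true(is.na(region_mean_s(fits, intervals("sc1", 20000,
                                                  30000))$mean_s))
})

test_that("identical frequencies give an unbounded Ne estimate", {
  f <- runif(200, 0.2, 0.8)
  expect_warning(est <- jorde_ryman_ne(f, f, 25, 25, t = 4), "unbounded")
  expect_equal(est$ne_hat, Inf)
})

test_that("jackknife CI width shrinks as loci accumulate", {
  set.seed(77)
  width_at <- function(n_loci) {
    sim <- simulate_trajectories(n_loci, 35, 0, c(0, 4), 50)
    est <- suppressWarnings(jorde_ryman_ne(
      sim$alt_counts[, 1] / 50, sim$alt_counts[, 2] / 50, 25, 25, t = 4))
    if (!is.finite(est$ci_high)) NA else est$ci_high - est$ci_low
  }
  w_small <- replicate(8, width_at(500))
  w_big <- replicate(8, width_at(5000))
  expect_lt(median(w_big, na.rm = TRUE), median(w_small, na.rm = TRUE))
})

test_that("Ne wrapper maps years to generations and uses per-locus sizes", {
  set.seed(15)
  sim <- simulate_trajectories(300, 35, 0, c(0, 4), 50)
  # embed the counts in a genotype table: 25 diploids per stratum
  pre_dos <- sapply(seq_len(300), function(l) {
    k <- sim$alt_counts[l, 1]
    v <- integer(25); v[seq_len(k %/% 2)] <- 2L
    if (k %% 2) v[k %/% 2 + 1] <- 1L
    v
  })
  post_dos <- sapply(seq_len(300), function(l) {
    k <- sim$alt_counts[l, 2]
    v <- integer(25); v[seq_len(k %/% 2)] <- 2L
    if (k %% 2) v[k %/% 2 + 1] <- 1L
    v
  })
  g <- toy_genotypes(rbind(pre_dos, post_dos),
                     pos = seq(0, by = 1e5, length.out = 300),
                     years = rep(c(2000, 2008), each = 25))
  est <- suppressWarnings(
    jorde_ryman_ne_genotypes(g, "popA", 2000, 2008, gen_time = 2))
  expect_equal(est$t, 4)
  expect_true(est$ne_hat > 10)  # same order as the simulated Ne
})
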