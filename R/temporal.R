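#' Temporal population-genetic estimation
#'
#' Two-sample temporal effective-population-size estimation (Jorde-Ryman
#' standardized temporal variance with sample-size correction, jackknife CIs
#' over loci) and per-SNP maximum-likelihood estimation of selection
#' coefficients from allele-frequency time series under an exact
#' Wright-Fisher hidden Markov model with genic selection.
#'
#' @name temporal
NULL

#' Allele-frequency trajectory container
#'
#' @param times sampling times in generations (length >= 2, increasing).
#' @param alt_counts observed alt-allele counts per time point.
#' @param totals called allele totals per time point.
#' @param snp optional SNP metadata row.
#' @return object of class `trajectory_data`.
#' @export
trajectory_data <- function(times, alt_counts, totals, snp = NULL) {
  stopifnot(length(times) == length(alt_counts),
            length(times) == length(totals))
  if (length(times) < 2) stop("need at least 2 time points")
  if (is.unsorted(times, strictly = TRUE)) stop("times must increase")
  if (any(alt_counts > totals) || any(alt_counts < 0)) {
    stop("allele counts must lie in [0, total]")
  }
  if (any(times != round(times))) stop("times must be whole generations")
  structure(list(times = as.integer(times),
                 alt_counts = as.integer(alt_counts),
                 totals = as.integer(totals), snp = snp),
            class = "trajectory_data")
}

# ---- Jorde-Ryman temporal Ne ------------------------------------------------

# pooled Fs and its sample-size-corrected version Fs' for biallelic loci.
# x, y: per-locus allele frequencies at the two samples; nx, ny: per-locus
# sample sizes in diploid individuals.
.jr_fs_prime <- function(x, y, nx, ny) {
  z <- (x + y) / 2
  num <- (x - y)^2
  den <- z * (1 - z)
  ok <- !is.na(num) & !is.na(den) & den > 0 & nx > 0 & ny > 0
  fs <- sum(num[ok]) / sum(den[ok])
  n_harm <- 1 / mean(0.5 * (1 / nx[ok] + 1 / ny[ok]))
  fs_prime <- (fs * (1 - 1 / (4 * n_harm)) - 1 / n_harm) / (1 + fs / 4)
  list(fs = fs, fs_prime = fs_prime, n_harm = n_harm, ok = ok,
       num = num, den = den)
}

#' Jorde-Ryman two-sample temporal Ne
#'
#' Standardized temporal variance `Fs = sum (x - y)^2 / sum z(1 - z)` pooled
#' over loci (z the mean of the two sample frequencies), corrected for
#' finite sample sizes. The corrected variance `Fs'` estimates the
#' accumulated drift `F = 1 - (1 - 1/(2 Ne))^t`, which is inverted exactly
#' for `Ne` (the familiar `Ne = t/(2 Fs')` is its first-order
#' approximation). 95% confidence limits come from a delete-one-locus
#' jackknife on `Fs'`.
#'
#' @param freq1,freq2 per-locus allele frequencies at the two samples.
#' @param n1,n2 per-locus sample sizes in diploid individuals (scalars are
#'   recycled).
#' @param t generations separating the samples.
#' @param population optional label.
#' @return list(ne_hat, ci_low, ci_high, fs, fs_prime, n_loci, population).
#'   `ne_hat` is Inf (with a warning) when the corrected variance is <= 0,
#'   i.e. the data show no drift signal beyond sampling noise.
#' @export
jorde_ryman_ne <- function(freq1, freq2, n1, n2, t, population = NA) {
  n1 <- rep_len(n1, length(freq1))
  n2 <- rep_len(n2, length(freq2))
  full <- .jr_fs_prime(freq1, freq2, n1, n2)
  ok <- full$ok
  n_loci <- sum(ok)
  if (n_loci < 2) stop("need at least 2 informative loci")
  ne_from_fsp <- function(fsp) {
    if (is.na(fsp) || fsp <= 0) return(Inf)
    if (fsp >= 1) return(0.5)
    0.5 / (1 - (1 - fsp)^(1 / t))
  }
  ne_hat <- ne_from_fsp(full$fs_prime)
  if (!is.finite(ne_hat)) {
    warning("corrected temporal variance <= 0; Ne is unbounded")
  }
  # delete-one-locus jackknife on Fs'
  idx <- which(ok)
  s_num <- sum(full$num[ok])
  s_den <- sum(full$den[ok])
  inv_n <- 0.5 * (1 / n1 + 1 / n2)
  s_inv <- sum(inv_n[ok])
  fsp_i <- vapply(idx, function(l) {
    fs_l <- (s_num - full$num[l]) / (s_den - full$den[l])
    nh_l <- 1 / ((s_inv - inv_n[l]) / (n_loci - 1))
    (fs_l * (1 - 1 / (4 * nh_l)) - 1 / nh_l) / (1 + fs_l / 4)
  }, numeric(1))
  m <- mean(fsp_i)
  se <- sqrt((n_loci - 1) / n_loci * sum((fsp_i - m)^2))
  lo_fsp <- full$fs_prime - 1.96 * se
  hi_fsp <- full$fs_prime + 1.96 * se
  list(ne_hat = ne_hat,
       ci_low = ne_from_fsp(hi_fsp),
       ci_high = ne_from_fsp(lo_fsp),
       fs = full$fs, fs_prime = full$fs_prime,
       n_loci = n_loci, t = t, population = population)
}

#' Jorde-Ryman Ne from a genotype table
#'
#' @param g genotype table (already filtered as desired).
#' @param population population label.
#' @param pre_years,post_years calendar years of the two strata.
#' @param gen_time generation time in years (default 2).
#' @return as [jorde_ryman_ne()].
#' @export
jorde_ryman_ne_genotypes <- function(g, population, pre_years, post_years,
                                     gen_time = 2) {
  pre <- which(g$samples$population == population &
                 g$samples$year %in% pre_years)
  post <- which(g$samples$population == population &
                  g$samples$year %in% post_years)
  if (!length(pre) || !length(post)) stop("empty stratum")
  t_gen <- round((mean(post_years) - mean(pre_years)) / gen_time)
  f1 <- allele_frequencies(g, pre)
  f2 <- allele_frequencies(g, post)
  n1 <- colSums(!is.na(g$calls[pre, , drop = FALSE]))
  n2 <- colSums(!is.na(g$calls[post, , drop = FALSE]))
  jorde_ryman_ne(f1, f2, n1, n2, t = t_gen, population = population)
}

# ---- Wright-Fisher likelihood ----------------------------------------------

#' Wright-Fisher transition matrix under genic selection
#'
#' States are alt-allele counts k in 0..2ne; one generation maps frequency
#' p = k/(2ne) to p' = p(1+s)/(1+ps) deterministically, followed by binomial
#' resampling of 2ne alleles. k = 0 and k = 2ne are absorbing.
#'
#' @param ne effective number of diploids (<= 500; the exact-matrix regime).
#' @param s selection coefficient (> -1) of the alt allele.
#' @return (2ne+1) x (2ne+1) row-stochastic matrix.
#' @export
wf_transition_matrix <- function(ne, s) {
  stopifnot(ne >= 1, ne <= 500, s > -1)
  n2 <- 2 * ne
  p <- (0:n2) / n2
  p_sel <- p * (1 + s) / (1 + p * s)
  t(vapply(p_sel, function(pp) stats::dbinom(0:n2, n2, pp), numeric(n2 + 1)))
}

#' Log-likelihood of an allele-frequency time series
#'
#' Hidden Markov model: the latent state is the population alt-allele count;
#' transitions follow [wf_transition_matrix()]; each observed alt count is a
#' binomial draw of the sampled alleles from the population frequency. The
#' initial state is uniform over 0..2ne. Computed by the scaled forward
#' algorithm.
#'
#' @param traj a [trajectory_data()].
#' @param s selection coefficient.
#' @param ne effective number of diploids.
#' @return log-likelihood of the observations.
#' @export
wf_loglikelihood <- function(traj, s, ne) {
  n2 <- 2 * ne
  p <- (0:n2) / n2
  emis <- function(i) {
    stats::dbinom(traj$alt_counts[i], traj$totals[i], p)
  }
  alpha <- rep(1 / (n2 + 1), n2 + 1) * emis(1)
  ll <- 0
  tot <- sum(alpha)
  if (tot == 0) return(-Inf)
  ll <- ll + log(tot)
  alpha <- alpha / tot
  if (length(traj$times) > 1) {
    trans <- wf_transition_matrix(ne, s)
    gaps <- diff(traj$times)
    for (i in seq_along(gaps)) {
      for (g in seq_len(gaps[i])) alpha <- as.vector(alpha %*% trans)
      alpha <- alpha * emis(i + 1)
      tot <- sum(alpha)
      if (tot == 0) return(-Inf)
      ll <- ll + log(tot)
      alpha <- alpha / tot
    }
  }
  ll
}

#' Maximum-likelihood selection coefficient for one SNP
#'
#' Profiles [wf_loglikelihood()] over a grid of selection coefficients,
#' refines the maximum by golden-section search, and reports a
#' profile-likelihood confidence interval (points within 1.92 log-units of
#' the maximum). A maximum on the grid boundary triggers a warning and a
#' censored interval.
#'
#' @param traj a [trajectory_data()].
#' @param ne effective number of diploids.
#' @param s_grid coarse grid (default seq(-0.5, 2.5, by = 0.1)).
#' @return list(s_hat, ci_low, ci_high, loglik, ne_used, boundary).
#' @export
estimate_s <- function(traj, ne, s_grid = seq(-0.5, 2.5, by = 0.1)) {
  ll <- vapply(s_grid, function(s) wf_loglikelihood(traj, s, ne), numeric(1))
  best <- which.max(ll)
  boundary <- best == 1 || best == length(s_grid)
  if (boundary) {
    warning("likelihood maximized at the grid boundary; CI censored")
    s_hat <- s_grid[best]
    ll_max <- ll[best]
  } else {
    opt <- stats::optimize(function(s) wf_loglikelihood(traj, s, ne),
                           lower = s_grid[best - 1], upper = s_grid[best + 1],
                           maximum = TRUE, tol = 1e-4)
    s_hat <- opt$maximum
    ll_max <- opt$objective
  }
  # profile-likelihood CI: crossings of ll_max - 1.92
  target <- ll_max - 1.92
  f <- function(s) wf_loglikelihood(traj, s, ne) - target
  lo <- s_grid[1]
  hi <- s_grid[length(s_grid)]
  below_lo <- which(s_grid < s_hat & ll < target)
  if (length(below_lo)) {
    lo <- stats::uniroot(f, c(s_grid[max(below_lo)], s_hat),
                         tol = 1e-4)$root
  }
  above_hi <- which(s_grid > s_hat & ll < target)
  if (length(above_hi)) {
    hi <- stats::uniroot(f, c(s_hat, s_grid[min(above_hi)]),
                         tol = 1e-4)$root
  }
  list(s_hat = s_hat, ci_low = lo, ci_high = hi, loglik = ll_max,
       ne_used = ne, boundary = boundary)
}

#' Selection estimates for every SNP of a genotype table
#'
#' Builds one frequency trajectory per SNP from the population's sampling
#' years (each year becomes a time point at `(year - first year)/gen_time`
#' generations) and fits the selection coefficient of the *increasing*
#' allele: SNPs whose alt allele decreased overall are label-flipped first,
#' so `s_hat` is always the fitness advantage of the rising allele.
#'
#' @param g genotype table.
#' @param population population label.
#' @param years calendar years to use as time points (default: all years
#'   present for the population).
#' @param ne effective number of diploids for this population.
#' @param gen_time generation time in years (default 2).
#' @param min_call_fraction per-time-point minimum call fraction for a SNP
#'   to be fitted (default 0; upstream filters normally apply).
#' @return data.frame: snp_id, scaffold, pos, s_hat, ci_low, ci_high,
#'   increasing_allele, ne_used, boundary.
#' @export
estimate_s_genotypes <- function(g, population, years = NULL, ne,
                                 gen_time = 2, min_call_fraction = 0) {
  samp <- g$samples$population == population
  if (is.null(years)) years <- sort(unique(g$samples$year[samp]))
  years <- sort(years)
  gens <- (years - years[1]) / gen_time
  if (any(gens != round(gens))) {
    stop("sampling years do not map to whole generations")
  }
  idx_by_year <- lapply(years, function(y) which(samp & g$samples$year == y))
  out <- lapply(seq_len(ncol(g$calls)), function(j) {
    alt <- vapply(idx_by_year, function(ii) {
      sum(g$calls[ii, j], na.rm = TRUE)
    }, numeric(1))
    tot <- vapply(idx_by_year, function(ii) {
      2 * sum(!is.na(g$calls[ii, j]))
    }, numeric(1))
    keep <- tot > 0 & (tot >= 2 * min_call_fraction *
                         vapply(idx_by_year, length, numeric(1)))
    if (sum(keep) < 2) return(NULL)
    alt <- alt[keep]; tot <- tot[keep]; tp <- gens[keep]
    rising <- (alt[length(alt)] / tot[length(tot)]) >= (alt[1] / tot[1])
    if (!rising) alt <- tot - alt
    fit <- suppressWarnings(
      estimate_s(trajectory_data(tp, alt, tot), ne = ne)
    )
    data.frame(snp_id = g$snps$snp_id[j], scaffold = g$snps$scaffold[j],
               pos = g$snps$pos[j], s_hat = fit$s_hat,
               ci_low = fit$ci_low, ci_high = fit$ci_high,
               increasing_allele = if (rising) "alt" else "ref",
               ne_used = ne, boundary = fit$boundary,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(snp_id = character(), scaffold = character(),
                      pos = numeric(), s_hat = numeric(),
                      ci_low = numeric(), ci_high = numeric(),
                      increasing_allele = character(), ne_used = numeric(),
                      boundary = logical(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Mean selection coefficient inside a region
#'
#' @param fits data.frame from [estimate_s_genotypes()].
#' @param region single-row interval data frame.
#' @return list(mean_s, min_s, max_s, n_snps); mean_s is NA for an empty
#'   region.
#' @export
region_mean_s <- function(fits, region) {
  inside <- fits$scaffold == region$scaffold &
    fits$pos >= region$start & fits$pos < region$end
  if (!any(inside)) {
    return(list(mean_s = NA_real_, min_s = NA_real_, max_s = NA_real_,
                n_snps = 0L))
  }
  s <- fits$s_hat[inside]
  list(mean_s = mean(s), min_s = min(s), max_s = max(s),
       n_snps = sum(inside))
}
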