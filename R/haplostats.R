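#' Haplotype homozygosity statistics
#'
#' Site-level extended haplotype homozygosity (EHHS), its integral over
#' genomic distance (iES), and the standardized temporal contrast Rsb
#' between a pre-epidemic and a post-epidemic stratum of the same
#' population.
#'
#' EHHS at distance x from a focal SNP is the probability that two random
#' haplotypes are identical over every SNP from the focal site out to x,
#' normalized so that the value at the focal site is 1. Haplotype
#' homozygosity over a SNP interval uses the unbiased estimator
#' sum(n_h (n_h - 1)) / (n (n - 1)) over distinct multi-site haplotypes. A
#' missing call breaks identity for every pair involving that haplotype
#' (conservative; it biases EHH downward symmetrically in both strata).
#'
#' @name haplostats
NULL

# homozygosity of a grouping vector: sum n_h(n_h-1) / (n(n-1))
.grp_hh <- function(grp) {
  n <- length(grp)
  tab <- tabulate(grp)
  sum(tab * (tab - 1)) / (n * (n - 1))
}

# extend groups by one site; NA alleles become permanent singletons
.grp_extend <- function(grp, allele) {
  key <- paste0(grp, ":", ifelse(is.na(allele),
                                 paste0("m", seq_along(allele)), allele))
  match(key, unique(key))
}

#' Site EHH curve around a focal SNP
#'
#' Extends leftward and rightward from the focal SNP, one SNP at a time,
#' until EHHS drops below `trunc` (values below the threshold are not
#' retained) or the scaffold's SNPs are exhausted.
#'
#' @param h a [haplotype_set()] (>= 4 haplotype rows).
#' @param focal column index of the focal SNP.
#' @param trunc truncation threshold (default 0.05).
#' @return data.frame with columns offset (bp relative to the focal SNP,
#'   negative = left) and ehhs; the focal row has offset 0 and ehhs 1.
#' @export
ehhs <- function(h, focal, trunc = 0.05) {
  H <- h$h
  n <- nrow(H)
  if (n < 4) stop("need at least 4 haplotypes")
  a0 <- H[, focal]
  if (length(unique(a0[!is.na(a0)])) < 2) {
    stop("focal SNP is monomorphic among called haplotypes")
  }
  grp0 <- .grp_extend(rep(1L, n), a0)
  hh0 <- .grp_hh(grp0)
  if (hh0 <= 0) stop("focal-site homozygosity is zero")
  pos <- h$snps$pos
  side <- function(cols) {
    grp <- grp0
    off <- numeric(0)
    val <- numeric(0)
    for (j in cols) {
      grp <- .grp_extend(grp, H[, j])
      e <- .grp_hh(grp) / hh0
      if (e < trunc) break
      off <- c(off, pos[j] - pos[focal])
      val <- c(val, e)
      if (e == 0) break
    }
    list(off = off, val = val)
  }
  left <- side(rev(seq_len(focal - 1)))
  right <- side(seq_len(ncol(H))[-seq_len(focal)])
  data.frame(
    offset = c(rev(left$off), 0, right$off),
    ehhs = c(rev(left$val), 1, right$val)
  )
}

#' Integrated EHH (iES)
#'
#' Trapezoidal integral of the truncated EHHS curve over both flanks, in bp.
#'
#' @param curve data.frame from [ehhs()].
#' @return numeric area (0 for a single-point curve).
#' @export
ies <- function(curve) {
  if (nrow(curve) < 2) return(0)
  x <- curve$offset
  y <- curve$ehhs
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

# iES for every eligible focal SNP of one haplotype set
.ies_all <- function(h, eligible, trunc) {
  vapply(seq_len(ncol(h$h)), function(j) {
    if (!eligible[j]) return(NA_real_)
    ies(ehhs(h, j, trunc = trunc))
  }, numeric(1))
}

# minor allele frequency per column of a haplotype matrix
.hap_maf <- function(H) {
  f <- colMeans(H, na.rm = TRUE)
  f[colSums(!is.na(H)) == 0] <- NA
  pmin(f, 1 - f)
}

#' Temporal Rsb contrast between pre and post strata
#'
#' For each SNP eligible in both strata (MAF >= `maf_min` before and after),
#' computes iES in each stratum and the raw score
#' `rsb_raw = ln(ies_pre / ies_post)`; the raw scores are then standardized
#' genome-wide (over all scaffolds supplied) by subtracting their median and
#' dividing by their standard deviation. Under this convention a sweep in
#' the post stratum (homozygosity increased after the epidemic) drives
#' `rsb_raw` negative, i.e. into the lower tail of `rsb_std`.
#'
#' @param pre,post a [haplotype_set()] or a list of haplotype sets (one per
#'   scaffold); pre and post must cover the same scaffolds with identical
#'   SNP coordinates.
#' @param maf_min per-stratum MAF floor (default 0.05).
#' @param trunc EHHS truncation threshold (default 0.05).
#' @return data.frame: snp_id, scaffold, pos, maf_pre, maf_post, ies_pre,
#'   ies_post, rsb_raw, rsb_std (NA rows mark excluded SNPs).
#' @export
rsb <- function(pre, post, maf_min = 0.05, trunc = 0.05) {
  if (inherits(pre, "haplotype_set")) pre <- list(pre)
  if (inherits(post, "haplotype_set")) post <- list(post)
  if (length(pre) != length(post)) stop("pre/post scaffold lists differ")
  tabs <- vector("list", length(pre))
  for (k in seq_along(pre)) {
    hp <- pre[[k]]; ha <- post[[k]]
    if (!identical(hp$snps$pos, ha$snps$pos) ||
        !identical(hp$snps$scaffold, ha$snps$scaffold)) {
      stop("pre and post strata must share SNP coordinates")
    }
    maf_pre <- .hap_maf(hp$h)
    maf_post <- .hap_maf(ha$h)
    eligible <- !is.na(maf_pre) & !is.na(maf_post) &
      maf_pre >= maf_min & maf_post >= maf_min
    ies_pre <- .ies_all(hp, eligible, trunc)
    ies_post <- .ies_all(ha, eligible, trunc)
    tabs[[k]] <- data.frame(
      snp_id = hp$snps$snp_id, scaffold = hp$snps$scaffold,
      pos = hp$snps$pos, maf_pre = maf_pre, maf_post = maf_post,
      ies_pre = ies_pre, ies_post = ies_post, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  ok <- !is.na(out$ies_pre) & !is.na(out$ies_post) &
    out$ies_pre > 0 & out$ies_post > 0
  n_dropped <- sum(!is.na(out$ies_pre) & !is.na(out$ies_post) & !ok)
  if (n_dropped > 0) {
    message(n_dropped, " SNP(s) with zero iES excluded from Rsb")
  }
  out$rsb_raw <- NA_real_
  out$rsb_raw[ok] <- log(out$ies_pre[ok] / out$ies_post[ok])
  out$rsb_std <- NA_real_
  raw <- out$rsb_raw[ok]
  if (sum(ok) >= 2 && stats::sd(raw) > 0) {
    out$rsb_std[ok] <- (raw - stats::median(raw)) / stats::sd(raw)
  } else if (sum(ok) >= 1) {
    out$rsb_std[ok] <- 0
  }
  out
}
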