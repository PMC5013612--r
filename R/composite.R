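#' Composite window statistic
#'
#' Combines evidence from several per-SNP selection statistics (absolute
#' allele-frequency change and the temporal Rsb contrast, per population)
#' into one score per 100 kb non-overlapping window. For each
#' (population, statistic) combination the SNP with the maximum genome-wide
#' quantile in the window is taken; the quantile is raised to the power of
#' the window's SNP count and subtracted from one, giving an adjusted P
#' value (conservative when SNPs are correlated). Adjusted P values across
#' combinations are combined with Fisher's method and referred to a
#' chi-squared distribution with twice as many degrees of freedom as there
#' are contributing combinations.
#'
#' @name composite
NULL

#' Window-adjusted P value
#'
#' `1 - q^s`: the probability that the maximum of `s` independent uniform
#' quantiles falls below `q`.
#'
#' @param q maximum quantile in the window, in (0, 1).
#' @param s number of SNPs with non-missing values in the window (>= 1).
#' @return adjusted P value; NA when `s` is 0 (the combination is skipped).
#' @export
adjusted_p <- function(q, s) {
  stopifnot(all(is.na(q) | (q > 0 & q < 1)), all(s >= 0))
  ifelse(s == 0 | is.na(q), NA_real_, 1 - q^s)
}

#' Fisher's method for combining P values
#'
#' @param p_values non-empty numeric vector of P values in (0, 1].
#' @return list(score = -2 sum(log p), df = 2n, combined_p = upper-tail
#'   chi-squared probability).
#' @export
fisher_combine <- function(p_values) {
  if (length(p_values) == 0) stop("no P values to combine")
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stop("P values must lie in (0, 1]")
  }
  score <- -2 * sum(log(p_values))
  df <- 2 * length(p_values)
  list(score = score, df = df,
       combined_p = stats::pchisq(score, df, lower.tail = FALSE))
}

#' Tile scaffolds with non-overlapping windows
#'
#' Windows are anchored at position 0 of each scaffold and never span
#' scaffold boundaries; the last window of a scaffold is clipped to its
#' length.
#'
#' @param scaffold_lengths named numeric vector.
#' @param width window width in bp (default 1e5).
#' @return interval data frame.
#' @export
tile_windows <- function(scaffold_lengths, width = 1e5) {
  out <- lapply(names(scaffold_lengths), function(scaf) {
    len <- scaffold_lengths[[scaf]]
    starts <- seq(0, max(0, len - 1), by = width)
    intervals(rep(scaf, length(starts)), starts, pmin(starts + width, len))
  })
  do.call(rbind, out)
}

#' Composite scan over windows
#'
#' @param stat_tables named list of per-SNP statistic tables, one per
#'   (population, statistic) combination. Each table needs columns
#'   `scaffold`, `pos` and `value`; larger values must mean stronger
#'   evidence of selection. Quantiles are computed genome-wide per table
#'   with the mid-rank convention.
#' @param scaffold_lengths named numeric vector defining the window tiling.
#' @param width window width in bp (default 1e5).
#' @return data.frame of windows, sorted by combined_p, with columns
#'   scaffold, start, end, n_combos, composite_score, df, combined_p, plus
#'   per-combination columns `q_<name>` and `s_<name>`. Windows with no
#'   contributing combination have NA score and combined_p.
#' @export
composite_scan <- function(stat_tables, scaffold_lengths, width = 1e5) {
  stopifnot(length(stat_tables) >= 1, !is.null(names(stat_tables)))
  win <- tile_windows(scaffold_lengths, width)
  n_win <- nrow(win)
  combo_q <- matrix(NA_real_, n_win, length(stat_tables))
  combo_s <- matrix(0L, n_win, length(stat_tables))
  for (k in seq_along(stat_tables)) {
    tab <- stat_tables[[k]]
    q <- midrank_quantiles(tab$value)
    ok <- !is.na(q)
    if (!any(ok)) next
    wi <- floor(tab$pos[ok] / width) + 1L
    key <- paste0(tab$scaffold[ok], ":", (wi - 1) * width)
    win_key <- paste0(win$scaffold, ":", win$start)
    idx <- match(key, win_key)
    valid <- !is.na(idx)
    qmax <- tapply(q[ok][valid], idx[valid], max)
    cnt <- tapply(q[ok][valid], idx[valid], length)
    rows <- as.integer(names(qmax))
    combo_q[rows, k] <- qmax
    combo_s[rows, k] <- as.integer(cnt)
  }
  adj <- adjusted_p(combo_q, combo_s)
  # Fisher combination per window over combinations with s >= 1; the
  # quantile convention keeps every adjusted p inside (0, 1)
  score <- rep(NA_real_, n_win)
  dfree <- rep(NA_integer_, n_win)
  comb_p <- rep(NA_real_, n_win)
  has <- !is.na(adj)
  n_combos <- rowSums(has)
  use <- n_combos > 0
  if (any(use)) {
    lp <- ifelse(has, log(pmax(adj, .Machine$double.xmin)), 0)
    score[use] <- -2 * rowSums(lp)[use]
    dfree[use] <- 2L * n_combos[use]
    comb_p[use] <- stats::pchisq(score[use], dfree[use], lower.tail = FALSE)
  }
  out <- cbind(
    win,
    data.frame(n_combos = n_combos, composite_score = score, df = dfree,
               combined_p = comb_p)
  )
  qdf <- as.data.frame(combo_q)
  names(qdf) <- paste0("q_", names(stat_tables))
  sdf <- as.data.frame(combo_s)
  names(sdf) <- paste0("s_", names(stat_tables))
  out <- cbind(out, qdf, sdf)
  out[order(out$combined_p), , drop = FALSE]
}

#' Combined P value of candidate regions
#'
#' A region's combined P value is the minimum over the grid windows that
#' overlap it.
#'
#' @param window_stats output of [composite_scan()].
#' @param regions interval data frame of candidate regions.
#' @return numeric vector, one value per region (NA if no overlapping window
#'   has a combined P).
#' @export
region_combined_p <- function(window_stats, regions) {
  vapply(seq_len(nrow(regions)), function(i) {
    reg <- regions[i, , drop = FALSE]
    ov <- .iv_overlaps_any(window_stats[c("scaffold", "start", "end")], reg)
    vals <- window_stats$combined_p[ov]
    if (all(is.na(vals))) NA_real_ else min(vals, na.rm = TRUE)
  }, numeric(1))
}
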