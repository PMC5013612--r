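#' Interval utilities
#'
#' Genomic intervals are plain data frames with columns `scaffold`, `start`,
#' `end`, interpreted as 0-based half-open `[start, end)` ranges. All interval
#' algebra is delegated to IRanges/GenomicRanges; coordinates are converted to
#' 1-based closed form at the boundary and back.
#'
#' @name intervals
NULL

#' Construct an interval table
#'
#' @param scaffold character vector of scaffold names.
#' @param start,end integer vectors, 0-based half-open.
#' @return data.frame with columns scaffold, start, end.
#' @export
intervals <- function(scaffold = character(), start = integer(),
                      end = integer()) {
  df <- data.frame(scaffold = as.character(scaffold),
                   start = as.numeric(start), end = as.numeric(end),
                   stringsAsFactors = FALSE)
  if (nrow(df) && any(df$start < 0 | df$start >= df$end)) {
    stop("intervals require 0 <= start < end")
  }
  df
}

# data.frame (0-based half-open) -> GRanges (1-based closed)
.iv_to_gr <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$scaffold,
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end)
  )
}

# GRanges -> data.frame (0-based half-open), sorted by (scaffold, start)
.gr_to_iv <- function(gr) {
  gr <- GenomicRanges::sort(gr)
  df <- data.frame(
    scaffold = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  df[order(df$scaffold, df$start), , drop = FALSE]
}

#' Merge overlapping intervals
#'
#' Overlapping or book-ended intervals on the same scaffold are unioned.
#'
#' @param df interval data frame (scaffold, start, end).
#' @return merged interval data frame sorted by (scaffold, start).
#' @export
merge_intervals <- function(df) {
  if (nrow(df) == 0) return(intervals())
  .gr_to_iv(GenomicRanges::reduce(.iv_to_gr(df)))
}

#' Intersect interval sets across populations
#'
#' Computes the per-scaffold set intersection of two or more interval sets:
#' the genomic positions covered by every set. The operation is commutative
#' and associative in the sets.
#'
#' @param interval_lists list (length >= 2) of interval data frames, one per
#'   population.
#' @return interval data frame of regions covered by all sets.
#' @export
intersect_interval_sets <- function(interval_lists) {
  if (length(interval_lists) < 2) {
    stop("need interval sets from at least two populations")
  }
  grs <- lapply(interval_lists, function(df) {
    GenomicRanges::reduce(.iv_to_gr(df))
  })
  # sets with disjoint scaffolds intersect to empty; the seqlevel-mismatch
  # warning GenomicRanges emits for that case is expected here
  out <- suppressWarnings(Reduce(GenomicRanges::intersect, grs))
  .gr_to_iv(out)
}

#' Write intervals to a BED file
#'
#' Overlapping intervals are merged before writing. BED is natively 0-based
#' half-open, so coordinates are written unchanged.
#'
#' @param df interval data frame.
#' @param path output file path.
#' @export
write_intervals <- function(df, path) {
  merged <- merge_intervals(df)
  lines <- sprintf("%s\t%d\t%d", merged$scaffold,
                   as.integer(merged$start), as.integer(merged$end))
  writeLines(lines, path)
  invisible(merged)
}

#' Read a BED3+ file as an interval table
#'
#' @param path BED file path.
#' @return interval data frame.
#' @export
read_intervals <- function(path) {
  if (file.size(path) == 0) return(intervals())
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  intervals(df[[1]], df[[2]], df[[3]])
}

#' Read a gene annotation BED file
#'
#' Expects BED4+ with columns scaffold, start, end, gene_id and, in the last
#' column, a comma-separated list of GO-term labels (may be "." or empty for
#' none). BED6 files with score/strand columns are accepted.
#'
#' @param path annotation file path.
#' @return data.frame with columns scaffold, start, end, gene_id and a
#'   list-column `go_terms`.
#' @export
read_gene_annotation <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 4) stop("gene annotation needs at least 4 BED columns")
  terms_col <- if (ncol(df) >= 5) df[[ncol(df)]] else rep(".", nrow(df))
  go <- lapply(as.character(terms_col), function(x) {
    if (is.na(x) || x %in% c(".", "")) character() else
      trimws(strsplit(x, ",", fixed = TRUE)[[1]])
  })
  out <- data.frame(scaffold = as.character(df[[1]]),
                    start = as.numeric(df[[2]]), end = as.numeric(df[[3]]),
                    gene_id = as.character(df[[4]]),
                    stringsAsFactors = FALSE)
  out$go_terms <- go
  out
}

#' Write a gene annotation table as BED6+
#'
#' @param genes data.frame as returned by [read_gene_annotation()].
#' @param path output path.
#' @export
write_gene_annotation <- function(genes, path) {
  terms <- vapply(genes$go_terms, function(x) {
    if (length(x) == 0) "." else paste(x, collapse = ",")
  }, character(1))
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t+\t%s", genes$scaffold,
                   as.integer(genes$start), as.integer(genes$end),
                   genes$gene_id, terms)
  writeLines(lines, path)
  invisible(path)
}

# TRUE for each row of `df` overlapping any interval in `regions`
.iv_overlaps_any <- function(df, regions) {
  if (nrow(df) == 0 || nrow(regions) == 0) return(logical(nrow(df)))
  hits <- GenomicRanges::countOverlaps(.iv_to_gr(df), .iv_to_gr(regions))
  hits > 0
}
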