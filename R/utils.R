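#' @importFrom stats cor cor.test cutree dist hclust mad median ppois
#'   quantile rbeta rlnorm rnorm rpois runif sd setNames wilcox.test
#'   binom.test rbinom
#' @importFrom utils read.table write.table head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

#' Convert a 0-based half-open interval data frame to GRanges
#'
#' Interval data frames throughout the package use BED semantics: `chrom`,
#' `start` (0-based, inclusive), `end` (exclusive). GRanges is 1-based
#' inclusive, so `start + 1` on the way in.
#'
#' @param df data.frame with columns chrom, start, end
#' @return a [GenomicRanges::GRanges]
#' @keywords internal
as_granges <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

## overlap hits between two 0-based half-open interval frames
overlap_pairs <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(data.frame(query = integer(0), subject = integer(0)))
  }
  h <- GenomicRanges::findOverlaps(as_granges(a), as_granges(b))
  data.frame(query = S4Vectors::queryHits(h),
             subject = S4Vectors::subjectHits(h))
}

## indices of rows in `a` overlapping >=1 row of `b`
overlaps_any <- function(a, b) {
  res <- rep(FALSE, nrow(a))
  res[unique(overlap_pairs(a, b)$query)] <- TRUE
  res
}

## merge overlapping/abutting intervals; returns chrom/start/end frame
merge_intervals <- function(df) {
  if (nrow(df) == 0L) return(df[, c("chrom", "start", "end")])
  gr <- GenomicRanges::reduce(as_granges(df))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

## aggregate a fine-resolution track (chrom,start,end,value) to per-bin means
## on a single chromosome; returns a numeric vector of length n_bins
bin_track <- function(track, chrom, bin_size, n_bins) {
  tr <- track[track$chrom == chrom, , drop = FALSE]
  out <- rep(NA_real_, n_bins)
  if (nrow(tr) == 0L) return(out)
  mid <- (tr$start + tr$end) / 2
  bin <- pmin(floor(mid / bin_size), n_bins - 1L) + 1L
  sums <- tapply(tr$value, bin, mean)
  out[as.integer(names(sums))] <- as.numeric(sums)
  out
}

## per-bin mean expression for genes whose midpoint falls in the bin
gene_expression_track <- function(genes, expression, chrom, bin_size, n_bins) {
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  out <- rep(NA_real_, n_bins)
  if (nrow(g) == 0L) return(out)
  expr <- expression$value[match(g$gene_id, expression$gene_id)]
  bin <- pmin(floor(floor((g$start + g$end) / 2) / bin_size), n_bins - 1L) + 1L
  keep <- !is.na(expr)
  if (!any(keep)) return(out)
  m <- tapply(expr[keep], bin[keep], mean)
  out[as.integer(names(m))] <- as.numeric(m)
  out
}
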