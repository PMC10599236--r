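#' Intersect SNPs with regulatory elements
#'
#' SNP positions are 1-based; elements are 0-based half-open, so a SNP at
#' position `p` lies inside `[s, e)` iff `s <= p - 1 < e`. A SNP may hit
#' several overlapping elements; all assignments are recorded.
#'
#' @param snps frame (chrom, pos_1based, id)
#' @param elements frame (chrom, start, end, ...)
#' @param chrom_sizes optional data.frame (chrom, length); SNPs beyond the
#'   chromosome length raise an error
#' @return data.frame (snp_idx, element_idx)
#' @export
intersect_snps <- function(snps, elements, chrom_sizes = NULL) {
  if (!is.null(chrom_sizes)) {
    len <- chrom_sizes$length[match(snps$chrom, chrom_sizes$chrom)]
    bad <- which(is.na(len) | snps$pos_1based > len | snps$pos_1based < 1)
    if (length(bad))
      stop2("SNP ", snps$id[bad[1]], " outside chromosome bounds")
  }
  sdf <- data.frame(chrom = snps$chrom, start = snps$pos_1based - 1,
                    end = snps$pos_1based)
  hits <- overlap_pairs(sdf, elements)
  data.frame(snp_idx = hits$query, element_idx = hits$subject)
}

#' SNP density and enrichment per element class
#'
#' Elements are merged per class before length summation (overlaps
#' collapsed so no kb is counted twice); the class density is SNPs per kb
#' of merged element space, and the enrichment is that density over the
#' genome-wide density `n_total_snps / (genome_length / 1000)`.
#'
#' @param snps frame (chrom, pos_1based, id)
#' @param elements frame (chrom, start, end, element_class)
#' @param genome_length_bp total genome length in bp
#' @param chrom_sizes optional bound check passed to [intersect_snps()]
#' @return data.frame, one row per class: class_name, n_snps,
#'   n_elements_hit, total_element_kb, density_snps_per_kb,
#'   genomewide_density, enrichment
#' @export
snp_density <- function(snps, elements, genome_length_bp,
                        chrom_sizes = NULL) {
  gw <- nrow(snps) / (genome_length_bp / 1000)
  out <- lapply(unique(elements$element_class), function(cls) {
    el <- merge_intervals(elements[elements$element_class == cls, ,
                                   drop = FALSE])
    kb <- sum(el$end - el$start) / 1000
    hits <- intersect_snps(snps, el, chrom_sizes)
    n_snps <- length(unique(hits$snp_idx))
    dens <- if (kb > 0) n_snps / kb else NA_real_
    data.frame(class_name = cls, n_snps = n_snps,
               n_elements_hit = length(unique(hits$element_idx)),
               total_element_kb = kb,
               density_snps_per_kb = dens,
               genomewide_density = gw,
               enrichment = dens / gw)
  })
  do.call(rbind, out)
}
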