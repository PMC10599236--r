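#' Strand-aware promoter windows
#'
#' The promoter of a gene is the 3000 bp (by default) immediately upstream
#' of its TSS: `[TSS-3000, TSS)` for + genes and `[TES, TES+3000)` for -
#' genes (whose TSS is the interval end). Windows are clipped at
#' chromosome bounds.
#'
#' @param genes gene frame (chrom, start, end, strand, gene_id)
#' @param upstream window size in bp (default 3000)
#' @param chrom_sizes data.frame (chrom, length)
#' @return frame (chrom, start, end, gene_id; 0-based half-open)
#' @export
promoter_windows <- function(genes, upstream = 3000, chrom_sizes) {
  if (!nrow(genes))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), gene_id = character(0)))
  len <- chrom_sizes$length[match(genes$chrom, chrom_sizes$chrom)]
  plus <- genes$strand != "-"
  start <- ifelse(plus, genes$start - upstream, genes$end)
  end <- ifelse(plus, genes$start, genes$end + upstream)
  start <- pmax(0, start)
  end <- pmin(len, end)
  keep <- end > start
  data.frame(chrom = genes$chrom, start = start, end = end,
             gene_id = genes$gene_id)[keep, , drop = FALSE]
}

#' Classify ATAC peaks into ACR classes
#'
#' A peak overlapping (>= 1 bp) any promoter window is a `promoter_ACR`
#' (promoter precedence); otherwise a peak overlapping any gene body is an
#' `other_ACR`; all remaining peaks are `distal_ACR`. The three classes
#' partition the peak set.
#'
#' @param atac_peaks peak frame (chrom, start, end, ...)
#' @param genes gene frame with strand
#' @param chrom_sizes data.frame (chrom, length)
#' @param upstream promoter window size (default 3000)
#' @return `atac_peaks` with an `element_class` column
#' @export
classify_acrs <- function(atac_peaks, genes, chrom_sizes, upstream = 3000) {
  pw <- promoter_windows(genes, upstream, chrom_sizes)
  in_prom <- overlaps_any(atac_peaks, pw)
  in_gene <- overlaps_any(atac_peaks, genes)
  atac_peaks$element_class <- ifelse(in_prom, "promoter_ACR",
                                     ifelse(in_gene, "other_ACR",
                                            "distal_ACR"))
  atac_peaks
}

#' Define enhancers and active enhancers
#'
#' Enhancers are H3K27ac peaks falling in distal intergenic space (no
#' gene-body and no promoter-window overlap, the same geometry as
#' [classify_acrs()]). An enhancer is active iff it overlaps (>= 1 bp) any
#' ATAC peak.
#'
#' @param h3k27ac_peaks H3K27ac peak frame
#' @param genes gene frame with strand
#' @param chrom_sizes data.frame (chrom, length)
#' @param upstream promoter window size (default 3000)
#' @return the distal subset of `h3k27ac_peaks` with `element_class =
#'   "enhancer"`
#' @export
define_enhancers <- function(h3k27ac_peaks, genes, chrom_sizes,
                             upstream = 3000) {
  cls <- classify_acrs(h3k27ac_peaks, genes, chrom_sizes, upstream)
  enh <- cls[cls$element_class == "distal_ACR", , drop = FALSE]
  enh$element_class <- "enhancer"
  rownames(enh) <- NULL
  enh
}

#' @rdname define_enhancers
#' @param enhancers a [define_enhancers()] result
#' @param atac_peaks ATAC peak frame
#' @return `mark_active()`: `enhancers` with a logical `active` column and
#'   attribute `active_fraction`
#' @export
mark_active <- function(enhancers, atac_peaks) {
  enhancers$active <- overlaps_any(enhancers, atac_peaks)
  attr(enhancers, "active_fraction") <-
    if (nrow(enhancers)) mean(enhancers$active) else NA_real_
  enhancers
}

#' Link enhancers to genes through loops
#'
#' For each loop, an anchor overlapping at least one enhancer marks that
#' anchor; genes whose body or promoter window overlaps the *other*
#' anchor are linked to those enhancers (loop-mediated only: an enhancer
#' and a gene on the same anchor with an empty partner anchor yield no
#' link). Reports the links, the number of distinct loop anchors
#' containing enhancers, and the number of distinct linked genes.
#'
#' @param enhancers enhancer frame
#' @param loops loop frame
#' @param genes gene frame with strand and `gene_id`
#' @param chrom_sizes data.frame (chrom, length)
#' @param upstream promoter window size (default 3000)
#' @return list with `links` (loop_idx, enhancer_idx, gene_id),
#'   `n_enhancer_anchors`, `n_genes`
#' @export
link_enhancer_genes <- function(enhancers, loops, genes, chrom_sizes,
                                upstream = 3000) {
  empty <- list(links = data.frame(loop_idx = integer(0),
                                   enhancer_idx = integer(0),
                                   gene_id = character(0)),
                n_enhancer_anchors = 0L, n_genes = 0L)
  if (!nrow(loops) || !nrow(enhancers)) return(empty)
  anchor_frame <- function(side) {
    data.frame(chrom = loops$chrom,
               start = loops[[paste0("anchor", side, "_start")]],
               end = loops[[paste0("anchor", side, "_end")]])
  }
  a <- list(anchor_frame(1), anchor_frame(2))
  pw <- promoter_windows(genes, upstream, chrom_sizes)
  gene_targets <- rbind(
    data.frame(chrom = genes$chrom, start = genes$start, end = genes$end,
               gene_id = genes$gene_id),
    pw[, c("chrom", "start", "end", "gene_id")])
  enh_hits <- lapply(a, function(x) overlap_pairs(x, enhancers))
  gene_hits <- lapply(a, function(x) overlap_pairs(x, gene_targets))
  links <- list()
  anchors <- list()
  for (side in 1:2) {
    other <- 3 - side
    eh <- enh_hits[[side]]; gh <- gene_hits[[other]]
    common <- intersect(unique(eh$query), unique(gh$query))
    for (lp in common) {
      eidx <- eh$subject[eh$query == lp]
      gids <- unique(gene_targets$gene_id[gh$subject[gh$query == lp]])
      links[[length(links) + 1L]] <-
        expand.grid(loop_idx = lp, enhancer_idx = eidx, gene_id = gids,
                    stringsAsFactors = FALSE)
      anchors[[length(anchors) + 1L]] <-
        a[[side]][lp, c("chrom", "start", "end")]
    }
  }
  if (!length(links)) return(empty)
  links <- unique(do.call(rbind, links))
  anchors <- unique(do.call(rbind, anchors))
  list(links = links,
       n_enhancer_anchors = nrow(anchors),
       n_genes = length(unique(links$gene_id)))
}

#' Average read-depth profile around TSSs
#'
#' Strand-oriented mean depth at offsets `-flank .. +flank` around each
#' TSS, at the resolution of the depth track. Genes whose window runs off
#' the chromosome contribute `NA` at the missing positions and are
#' excluded position-wise.
#'
#' @param depth_track frame (chrom, start, end, value) on a fixed step
#' @param genes gene frame with strand
#' @param flank flank size in bp (default 2000)
#' @return list with `offsets` (bp, centre of each step), `values` (mean
#'   depth), `n_features`, `peak_offset`
#' @export
tss_metaprofile <- function(depth_track, genes, flank = 2000) {
  step <- depth_track$end[1] - depth_track$start[1]
  k <- floor(flank / step)
  vecs <- split(depth_track$value, depth_track$chrom)
  mat <- matrix(NA_real_, nrow(genes), 2 * k + 1)
  for (g in seq_len(nrow(genes))) {
    v <- vecs[[genes$chrom[g]]]
    if (is.null(v)) next
    tss <- if (genes$strand[g] == "-") genes$end[g] else genes$start[g]
    w <- floor(tss / step)
    idx <- (w - k):(w + k)
    ok <- idx >= 0 & idx < length(v)
    row <- rep(NA_real_, 2 * k + 1)
    row[ok] <- v[idx[ok] + 1]
    if (genes$strand[g] == "-") row <- rev(row)
    mat[g, ] <- row
  }
  values <- colMeans(mat, na.rm = TRUE)
  offsets <- (-k:k) * step
  list(offsets = offsets, values = values, n_features = nrow(genes),
       peak_offset = offsets[which.max(values)])
}

#' Methylation meta-profile around peaks
#'
#' Peak bodies are rescaled to `body_positions` positions; flanks are kept
#' at track resolution. Returns per-context mean profiles plus body and
#' flank means.
#'
#' @param meth_tracks named list of methylation tracks (chrom, start, end,
#'   value in `[0,1]`), one per context
#' @param peaks peak frame
#' @param flank flank size in bp (default 2000)
#' @param body_positions positions the body is rescaled to (default 100)
#' @return named list per context: `profile` (numeric), `body_mean`,
#'   `flank_up_mean`, `flank_down_mean`
#' @export
peak_methylation_profile <- function(meth_tracks, peaks, flank = 2000,
                                     body_positions = 100) {
  if (!nrow(peaks)) stop2("empty peak set")
  lapply(meth_tracks, function(track) {
    step <- track$end[1] - track$start[1]
    k <- floor(flank / step)
    vecs <- split(track$value, track$chrom)
    up <- matrix(NA_real_, nrow(peaks), k)
    body <- matrix(NA_real_, nrow(peaks), body_positions)
    down <- matrix(NA_real_, nrow(peaks), k)
    for (p in seq_len(nrow(peaks))) {
      v <- vecs[[peaks$chrom[p]]]
      if (is.null(v)) next
      w0 <- floor(peaks$start[p] / step)
      w1 <- floor((peaks$end[p] - 1) / step)
      ui <- (w0 - k):(w0 - 1); ok <- ui >= 0 & ui < length(v)
      up[p, ok] <- v[ui[ok] + 1]
      di <- (w1 + 1):(w1 + k); ok <- di >= 0 & di < length(v)
      down[p, ok] <- v[di[ok] + 1]
      bv <- v[(max(0, w0):min(length(v) - 1, w1)) + 1]
      body[p, ] <- if (length(bv) == 1) rep(bv, body_positions)
        else stats::approx(seq_along(bv), bv, n = body_positions)$y
    }
    profile <- c(colMeans(up, na.rm = TRUE), colMeans(body, na.rm = TRUE),
                 colMeans(down, na.rm = TRUE))
    list(profile = profile,
         body_mean = mean(body, na.rm = TRUE),
         flank_up_mean = mean(up, na.rm = TRUE),
         flank_down_mean = mean(down, na.rm = TRUE))
  })
}

#' Expression contrast between genes with and without promoter ACRs
#'
#' Genes are split by whether at least one promoter-classified ATAC peak
#' overlaps their promoter window; group medians and a two-sided Wilcoxon
#' rank-sum p-value are reported.
#'
#' @param genes gene frame with strand and `gene_id`
#' @param promoter_acrs peak frame (typically the `promoter_ACR` subset of
#'   [classify_acrs()])
#' @param expression frame (gene_id, value)
#' @param chrom_sizes data.frame (chrom, length)
#' @param upstream promoter window size (default 3000)
#' @return list with `median_with`, `median_without`, `n_with`,
#'   `n_without`, `p_value`, `flag`
#' @export
promoter_acr_expression <- function(genes, promoter_acrs, expression,
                                    chrom_sizes, upstream = 3000) {
  pw <- promoter_windows(genes, upstream, chrom_sizes)
  hit_genes <- unique(pw$gene_id[overlaps_any(pw, promoter_acrs)])
  expr <- expression$value[match(genes$gene_id, expression$gene_id)]
  with <- expr[genes$gene_id %in% hit_genes]
  without <- expr[!genes$gene_id %in% hit_genes]
  if (!length(with) || !length(without))
    return(list(median_with = median(with), median_without = median(without),
                n_with = length(with), n_without = length(without),
                p_value = NA_real_, flag = "undefined"))
  wt <- suppressWarnings(wilcox.test(with, without))
  list(median_with = median(with), median_without = median(without),
       n_with = length(with), n_without = length(without),
       p_value = wt$p.value, flag = "ok")
}

#' Two-sample differential accessibility over peaks
#'
#' Per-peak read counts are taken from the two depth tracks, scaled to
#' counts per million, and compared as `log2((cpm1 + pc) / (cpm2 + pc))`.
#' A peak is differential iff `|log2 ratio| >= lfc_threshold` and the
#' two-sided exact rate test (binomial conditional on the summed count,
#' success probability `lib1 / (lib1 + lib2)`) gives `p < alpha`.
#'
#' @param depth_sample1,depth_sample2 depth tracks (chrom, start, end,
#'   value)
#' @param peaks peak frame
#' @param pseudocount added to both CPMs (default 0.5)
#' @param lfc_threshold minimum absolute log2 ratio (default 1)
#' @param alpha rate-test significance level (default 0.05)
#' @return `peaks` with columns count1, count2, cpm1, cpm2, log2_ratio,
#'   p_value, differential
#' @export
differential_accessibility <- function(depth_sample1, depth_sample2, peaks,
                                       pseudocount = 0.5, lfc_threshold = 1,
                                       alpha = 0.05) {
  lib1 <- sum(depth_sample1$value)
  lib2 <- sum(depth_sample2$value)
  if (lib1 <= 0 || lib2 <= 0) stop2("zero library size")
  count_in <- function(track) {
    hits <- overlap_pairs(peaks, track)
    cnt <- numeric(nrow(peaks))
    if (nrow(hits)) {
      s <- tapply(track$value[hits$subject], hits$query, sum)
      cnt[as.integer(names(s))] <- as.numeric(s)
    }
    round(cnt)
  }
  c1 <- count_in(depth_sample1)
  c2 <- count_in(depth_sample2)
  cpm1 <- c1 / lib1 * 1e6
  cpm2 <- c2 / lib2 * 1e6
  lfc <- log2((cpm1 + pseudocount) / (cpm2 + pseudocount))
  pr <- lib1 / (lib1 + lib2)
  pv <- vapply(seq_len(nrow(peaks)), function(i) {
    tot <- c1[i] + c2[i]
    if (tot == 0) return(1)
    binom.test(c1[i], tot, p = pr)$p.value
  }, numeric(1))
  peaks$count1 <- c1; peaks$count2 <- c2
  peaks$cpm1 <- cpm1; peaks$cpm2 <- cpm2
  peaks$log2_ratio <- lfc
  peaks$p_value <- pv
  peaks$differential <- abs(lfc) >= lfc_threshold & pv < alpha
  peaks
}
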