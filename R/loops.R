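#' Benjamini-Hochberg step-up q-values
#'
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1, returned in the
#' input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`
#' @return q-values, same length and order
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) stop2("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  q[order(o)]
}

#' Call chromatin loops with a donut local background
#'
#' A simplified single-resolution donut test. For every candidate pixel
#' (distance between `min_dist_bins` and `max_dist_bp`, both bins valid),
#' the local expectation is the decay expectation scaled by the ratio of
#' the donut-neighbourhood balanced mean to the donut-neighbourhood decay
#' mean. The p-value is the upper-tail Poisson probability of the observed
#' raw count given that expectation mapped back through the balancing
#' weights. BH-FDR is applied per chromosome; significant pixels must also
#' be enriched at least `donut_enrichment`-fold over the donut and
#' `lowerleft_enrichment`-fold over the lower-left neighbourhood.
#' 8-connected significant pixels are merged into one loop whose
#' representative is the most donut-enriched pixel; anchors are the
#' representative pixel's bins as bp intervals. A genuine loop enriches a
#' neighbourhood of pixels, not a single one, so clusters smaller than
#' `min_cluster_pixels` are discarded as isolated-pixel noise (the
#' singleton filter customary in donut-based callers).
#'
#' @param m a balanced [contact_matrix()] (raw counts retained inside)
#' @param min_dist_bins minimum pixel distance in bins (default 2)
#' @param max_dist_bp maximum anchor distance in bp (default 2e6)
#' @param outer_radius,inner_radius donut radii in bins (defaults 5 and 2)
#' @param q_threshold FDR threshold (default 0.05)
#' @param donut_enrichment,lowerleft_enrichment enrichment thresholds
#'   (defaults 1.75 and 1.5)
#' @param min_cluster_pixels minimum significant pixels per merged cluster
#'   (default 2; 1 disables the singleton filter)
#' @return data.frame of loops: chrom, anchor coordinates, pixel bins
#'   (0-based), observed raw count, local expectation, both enrichments,
#'   p and q
#' @export
call_loops <- function(m, min_dist_bins = 2L, max_dist_bp = 2e6,
                       outer_radius = 5L, inner_radius = 2L,
                       q_threshold = 0.05, donut_enrichment = 1.75,
                       lowerleft_enrichment = 1.5, min_cluster_pixels = 2L) {
  if (!m$balanced) stop2("matrix is not balanced; run ice_balance() first")
  nb <- n_bins(m)
  b <- balanced_counts(m)
  prof <- unclass(expected_by_distance(m))
  d <- abs(outer(seq_len(nb), seq_len(nb), "-"))
  e <- matrix(prof[d + 1], nb, nb)
  fin <- is.finite(b) & is.finite(e)
  b0 <- ifelse(fin, b, 0)
  e0 <- ifelse(fin, e, 0)
  v0 <- fin * 1

  shift_sum <- function(X, offsets) {
    S <- matrix(0, nb, nb)
    for (k in seq_len(nrow(offsets))) {
      di <- offsets[k, 1]; dj <- offsets[k, 2]
      si <- max(1, 1 - di):min(nb, nb - di)
      sj <- max(1, 1 - dj):min(nb, nb - dj)
      S[si, sj] <- S[si, sj] + X[si + di, sj + dj]
    }
    S
  }
  og <- as.matrix(expand.grid(di = -outer_radius:outer_radius,
                              dj = -outer_radius:outer_radius))
  cheb <- pmax(abs(og[, 1]), abs(og[, 2]))
  donut_off <- og[cheb > inner_radius & cheb <= outer_radius, , drop = FALSE]
  ll_off <- og[og[, 1] >= 1 & og[, 2] <= -1 & cheb > inner_radius &
                 cheb <= outer_radius, , drop = FALSE]

  db <- shift_sum(b0, donut_off); de <- shift_sum(e0, donut_off)
  dn <- shift_sum(v0, donut_off)
  lb <- shift_sum(b0, ll_off); le <- shift_sum(e0, ll_off)
  ln <- shift_sum(v0, ll_off)

  max_dist_bins <- floor(max_dist_bp / m$bin_size)
  cand <- which(upper.tri(b) & fin & d >= min_dist_bins &
                  d <= max_dist_bins & dn >= 10 & ln >= 3 &
                  de > 0 & le > 0, arr.ind = TRUE)
  if (nrow(cand) == 0L)
    return(empty_loop_frame(m$chrom))
  ci <- cand[, 1]; cj <- cand[, 2]
  idx <- cbind(ci, cj)
  ## decay-normalised local expectations: the donut (and lower-left) O/E
  ## ratio rescales the global decay expectation at this pixel's distance
  expected_local <- e[idx] * db[idx] / de[idx]
  expected_ll <- e[idx] * lb[idx] / le[idx]
  w <- m$weights
  lambda_raw <- expected_local / (w[ci] * w[cj])
  obs_raw <- m$counts[idx]
  p <- ppois(obs_raw - 1, lambda_raw, lower.tail = FALSE)
  q <- bh_fdr(p)
  enr_donut <- b[idx] / expected_local
  enr_ll <- b[idx] / expected_ll
  sig <- q <= q_threshold & enr_donut >= donut_enrichment &
    enr_ll >= lowerleft_enrichment & is.finite(enr_donut) & is.finite(enr_ll)
  if (!any(sig)) return(empty_loop_frame(m$chrom))

  si <- ci[sig]; sj <- cj[sig]
  comp <- connected_pixels(si, sj)
  clusters <- split(seq_along(si), comp)
  clusters <- clusters[lengths(clusters) >= min_cluster_pixels]
  if (!length(clusters)) return(empty_loop_frame(m$chrom))
  ## representative: the member pixel nearest the cluster centroid (ties
  ## broken by donut enrichment), so the reported anchor tracks the focus
  ## centre rather than the noisiest pixel
  enr_sig <- enr_donut[sig]
  keep <- vapply(clusters, function(members) {
    dc <- pmax(abs(si[members] - mean(si[members])),
               abs(sj[members] - mean(sj[members])))
    near <- members[dc < min(dc) + 1e-9]
    near[which.max(enr_sig[near])]
  }, integer(1))
  sel <- which(sig)[keep]
  bi <- ci[sel] - 1L; bj <- cj[sel] - 1L
  bs <- m$bin_size
  out <- data.frame(
    chrom = m$chrom,
    anchor1_start = bi * bs, anchor1_end = pmin((bi + 1) * bs, m$chrom_length),
    anchor2_start = bj * bs, anchor2_end = pmin((bj + 1) * bs, m$chrom_length),
    bin_i = bi, bin_j = bj,
    observed = obs_raw[sel], expected_local = expected_local[sel],
    enrichment_donut = enr_donut[sel], enrichment_lowerleft = enr_ll[sel],
    p = p[sel], q = q[sel])
  out <- out[order(out$bin_i, out$bin_j), ]
  rownames(out) <- NULL
  out
}

empty_loop_frame <- function(chrom) {
  data.frame(chrom = character(0), anchor1_start = numeric(0),
             anchor1_end = numeric(0), anchor2_start = numeric(0),
             anchor2_end = numeric(0), bin_i = integer(0), bin_j = integer(0),
             observed = numeric(0), expected_local = numeric(0),
             enrichment_donut = numeric(0), enrichment_lowerleft = numeric(0),
             p = numeric(0), q = numeric(0))
}

## label 8-connected components among pixels (i, j)
connected_pixels <- function(i, j) {
  n <- length(i)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      a <- queue[1]; queue <- queue[-1]
      nb <- which(comp == 0L & abs(i - i[a]) <= 1L & abs(j - j[a]) <= 1L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Classify loops by the genic state of their anchors
#'
#' An anchor is genic iff it overlaps at least 1 bp of any gene body
#' (strand ignored). Categories: `gene-gene`, `gene-intergenic`,
#' `intergenic-intergenic`.
#'
#' @param loops frame from [call_loops()] (possibly multi-chromosome)
#' @param genes gene frame (chrom, start, end)
#' @return `loops` with a `category` column added
#' @export
classify_loops <- function(loops, genes) {
  a1 <- data.frame(chrom = loops$chrom, start = loops$anchor1_start,
                   end = loops$anchor1_end)
  a2 <- data.frame(chrom = loops$chrom, start = loops$anchor2_start,
                   end = loops$anchor2_end)
  g1 <- overlaps_any(a1, genes)
  g2 <- overlaps_any(a2, genes)
  loops$category <- ifelse(g1 & g2, "gene-gene",
                           ifelse(g1 | g2, "gene-intergenic",
                                  "intergenic-intergenic"))
  loops
}

#' Loop count per gene
#'
#' Counts, per gene, the loops with at least one anchor overlapping the
#' gene body; a loop with both anchors on the same gene is counted once.
#'
#' @param loops loop frame
#' @param genes gene frame with `gene_id`
#' @return data.frame (gene_id, n_loops) covering every gene
#' @export
loops_per_gene <- function(loops, genes) {
  n <- setNames(integer(nrow(genes)), genes$gene_id)
  if (nrow(loops)) {
    a1 <- data.frame(chrom = loops$chrom, start = loops$anchor1_start,
                     end = loops$anchor1_end)
    a2 <- data.frame(chrom = loops$chrom, start = loops$anchor2_start,
                     end = loops$anchor2_end)
    h1 <- overlap_pairs(a1, genes)
    h2 <- overlap_pairs(a2, genes)
    hits <- unique(rbind(h1, h2))      # loop row x gene row, de-duplicated
    if (nrow(hits)) {
      tab <- table(hits$subject)
      n[as.integer(names(tab))] <- as.integer(tab)
    }
  }
  data.frame(gene_id = genes$gene_id, n_loops = unname(n))
}

#' Select genes with more than `min_loops` loops
#'
#' @param profiles frame from [loops_per_gene()]
#' @param min_loops strict lower bound (default 10: "more than 10")
#' @return character vector of gene ids
#' @export
select_multi_loop_genes <- function(profiles, min_loops = 10L) {
  profiles$gene_id[profiles$n_loops > min_loops]
}

#' Expression versus loop count
#'
#' Genes with at least one loop are binned by loop count (1, 2-5, 6-10,
#' >10); the per-bin median expression and the Spearman rank correlation
#' between loop count and expression (with p-value) are reported.
#'
#' @param profiles frame from [loops_per_gene()]
#' @param expression frame (gene_id, value)
#' @return list with `groups` (group, n, median_expression), `rho`,
#'   `p_value`, and `flag` ("ok" or "undefined" when fewer than two
#'   distinct loop counts are present)
#' @export
expression_by_loopcount <- function(profiles, expression) {
  df <- merge(profiles, expression, by = "gene_id")
  df <- df[df$n_loops >= 1, , drop = FALSE]
  grp <- cut(df$n_loops, breaks = c(0, 1, 5, 10, Inf),
             labels = c("1", "2-5", "6-10", ">10"))
  groups <- do.call(rbind, lapply(levels(grp), function(g) {
    v <- df$value[grp == g]
    if (!length(v)) return(NULL)
    data.frame(group = g, n = length(v), median_expression = median(v))
  }))
  if (length(unique(df$n_loops)) < 2 || sd(df$value) == 0) {
    rho <- if (nrow(df) && sd(df$value) == 0) 0 else NA_real_
    return(list(groups = groups, rho = rho, p_value = NA_real_,
                flag = "undefined"))
  }
  ct <- suppressWarnings(cor.test(df$n_loops, df$value, method = "spearman",
                                  exact = FALSE))
  list(groups = groups, rho = unname(ct$estimate), p_value = ct$p.value,
       flag = "ok")
}

#' Loop distance statistics
#'
#' Anchor mid-point distances, the fraction of loops within
#' `threshold_bp`, and a histogram at 50-kb bins.
#'
#' @param loops loop frame
#' @param threshold_bp distance threshold (default 400 kb)
#' @return list with `fraction_within`, `distances`, `histogram`
#'   (data.frame bin_start, count), and `flag`
#' @export
loop_distance_stats <- function(loops, threshold_bp = 400000) {
  if (!nrow(loops))
    return(list(fraction_within = NA_real_, distances = numeric(0),
                histogram = NULL, flag = "undefined"))
  mid1 <- (loops$anchor1_start + loops$anchor1_end) / 2
  mid2 <- (loops$anchor2_start + loops$anchor2_end) / 2
  dist_bp <- abs(mid2 - mid1)
  brk <- seq(0, max(dist_bp) + 50000, by = 50000)
  h <- hist(dist_bp, breaks = brk, plot = FALSE)
  list(fraction_within = mean(dist_bp <= threshold_bp),
       distances = dist_bp,
       histogram = data.frame(bin_start = head(brk, -1), count = h$counts),
       flag = "ok")
}

#' @importFrom graphics hist
NULL
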