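chrom_sizes_1 <- data.frame(chrom = "chr1", length = 1e6)

test_that("ACR classification applies window arithmetic and precedence", {
  genes <- data.frame(chrom = "chr1", start = 5000, end = 8000,
                      strand = "+", gene_id = "g1")
  peaks <- data.frame(chrom = "chr1",
                      start = c(2500, 6000, 100000),
                      end = c(3100, 6400, 100400))
  cls <- classify_acrs(peaks, genes, chrom_sizes_1)
  ## promoter window [2000, 5000) catches the first peak
  expect_identical(cls$element_class,
                   c("promoter_ACR", "other_ACR", "distal_ACR"))
  ## promoter precedence when a peak overlaps both window and body
  both <- data.frame(chrom = "chr1", start = 4900, end = 5200)
  expect_identical(classify_acrs(both, genes, chrom_sizes_1)$element_class,
                   "promoter_ACR")
  ## minus-strand promoter sits downstream of the gene end
  gneg <- data.frame(chrom = "chr1", start = 5000, end = 8000,
                     strand = "-", gene_id = "g2")
  pk <- data.frame(chrom = "chr1", start = 9000, end = 9200)
  expect_identical(classify_acrs(pk, gneg, chrom_sizes_1)$element_class,
                   "promoter_ACR")
  ## window clipped at the chromosome start, not an error
  gearly <- data.frame(chrom = "chr1", start = 1000, end = 2000,
                       strand = "+", gene_id = "g3")
  pw <- promoter_windows(gearly, 3000, chrom_sizes_1)
  expect_equal(pw$start, 0)
})

test_that("classification agrees with a brute-force overlap oracle", {
  set.seed(99)
  n <- 1000
  genes <- data.frame(chrom = sample(c("chr1", "chr2"), n, TRUE),
                      start = sample(0:990000, n),
                      strand = sample(c("+", "-"), n, TRUE),
                      gene_id = sprintf("g%04d", 1:n))
  genes$end <- genes$start + sample(500:5000, n, TRUE)
  sizes <- data.frame(chrom = c("chr1", "chr2"), length = c(1e6, 1e6))
  peaks <- data.frame(chrom = sample(c("chr1", "chr2"), n, TRUE),
                      start = sample(0:995000, n))
  peaks$end <- peaks$start + sample(100:2000, n, TRUE)
  cls <- classify_acrs(peaks, genes, sizes)
  pw <- promoter_windows(genes, 3000, sizes)
  in_prom <- brute_overlaps_any(peaks, pw)
  in_gene <- brute_overlaps_any(peaks, genes)
  oracle <- ifelse(in_prom, "promoter_ACR",
                   ifelse(in_gene, "other_ACR", "distal_ACR"))
  expect_identical(cls$element_class, oracle)
  expect_identical(sum(table(cls$element_class)), as.integer(n))
})

test_that("enhancer definition and the 1-bp active rule", {
  genes <- data.frame(chrom = "chr1", start = 5000, end = 8000,
                      strand = "+", gene_id = "g1")
  h3k <- data.frame(chrom = "chr1",
                    start = c(3000, 50000), end = c(4000, 51200))
  enh <- define_enhancers(h3k, genes, chrom_sizes_1)
  expect_equal(nrow(enh), 1L)          # promoter-window peak excluded
  expect_equal(enh$start, 50000)
  atac <- data.frame(chrom = "chr1", start = 51199, end = 51500)
  act <- mark_active(enh, atac)
  expect_true(act$active[1])           # 1-bp overlap suffices
  act2 <- mark_active(enh, data.frame(chrom = "chr1", start = 51200,
                                      end = 51500))
  expect_false(act2$active[1])         # abutment is not overlap
})

test_that("planted active-enhancer fraction is recovered exactly", {
  sim <- fixture_dataset(1)
  cs <- data.frame(chrom = chrom_names_of(sim),
                   length = sim$config$chrom_length_bp)
  enh <- define_enhancers(sim$layers$h3k27ac_peaks, sim$genome$genes, cs)
  enh <- mark_active(enh, sim$layers$atac_peaks)
  expect_equal(attr(enh, "active_fraction"),
               sim$config$active_enhancer_fraction)
  ## H3K27ac peaks are constructed longer than ATAC peaks
  expect_gt(median(sim$layers$h3k27ac_peaks$end -
                     sim$layers$h3k27ac_peaks$start),
            median(sim$layers$atac_peaks$end - sim$layers$atac_peaks$start))
})

test_that("enhancer-gene links are loop-mediated and de-duplicated", {
  cs <- chrom_sizes_1
  genes <- data.frame(chrom = "chr1", start = 50000, end = 53000,
                      strand = "+", gene_id = "g1")
  enh <- data.frame(chrom = "chr1", start = 10100, end = 10500)
  loop1 <- data.frame(chrom = "chr1", anchor1_start = 10000,
                      anchor1_end = 11000, anchor2_start = 50000,
                      anchor2_end = 51000)
  res <- link_enhancer_genes(enh, loop1, genes, cs)
  expect_equal(nrow(res$links), 1L)
  expect_identical(res$links$gene_id, "g1")
  ## same-anchor enhancer+gene with empty partner anchor: no link
  loop2 <- data.frame(chrom = "chr1", anchor1_start = 49000,
                      anchor1_end = 53500, anchor2_start = 200000,
                      anchor2_end = 201000)
  enh2 <- data.frame(chrom = "chr1", start = 49100, end = 49500)
  res2 <- link_enhancer_genes(enh2, loop2, genes, cs)
  expect_equal(nrow(res2$links), 0L)
  ## two loops sharing one enhancer anchor to two genes
  genes3 <- rbind(genes, data.frame(chrom = "chr1", start = 80000,
                                    end = 83000, strand = "+",
                                    gene_id = "g2"))
  loops3 <- rbind(loop1, data.frame(chrom = "chr1", anchor1_start = 10000,
                                    anchor1_end = 11000,
                                    anchor2_start = 80000,
                                    anchor2_end = 81000))
  res3 <- link_enhancer_genes(enh, loops3, genes3, cs)
  expect_identical(res3$n_enhancer_anchors, 1L)
  expect_identical(res3$n_genes, 2L)
})

test_that("fixture links recover planted enhancer-gene pairs", {
  sim <- fixture_dataset(1)
  cs <- data.frame(chrom = chrom_names_of(sim),
                   length = sim$config$chrom_length_bp)
  calls <- do.call(rbind, lapply(fixture_balanced(1), call_loops))
  enh <- mark_active(define_enhancers(sim$layers$h3k27ac_peaks,
                                      sim$genome$genes, cs),
                     sim$layers$atac_peaks)
  res <- link_enhancer_genes(enh, calls, sim$genome$genes, cs)
  expect_gt(res$n_enhancer_anchors, 0L)
  expect_gte(res$n_genes, res$n_enhancer_anchors * 0)
  expect_gt(nrow(res$links), 0L)
})

test_that("TSS meta-profile peaks at the TSS and honours strand", {
  ## uniform depth -> flat profile
  step <- 100
  track <- data.frame(chrom = "chr1", start = seq(0, 99900, step),
                      end = seq(0, 99900, step) + step, value = 7)
  genes <- data.frame(chrom = "chr1", start = 50000, end = 53000,
                      strand = "+", gene_id = "g1")
  mp <- tss_metaprofile(track, genes)
  expect_true(all(abs(mp$values - 7) < 1e-12))
  ## planted bump at the TSS of every fixture gene
  sim <- fixture_dataset(1)
  mp2 <- tss_metaprofile(sim$layers$atac_depth_sample1, sim$genome$genes)
  expect_lte(abs(mp2$peak_offset), 100)
  ## strand reversal: bump upstream of a + TSS appears mirrored for -
  track$value <- 7 + dnorm((track$start + 50) / 1000, 49.5, 0.2) * 100
  gneg <- data.frame(chrom = "chr1", start = 47000, end = 50000,
                     strand = "-", gene_id = "g2")
  mp_pos <- tss_metaprofile(track, genes)
  mp_neg <- tss_metaprofile(track, gneg)
  expect_equal(mp_pos$values, rev(mp_neg$values), tolerance = 1e-9)
})

test_that("methylation dips inside peak bodies on the fixture", {
  sim <- fixture_dataset(1)
  prof <- peak_methylation_profile(sim$layers$methylation,
                                   sim$layers$atac_peaks)
  for (ctx in names(prof)) {
    expect_lt(prof[[ctx]]$body_mean, prof[[ctx]]$flank_up_mean)
    expect_lt(prof[[ctx]]$body_mean, prof[[ctx]]$flank_down_mean)
  }
  ## constant methylation -> flat profile at the constant
  step <- 100
  flat <- data.frame(chrom = "chr1", start = seq(0, 99900, step),
                     end = seq(0, 99900, step) + step, value = 0.5)
  pk <- data.frame(chrom = "chr1", start = 50000, end = 51000)
  pf <- peak_methylation_profile(list(CG = flat), pk)
  expect_true(all(abs(pf$CG$profile - 0.5) < 1e-12))
  expect_error(peak_methylation_profile(list(CG = flat), pk[0, ]), "empty")
})

test_that("promoter-ACR genes express higher on the fixture", {
  sim <- fixture_dataset(1)
  cs <- data.frame(chrom = chrom_names_of(sim),
                   length = sim$config$chrom_length_bp)
  acrs <- classify_acrs(sim$layers$atac_peaks, sim$genome$genes, cs)
  res <- promoter_acr_expression(
    sim$genome$genes,
    acrs[acrs$element_class == "promoter_ACR", ],
    sim$layers$expression, cs)
  expect_identical(res$flag, "ok")
  expect_gt(res$median_with, res$median_without)
  expect_lt(res$p_value, 0.05)
})

test_that("differential accessibility flags exactly the planted peaks", {
  ## identity case: equal counts, equal libraries
  step <- 100
  tr <- data.frame(chrom = "chr1", start = seq(0, 99900, step),
                   end = seq(0, 99900, step) + step, value = 10)
  pk <- data.frame(chrom = "chr1", start = 1000, end = 2000)
  da0 <- differential_accessibility(tr, tr, pk)
  expect_equal(da0$log2_ratio, 0)
  expect_false(da0$differential)
  ## 100 vs 25 at equal library size: log2 ~ 2, differential
  tr2 <- tr; tr2$value[11:20] <- 100
  tr3 <- tr; tr3$value[11:20] <- 25
  extra2 <- sum(tr2$value) - sum(tr$value)
  tr2$value[500] <- tr2$value[500] - extra2 + (sum(tr3$value) - sum(tr$value))
  da <- differential_accessibility(tr2, tr3, pk)
  expect_equal(da$log2_ratio, 2, tolerance = 0.05)
  expect_true(da$differential)
  expect_error(differential_accessibility(tr, transform(tr, value = 0), pk),
               "library")
  ## fixture: the two planted peaks and nothing else among nulls
  hits <- 0L
  for (seed in 1:5) {
    sim <- fixture_dataset(seed)
    da <- differential_accessibility(sim$layers$atac_depth_sample1,
                                     sim$layers$atac_depth_sample2,
                                     sim$layers$atac_peaks)
    dp <- sim$layers$differential_peaks
    flagged <- da[da$differential, ]
    exact <- nrow(flagged) == 2 &&
      all(paste(flagged$chrom, flagged$start) %in%
            paste(dp$chrom, dp$start))
    hits <- hits + exact
  }
  expect_gte(hits, 4L)
})
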