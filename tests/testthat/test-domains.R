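## balanced two-block matrix: within-block value hi, between lo
two_block_matrix <- function(n = 20, junction = 10, hi = 4, lo = 1) {
  lab <- c(rep(1, junction), rep(2, n - junction))
  counts <- ifelse(outer(lab, lab, "=="), hi, lo)
  m <- contact_matrix(counts, "chr1", 100)
  m$balanced <- TRUE
  m$weights <- rep(1, n)
  m
}

test_that("insulation score has its unique minimum at a block junction", {
  m <- two_block_matrix()
  prof <- insulation_score(m, window_bins = 2)
  ## brute-force diamond oracle
  b <- m$counts
  oracle <- rep(NA_real_, 20)
  for (i in 3:18) oracle[i] <- mean(b[(i - 2):(i - 1), (i + 1):(i + 2)])
  oracle <- log2(oracle / mean(oracle, na.rm = TRUE))
  expect_equal(prof$score, oracle)
  expect_identical(which.min(prof$score), 10L)   # bin left of the junction
})

test_that("uniform matrices have zero insulation and no boundaries", {
  m <- contact_matrix(matrix(3, 20, 20), "chr1", 100)
  m$balanced <- TRUE; m$weights <- rep(1, 20)
  prof <- insulation_score(m, 3)
  expect_true(all(abs(prof$score[!is.na(prof$score)]) < 1e-12))
  expect_identical(nrow(call_boundaries(prof)), 0L)
  expect_error(insulation_score(m, 11), "half")
})

test_that("masked diamonds give undefined scores", {
  m <- two_block_matrix()
  ## bin 10's diamond is rows 8:9 x cols 11:12; masking both columns
  ## leaves it with no valid pixel
  m$valid[11:12] <- FALSE
  m$weights[11:12] <- NA
  prof <- insulation_score(m, 2)
  expect_true(is.na(prof$score[10]))
})

test_that("boundary prominence and tie rules behave as documented", {
  mk_prof <- function(score) structure(
    list(chrom = "chr1", window_bins = 1, bin_size = 100, score = score),
    class = "insulation_profile")
  ## V shape of depth 0.5 -> one boundary at the vertex
  v <- mk_prof(c(NA, 0.5, 0.25, 0, 0.25, 0.5, NA))
  b <- call_boundaries(v, 0.1)
  expect_identical(b$bin, 3L)
  expect_equal(b$strength, 0.5)
  ## monotone profile -> nothing
  expect_identical(nrow(call_boundaries(mk_prof(c(NA, 1:5 / 10, NA)), 0.1)), 0L)
  ## plateau of two equal minima keeps the left one
  p <- mk_prof(c(NA, 0.5, 0, 0, 0.5, NA))
  bp <- call_boundaries(p, 0.1)
  expect_identical(bp$bin, 2L)
  ## shallow dip below threshold is dropped
  expect_identical(
    nrow(call_boundaries(mk_prof(c(NA, 0.05, 0, 0.05, NA)), 0.1)), 0L)
})

test_that("TAD assembly applies end and minimum-size rules", {
  tads <- assemble_tads(c(10L, 20L), 30L)
  expect_equal(tads$start_bin, c(0L, 10L, 20L))
  expect_equal(tads$end_bin, c(10L, 20L, 30L))
  tads2 <- assemble_tads(c(10L, 11L), 30L, min_tad_bins = 3)
  expect_equal(nrow(tads2), 2L)                 # middle sliver dropped
  expect_false(any(tads2$end_bin - tads2$start_bin < 3))
})

test_that("planted TAD boundaries are recovered on the fixture", {
  hits <- 0; total <- 0
  for (seed in 1:2) {
    sim <- fixture_dataset(seed)
    for (ch in names(sim$contacts)) {
      tads <- call_tads(sim$contacts[[ch]])
      ## TADs tile without overlap and respect the size floor
      expect_true(all(tads$start_bin[-1] >= head(tads$end_bin, -1)))
      expect_true(all(tads$end_bin - tads$start_bin >= 3))
      called <- tads$start_bin[-1]
      planted <- sim$truth$tad_boundaries[[ch]]
      hits <- hits + sum(sapply(planted, function(b)
        any(abs(called - b) <= 1)))
      total <- total + length(planted)
    }
  }
  expect_gte(hits / total, 0.8)
})

test_that("coarser resolutions give no more TADs than finer ones", {
  sim <- fixture_dataset(1)
  res <- multi_resolution_tads(sim$contacts$chr1, factors = c(1, 2, 4))
  n <- sapply(res, nrow)
  expect_true(all(diff(n) <= 0))
})

test_that("marker matrix z-scores per-TAD means; correlations behave", {
  tads <- data.frame(start_bin = c(0L, 5L), end_bin = c(5L, 10L))
  tr1 <- c(rep(1, 5), rep(3, 5))
  tracks <- list(a = tr1, b = 2 * tr1 + 7, flat = rep(1, 10))
  mm <- tad_marker_matrix(tads, tracks)
  expect_equal(dim(mm), c(2L, 3L))
  expect_identical(attr(mm, "flagged"), "flat")
  mc <- marker_correlation(mm)
  expect_equal(mc["a", "b"], 1)                  # affine invariance
  expect_error(tad_marker_matrix(tads[1, ], tracks), "2 TADs")
})

test_that("clustering separates planted archetypes and assigns roles", {
  set.seed(8)
  arche <- rbind(matrix(rep(c(2, 2, -2), each = 10), 10) +
                   rnorm(30, 0, 0.05),          # active-ish
                 matrix(rep(c(-2, -2, 2), each = 10), 10) +
                   rnorm(30, 0, 0.05),          # repressive-ish
                 matrix(0, 10, 3) + rnorm(30, 0, 0.05))
  colnames(arche) <- c("h3k27ac", "expression", "cg")
  cl <- cluster_tads(arche, k = 3)
  planted <- rep(1:3, each = 10)
  ## 100% purity: one cluster per archetype
  expect_identical(length(unique(paste(cl$cluster, planted))), 3L)
  expect_true(all(cl$role[1:10] == "active"))
  expect_true(all(cl$role[11:20] == "repressive"))
  expect_true(all(cl$role[21:30] == "intermediate"))
  expect_error(cluster_tads(arche, k = 50), "exceeds")
  expect_error(cluster_tads(matrix(1, 4, 3,
                                   dimnames = list(NULL, c("a", "b", "c"))),
                            k = 2), "identical")
})

test_that("fixture TAD clusters order expression and methylation by role", {
  sim <- fixture_dataset(1)
  cfg <- sim$config
  nb <- as.integer(cfg$chrom_length_bp / cfg$bin_size_bp)
  rows <- list()
  expr_log <- transform(sim$layers$expression, value = log2(1 + value))
  for (ch in names(sim$contacts)) {
    tads <- call_tads(sim$contacts[[ch]])
    tracks <- list(
      gene_density = fixture_gene_density(sim, ch),
      h3k27ac = bin_track(sim$layers$h3k27ac_depth, ch, cfg$bin_size_bp, nb),
      atac = bin_track(sim$layers$atac_depth_sample1, ch, cfg$bin_size_bp, nb),
      expression = gene_expression_track(sim$genome$genes, expr_log, ch,
                                         cfg$bin_size_bp, nb),
      cg = bin_track(sim$layers$methylation$CG, ch, cfg$bin_size_bp, nb),
      chg = bin_track(sim$layers$methylation$CHG, ch, cfg$bin_size_bp, nb),
      chh = bin_track(sim$layers$methylation$CHH, ch, cfg$bin_size_bp, nb))
    raw <- sapply(names(tracks), function(nm)
      apply(tads, 1, function(td)
        mean(tracks[[nm]][(as.numeric(td["start_bin"]) + 1):
                            as.numeric(td["end_bin"])], na.rm = TRUE)))
    rows[[ch]] <- raw
  }
  z <- scale(do.call(rbind, rows))
  mc <- marker_correlation(z)
  expect_gt(mc["h3k27ac", "atac"], 0)
  expect_lt(mc["cg", "expression"], 0)
  cl <- cluster_tads(z, k = 3)
  by_role <- function(col) tapply(z[, col], cl$role, mean, na.rm = TRUE)
  expr <- by_role("expression")
  cg <- by_role("cg")
  expect_gte(expr["active"], max(expr))
  expect_gte(cg["repressive"], max(cg))
  ## permutation stability: shuffling TAD order never changes role content
  perm <- sample(nrow(z))
  cl2 <- cluster_tads(z[perm, ], k = 3)
  expect_identical(cl2$role, cl$role[perm])
})

test_that("gene-in-TAD lookup requires full containment", {
  tads <- data.frame(start = c(0, 5000), end = c(5000, 9000))
  expect_equal(locate_gene_tad(list(start = 1000, end = 2000), tads)$start, 0)
  expect_null(locate_gene_tad(list(start = 4000, end = 6000), tads))
  expect_null(locate_gene_tad(list(start = 9500, end = 9800), tads))
})
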