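test_that("configuration invariants are enforced", {
  expect_error(synthetic_config(chrom_length_bp = 5e6 + 1), "divisible")
  expect_error(synthetic_config(plaid_amplitude = 1), "plaid_amplitude")
  expect_error(synthetic_config(coverage_scale = 0), "coverage_scale")
  expect_error(synthetic_config(tad_contrast = 0.5), "tad_contrast")
})

test_that("planted truth respects positional and spacing rules", {
  truth <- make_truth(synthetic_config(rng_seed = 3))
  for (ch in names(truth$compartment_labels)) {
    lab <- truth$compartment_labels[[ch]]
    nb <- length(lab)
    dec <- ceiling(nb / 10)
    ## A concentrated in telomeric deciles, B around the midpoint
    expect_true(all(lab[1:dec] == "A"))
    expect_true(all(lab[(nb - dec + 1):nb] == "A"))
    expect_true(all(lab[(nb / 2 - 5):(nb / 2 + 5)] == "B"))
    b <- truth$tad_boundaries[[ch]]
    expect_true(all(diff(b) > 0))
  }
  expect_true(all(truth$loops$j - truth$loops$i >= 2))
  ## pixel separation guarantees non-merging boosted neighbourhoods
  for (ch in unique(truth$loops$chrom)) {
    lp <- truth$loops[truth$loops$chrom == ch, ]
    d <- as.matrix(pmax(abs(outer(lp$i, lp$i, "-")),
                        abs(outer(lp$j, lp$j, "-"))))
    diag(d) <- Inf
    expect_gte(min(d), 4)
  }
})

test_that("same seed reproduces byte-identical files; layers are in range", {
  cfg <- synthetic_config(rng_seed = 42)
  d1 <- file.path(tempdir(), "sim_a")
  d2 <- file.path(tempdir(), "sim_b")
  write_dataset(simulate_dataset(cfg), d1)
  write_dataset(simulate_dataset(cfg), d2)
  files <- list.files(d1)
  expect_true(length(files) > 10)
  for (f in files)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("checksum of", f))
  sim <- simulate_dataset(cfg)
  ## all intervals within chromosome bounds, half-open
  for (df in list(sim$genome$genes, sim$layers$atac_peaks,
                  sim$layers$h3k27ac_peaks)) {
    expect_true(all(df$start >= 0))
    expect_true(all(df$end <= cfg$chrom_length_bp))
    expect_true(all(df$end > df$start))
  }
  expect_true(all(sim$layers$snps$pos_1based >= 1 &
                    sim$layers$snps$pos_1based <= cfg$chrom_length_bp))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("genomic and epigenomic tracks carry the planted A/B contrasts", {
  sim <- fixture_dataset(1)
  cfg <- sim$config
  for (ch in names(sim$truth$compartment_labels)) {
    lab <- sim$truth$compartment_labels[[ch]]
    A <- lab == "A"
    dens <- fixture_gene_density(sim, ch)
    expect_gt(mean(dens[A]), mean(dens[!A]))
    ## planted 5:1 A:B gene-density ratio echoes into the bin means
    expect_gt(mean(dens[A]) / mean(dens[!A]), 2.5)
    expect_gt(mean(sim$genome$ltr[[ch]][!A]), mean(sim$genome$ltr[[ch]][A]))
    expect_gt(mean(sim$genome$gc[[ch]][!A]), mean(sim$genome$gc[[ch]][A]))
    nb <- length(lab)
    for (ctx in c("CG", "CHG")) {
      v <- bin_track(sim$layers$methylation[[ctx]], ch, cfg$bin_size_bp, nb)
      expect_gt(mean(v[!A]), mean(v[A]))
    }
    chh <- bin_track(sim$layers$methylation$CHH, ch, cfg$bin_size_bp, nb)
    expect_gt(mean(chh[A]), mean(chh[!A]))
  }
})

test_that("zero genes give an empty annotation and all-zero density", {
  cfg <- synthetic_config(n_genes = 0, promoter_acr_fraction = 0,
                          rng_seed = 5)
  g <- make_genome(cfg)
  expect_identical(nrow(g$genes), 0L)
  expect_true(all(unlist(g$gene_density) == 0))
  path <- tempfile(fileext = ".gff3")
  write_gff3(g$genes, path)
  expect_identical(readLines(path), "##gff-version 3")
  unlink(path)
})

test_that("contact counts follow the planted generative model", {
  ## pure decay limit: empirical mean at distance d ~ scale * (1+d)^-alpha
  m <- null_contact_matrix(seed = 9, scale = 50, alpha = 1)
  cm <- m$counts
  nb <- nrow(cm)
  expect_true(isSymmetric(cm))
  expect_true(all(cm >= 0) && all(cm == round(cm)))
  for (d in c(0, 5, 20)) {
    i <- seq_len(nb - d)
    emp <- mean(cm[cbind(i, i + d)])
    expect_equal(emp, 50 / (1 + d), tolerance = 0.12)
  }
  ## flat limit: alpha = 0, amplitude 0 -> overall mean ~ coverage_scale
  m0 <- null_contact_matrix(seed = 10, scale = 5, alpha = 0)
  expect_equal(mean(m0$counts), 5, tolerance = 0.05)
})

test_that("a planted loop pixel is boosted by loop_strength on average", {
  cfg <- synthetic_config(n_chromosomes = 1L, chrom_length_bp = 1.5e6,
                          bin_size_bp = 25000L, plaid_amplitude = 0,
                          tad_contrast = 1, loop_strength = 5,
                          rng_seed = 2)
  truth <- make_truth(cfg)
  truth$tad_boundaries[[1]] <- integer(0)
  truth$loops <- data.frame(i = 10L, j = 30L, kind = "single",
                            chrom = "chr1")
  ## average the loop pixel over replicate draws against off-loop pixels
  on <- off <- numeric(300)
  for (r in seq_len(300)) {
    cfg$rng_seed <- 1000L + r
    cm <- simulate_contacts(truth, cfg)[[1]]$counts
    on[r] <- cm[11, 31]
    off[r] <- mean(cm[cbind(3:8, 23:28)])   # same distance, unboosted
  }
  expect_equal(mean(on) / mean(off), 5, tolerance = 0.1)
})

test_that("planted SNP share matches the closed-form expectation", {
  ## factor 20, elements 1% of genome -> in-element share 20/119
  el <- data.frame(chrom = "chr1",
                   start = seq(0, 4.9e6, by = 1e5),
                   end = seq(0, 4.9e6, by = 1e5) + 1000)
  cs <- data.frame(chrom = "chr1", length = 5e6)
  set.seed(77)
  snps <- simulate_snps(el, cs, n_snps = 5000, enrichment_factor = 20)
  share <- mean(snps$in_element)
  expected <- 20 * 0.01 / (20 * 0.01 + 0.99)
  se <- sqrt(expected * (1 - expected) / 5000)
  expect_lt(abs(share - expected), 4 * se)
  ## recorded stratum agrees with geometry
  hits <- intersect_snps(snps, el)
  expect_setequal(hits$snp_idx, which(snps$in_element))
})

test_that("expression increases with planted loop class and the
           differential gene is constructed as specified", {
  sim <- fixture_dataset(1)
  lpg <- sim$layers$loops_per_gene
  expr <- sim$layers$expression
  stopifnot(all(lpg$gene_id == expr$gene_id))
  cls <- split(expr$value, cut(lpg$n_loops, c(-1, 0, 1, 5, 100)))
  med <- sapply(cls[lengths(cls) > 0], median)
  expect_true(all(diff(med) > 0))
  ## differential peaks: planted heights 100 vs 25 at equal library scale
  dp <- sim$layers$differential_peaks
  expect_identical(nrow(dp), 2L)
  da <- differential_accessibility(sim$layers$atac_depth_sample1,
                                   sim$layers$atac_depth_sample2, dp)
  expect_true(all(da$log2_ratio > 1.5 & da$log2_ratio < 2.5))
})
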