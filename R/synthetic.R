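#' Configuration for the synthetic genome generator
#'
#' Defines the study conditions of the planted-truth fixture: a small
#' multi-chromosome genome whose Hi-C map, gene models, peaks, methylation,
#' expression and SNPs carry the statistical structure the downstream
#' analyses assume (telomeric A / pericentromeric B compartments,
#' contact-enriched TADs, focal loops, accessible promoters, distal
#' enhancers, loop-count-driven expression, element-enriched SNPs).
#'
#' @param n_chromosomes number of chromosomes
#' @param chrom_length_bp chromosome length in bp; must be divisible by
#'   `bin_size_bp`
#' @param bin_size_bp Hi-C bin width in bp
#' @param decay_exponent alpha in the contact decay `(1+d)^-alpha`
#' @param plaid_amplitude compartment plaid contrast in `[0, 1)`: pixels in
#'   the same compartment are scaled by `1 + a`, across compartments by
#'   `1 - a`
#' @param tad_contrast within-TAD contact multiplier (> 1)
#' @param loop_strength contact multiplier on the 1-pixel neighbourhood of
#'   each planted loop pixel (> 1)
#' @param coverage_scale expected contact count at distance 0 (> 0)
#' @param n_genes genes per genome
#' @param gene_density_ratio expected genes-per-bin ratio A : B
#' @param promoter_acr_fraction fraction of genes given a promoter ATAC peak
#' @param promoter_expression_fold expression fold-change for genes with a
#'   promoter ATAC peak
#' @param n_enhancers planted distal H3K27ac enhancers per genome
#' @param active_enhancer_fraction fraction of enhancers co-planted with an
#'   ATAC peak (active enhancers)
#' @param n_snps SNPs per genome
#' @param snp_enrichment_factor in-element versus background SNP density
#'   ratio (> 1)
#' @param atac_peak_width,h3k27ac_peak_width peak widths in bp (H3K27ac
#'   peaks are generated longer than ATAC peaks)
#' @param track_step_bp resolution of the fine read-depth and methylation
#'   tracks in bp
#' @param rng_seed integer seed; identical configs give byte-identical
#'   outputs
#' @return an object of class `synthetic_config`
#' @export
synthetic_config <- function(n_chromosomes = 2L,
                             chrom_length_bp = 5e6,
                             bin_size_bp = 25000L,
                             decay_exponent = 1.0,
                             plaid_amplitude = 0.3,
                             tad_contrast = 1.5,
                             loop_strength = 3,
                             coverage_scale = 50,
                             n_genes = 400L,
                             gene_density_ratio = 5,
                             promoter_acr_fraction = 0.5,
                             promoter_expression_fold = 2.5,
                             n_enhancers = 40L,
                             active_enhancer_fraction = 0.25,
                             n_snps = 3000L,
                             snp_enrichment_factor = 20,
                             atac_peak_width = 400L,
                             h3k27ac_peak_width = 1200L,
                             track_step_bp = 100L,
                             rng_seed = 1L) {
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              chrom_length_bp = as.numeric(chrom_length_bp),
              bin_size_bp = as.integer(bin_size_bp),
              decay_exponent = decay_exponent,
              plaid_amplitude = plaid_amplitude,
              tad_contrast = tad_contrast,
              loop_strength = loop_strength,
              coverage_scale = coverage_scale,
              n_genes = as.integer(n_genes),
              gene_density_ratio = gene_density_ratio,
              promoter_acr_fraction = promoter_acr_fraction,
              promoter_expression_fold = promoter_expression_fold,
              n_enhancers = as.integer(n_enhancers),
              active_enhancer_fraction = active_enhancer_fraction,
              n_snps = as.integer(n_snps),
              snp_enrichment_factor = snp_enrichment_factor,
              atac_peak_width = as.integer(atac_peak_width),
              h3k27ac_peak_width = as.integer(h3k27ac_peak_width),
              track_step_bp = as.integer(track_step_bp),
              rng_seed = as.integer(rng_seed))
  if (cfg$chrom_length_bp %% cfg$bin_size_bp != 0)
    stop2("chrom_length_bp must be divisible by bin_size_bp")
  if (cfg$plaid_amplitude < 0 || cfg$plaid_amplitude >= 1)
    stop2("plaid_amplitude must be in [0, 1)")
  if (cfg$tad_contrast < 1) stop2("tad_contrast must be >= 1")
  if (cfg$loop_strength < 1) stop2("loop_strength must be >= 1")
  if (cfg$coverage_scale <= 0) stop2("coverage_scale must be positive")
  if (cfg$snp_enrichment_factor < 1)
    stop2("snp_enrichment_factor must be >= 1")
  if (cfg$promoter_acr_fraction < 0 || cfg$promoter_acr_fraction > 1)
    stop2("promoter_acr_fraction must be in [0, 1]")
  structure(cfg, class = "synthetic_config")
}

chrom_names <- function(config) paste0("chr", seq_len(config$n_chromosomes))

bins_per_chrom <- function(config) {
  as.integer(config$chrom_length_bp / config$bin_size_bp)
}

## deterministic compartment layout: A blocks over the telomeric quarters,
## B over the central (pericentromeric) half
compartment_labels <- function(config) {
  nb <- bins_per_chrom(config)
  q <- floor(nb / 4)
  lab <- rep("B", nb)
  lab[seq_len(q)] <- "A"
  lab[(nb - q + 1):nb] <- "A"
  lab
}

## layer-indexed RNG streams: adding a layer never perturbs earlier ones
layer_seed <- function(config, layer) {
  (config$rng_seed * 131L + layer * 7919L) %% .Machine$integer.max
}

#' Plant the ground truth of a synthetic genome
#'
#' Generates the deterministic compartment layout, planted TAD boundaries,
#' planted loop pixels (two shared-anchor "hubs" plus isolated loops per
#' chromosome, all pairwise separated so the loop caller sees distinct
#' foci), and designates enhancer-anchor / gene-anchor bins for
#' loop-mediated enhancer-gene links.
#'
#' @param config a [synthetic_config()]
#' @return an object of class `synthetic_truth`: per-chromosome compartment
#'   labels, TAD boundary bin indices, loop pixel table, enhancer-anchor
#'   and gene-anchor bin designations
#' @export
make_truth <- function(config) {
  nb <- bins_per_chrom(config)
  chroms <- chrom_names(config)
  labels <- setNames(lapply(chroms, function(ch) compartment_labels(config)),
                     chroms)

  set.seed(layer_seed(config, 1L))
  boundaries <- list()
  loops <- list()
  for (ch in chroms) {
    ## TAD boundaries. The two loop-hub domains are pinned inside the
    ## telomeric A blocks (hub anchors sit in gene-rich active chromatin,
    ## mirroring the association of loop-dense anchors with active
    ## regulation); the remaining boundaries fall every 15-25 bins.
    q <- floor(nb / 4)
    if (nb >= 80L) {
      h1s <- max(3L, floor(nb * 0.05)); h1e <- min(q, h1s + 34L)
      h2e <- nb - max(3L, floor(nb * 0.05))
      h2s <- max(nb - q, h2e - 26L)
      b <- c(h1s, h1e)
      pos <- h1e
      repeat {
        pos <- pos + sample(15:25, 1L)
        if (pos > h2s - 8L) break
        b <- c(b, pos)
      }
      b <- c(b, h2s, h2e)
      hub_tads <- list(c(h1s, h1e), c(h2s, h2e))
    } else {
      b <- integer(0)
      pos <- 0L
      repeat {
        pos <- pos + sample(15:25, 1L)
        if (pos > nb - 10L) break
        b <- c(b, pos)
      }
      hub_tads <- NULL
    }
    boundaries[[ch]] <- b
    ## TAD intervals [start, end) in bins
    cut <- c(0L, b, nb)
    tads <- data.frame(start = cut[-length(cut)], end = cut[-1])
    tads$len <- tads$end - tads$start

    pix <- make_loop_pixels(tads, nb, hub_tads)
    pix$chrom <- ch
    loops[[ch]] <- pix
  }
  loop_df <- do.call(rbind, loops)
  rownames(loop_df) <- NULL
  structure(list(config = config,
                 compartment_labels = labels,
                 tad_boundaries = boundaries,
                 loops = loop_df),
            class = "synthetic_truth")
}

## hub1: 7 loops sharing one anchor; hub2: 4 loops; 14 singles.
## all pixels pairwise Chebyshev distance >= 5, so the boosted 3x3
## neighbourhoods of distinct planted loops stay >= 3 pixels apart and a
## single noise pixel can never bridge two loops into one 8-connected
## cluster.
make_loop_pixels <- function(tads, nb, hub_tads = NULL) {
  if (!is.null(hub_tads)) {
    t1 <- data.frame(start = hub_tads[[1]][1], end = hub_tads[[1]][2])
    t2 <- data.frame(start = hub_tads[[2]][1], end = hub_tads[[2]][2])
    t1$len <- t1$end - t1$start
    t2$len <- t2$end - t2$start
  } else {
    ord <- order(-tads$len)
    t1 <- tads[ord[1], ]; t2 <- tads[ord[2], ]
  }
  pix <- data.frame(i = integer(0), j = integer(0), kind = character(0))
  add <- function(pix, i, j, kind) {
    ii <- min(i, j); jj <- max(i, j)
    rbind(pix, data.frame(i = ii, j = jj, kind = kind))
  }
  ## hub 1 (7 partners) centred in its domain
  h1 <- as.integer(t1$start + floor(t1$len / 2))
  for (d in c(2L, 7L, 12L)) {
    if (h1 + d <= t1$end - 3L) pix <- add(pix, h1, h1 + d, "hub1")
  }
  for (d in c(5L, 10L, 15L, 20L)) {
    if (h1 - d >= t1$start + 2L) pix <- add(pix, h1 - d, h1, "hub1")
  }
  ## hub 2 (4 partners)
  h2 <- as.integer(t2$start + floor(t2$len / 2))
  for (d in c(3L, 8L)) {
    if (h2 + d <= t2$end - 3L) pix <- add(pix, h2, h2 + d, "hub2")
  }
  for (d in c(6L, 11L)) {
    if (h2 - d >= t2$start + 2L) pix <- add(pix, h2 - d, h2, "hub2")
  }
  ## isolated loops inside TADs, rejection-sampled for separation
  target <- 25L
  tries <- 0L
  while (nrow(pix) < target && tries < 5000L) {
    tries <- tries + 1L
    trow <- tads[sample(nrow(tads), 1L), ]
    if (trow$len < 10L) next
    d <- sample(2:12, 1L)
    lo <- trow$start + 2L
    hi <- trow$end - 3L - d
    if (hi < lo) next
    i <- sample(lo:hi, 1L)
    j <- i + d
    if (nrow(pix) > 0 &&
        min(pmax(abs(pix$i - i), abs(pix$j - j))) < 5L) next
    pix <- add(pix, i, j, "single")
  }
  pix
}

#' Generate gene models and per-bin genomic tracks
#'
#' Places genes with an A:B bin-density ratio of `gene_density_ratio`,
#' forcing one gene into each hub/gene-anchor bin and keeping
#' enhancer-anchor bins gene-free; generates GC ratio and LTR-density
#' tracks higher in B, consistent with compact repressed chromatin.
#'
#' @param config a [synthetic_config()]
#' @param truth a [make_truth()] result (defaults to `make_truth(config)`)
#' @return list with `genes` (chrom, start, end, strand, gene_id; 0-based
#'   half-open), per-chromosome `gene_density`, `gc`, `ltr` bin tracks, and
#'   the link designations (`enhancer_anchor_bins`, `gene_anchor_bins`,
#'   `link_loops`) carried forward from the loop layout
#' @export
make_genome <- function(config, truth = make_truth(config)) {
  nb <- bins_per_chrom(config)
  bs <- config$bin_size_bp
  chroms <- chrom_names(config)
  set.seed(layer_seed(config, 2L))

  ## designate link anchors on single loops: enhancer on one side, gene on
  ## the other (8 per chromosome where available)
  enh_bins <- list(); gene_bins <- list(); link_rows <- integer(0)
  for (ch in chroms) {
    lp <- truth$loops[truth$loops$chrom == ch & truth$loops$kind == "single", ]
    lp <- lp[seq_len(min(8L, nrow(lp))), , drop = FALSE]
    enh_bins[[ch]] <- lp$i
    gene_bins[[ch]] <- lp$j
    link_rows <- c(link_rows, as.integer(rownames(lp)))
  }

  genes <- list()
  gid <- 0L
  gene_len <- 3000L
  for (ch in chroms) {
    lab <- truth$compartment_labels[[ch]]
    w <- ifelse(lab == "A", config$gene_density_ratio, 1)
    w[enh_bins[[ch]] + 1L] <- 0          # keep enhancer anchors intergenic
    ## forced genes: hub anchor bins and link gene-anchor bins
    lp <- truth$loops[truth$loops$chrom == ch, ]
    hub1 <- unique(c(lp$i[lp$kind == "hub1"], lp$j[lp$kind == "hub1"]))
    hub1 <- hub1[which.max(tabulate(match(c(lp$i, lp$j), hub1)))]
    hub2 <- unique(c(lp$i[lp$kind == "hub2"], lp$j[lp$kind == "hub2"]))
    hub2 <- hub2[which.max(tabulate(match(c(lp$i, lp$j), hub2)))]
    forced <- unique(c(hub1, hub2, gene_bins[[ch]]))
    forced <- setdiff(forced, enh_bins[[ch]])
    n_free <- max(0L, as.integer(round(config$n_genes / length(chroms))) -
                    length(forced))
    free_bins <- if (config$n_genes > 0 && sum(w) > 0)
      sample(seq_len(nb) - 1L, n_free, replace = TRUE, prob = w)
    else integer(0)
    bins <- if (config$n_genes > 0) c(forced, free_bins) else integer(0)
    for (b in bins) {
      gid <- gid + 1L
      ## gene placed mid-bin, away from the 3 kb promoter margins where the
      ## bin is large enough; tiny-bin configs centre a shortened gene
      glen <- if (bs >= gene_len + 12000L) gene_len
              else max(200L, as.integer(bs * 0.3))
      lo <- if (bs >= glen + 12000L) 6000L else as.integer((bs - glen) / 2)
      hi <- max(lo, bs - glen - lo)
      start <- as.numeric(b) * bs +
        sample(seq(lo, hi, by = min(100L, max(1L, hi - lo))), 1L)
      genes[[gid]] <- data.frame(chrom = ch, start = start,
                                 end = start + glen,
                                 strand = sample(c("+", "-"), 1L),
                                 gene_id = sprintf("gene%04d", gid))
    }
  }
  genes <- if (length(genes)) do.call(rbind, genes)
           else data.frame(chrom = character(0), start = numeric(0),
                           end = numeric(0), strand = character(0),
                           gene_id = character(0))

  gene_density <- list(); gc <- list(); ltr <- list()
  for (ch in chroms) {
    lab <- truth$compartment_labels[[ch]]
    g <- genes[genes$chrom == ch, , drop = FALSE]
    dens <- tabulate(pmin(floor((g$start + g$end) / 2 / bs), nb - 1) + 1L, nb)
    gene_density[[ch]] <- as.numeric(dens)
    gc[[ch]] <- ifelse(lab == "A", 0.38, 0.44) + rnorm(nb, 0, 0.005)
    ltr[[ch]] <- pmin(1, pmax(0, ifelse(lab == "A", 0.2, 0.6) +
                                rnorm(nb, 0, 0.03)))
  }
  list(genes = genes,
       gene_density = gene_density, gc = gc, ltr = ltr,
       enhancer_anchor_bins = enh_bins, gene_anchor_bins = gene_bins,
       link_loop_rows = link_rows)
}

#' Simulate Hi-C contact matrices with planted structure
#'
#' Draws each upper-triangle pixel independently from a Poisson whose mean
#' is `coverage_scale * (1+d)^-alpha * c * t * l`: `c` is the compartment
#' plaid factor (`1 + a` same label, `1 - a` different), `t` the within-TAD
#' contrast, and `l` the loop strength on the 1-pixel neighbourhood of each
#' planted loop pixel. The matrix is then symmetrised.
#'
#' @param truth a [make_truth()] result
#' @param config the matching [synthetic_config()]
#' @return named list of raw [contact_matrix()] objects, one per chromosome
#' @export
simulate_contacts <- function(truth, config) {
  if (config$coverage_scale <= 0) stop2("coverage_scale must be positive")
  nb <- bins_per_chrom(config)
  out <- list()
  for (k in seq_along(chrom_names(config))) {
    ch <- chrom_names(config)[k]
    set.seed(layer_seed(config, 10L + k))
    mu <- expected_contact_surface(truth, config, ch)
    counts <- matrix(0, nb, nb)
    ut <- upper.tri(counts, diag = TRUE)
    counts[ut] <- rpois(sum(ut), mu[ut])
    counts[lower.tri(counts)] <- t(counts)[lower.tri(counts)]
    out[[ch]] <- contact_matrix(counts, ch, config$bin_size_bp,
                                chrom_length = config$chrom_length_bp)
  }
  out
}

## expected (Poisson-mean) contact surface for one chromosome
expected_contact_surface <- function(truth, config, chrom) {
  nb <- bins_per_chrom(config)
  d <- abs(outer(seq_len(nb), seq_len(nb), "-"))
  mu <- config$coverage_scale * (1 + d)^(-config$decay_exponent)
  lab <- truth$compartment_labels[[chrom]]
  same <- outer(lab, lab, "==")
  mu <- mu * ifelse(same, 1 + config$plaid_amplitude,
                    1 - config$plaid_amplitude)
  ## TAD factor
  cut <- c(0L, truth$tad_boundaries[[chrom]], nb)
  tad_id <- findInterval(seq_len(nb) - 1L, cut, rightmost.closed = FALSE)
  mu <- mu * ifelse(outer(tad_id, tad_id, "=="), config$tad_contrast, 1)
  ## loop factor on 3x3 neighbourhoods
  lp <- truth$loops[truth$loops$chrom == chrom, , drop = FALSE]
  if (nrow(lp)) {
    lf <- matrix(1, nb, nb)
    for (r in seq_len(nrow(lp))) {
      ii <- max(1L, lp$i[r]):min(nb, lp$i[r] + 2L)  # bins i-1..i+1, 1-based
      jj <- max(1L, lp$j[r]):min(nb, lp$j[r] + 2L)
      lf[ii, jj] <- config$loop_strength
      lf[jj, ii] <- config$loop_strength
    }
    mu <- mu * lf
  }
  mu
}

#' Simulate peaks, methylation, depth, expression and SNP layers
#'
#' Generates: ATAC peaks (promoter / genic / distal, two samples with two
#' attenuated peaks at a designated differential gene), H3K27ac peaks
#' (longer than ATAC; distal ones are the planted enhancers, a quarter of
#' which coincide with ATAC peaks and are therefore active), fine-scale
#' CG/CHG/CHH methylation with compartment-specific means and a dip inside
#' peak bodies, ATAC read-depth tracks for both samples with a bump at
#' every TSS, a per-gene expression table increasing in planted loop count
#' and boosted by promoter ATAC peaks, and an element-enriched SNP table.
#'
#' @param truth a [make_truth()] result
#' @param genome a [make_genome()] result
#' @param config the matching [synthetic_config()]
#' @return list of layer tables (see Details) plus the planted truth of
#'   each layer (`differential_peaks`, `enhancers`, `links`,
#'   `loops_per_gene`, `snp_in_element`)
#' @export
simulate_functional_layers <- function(truth, genome, config) {
  genes <- genome$genes
  chroms <- chrom_names(config)
  L <- config$chrom_length_bp
  bs <- config$bin_size_bp
  step <- config$track_step_bp

  ## ---- peaks (layer 3) ----
  set.seed(layer_seed(config, 3L))
  aw <- config$atac_peak_width
  hw <- config$h3k27ac_peak_width
  atac <- list(); h3k <- list(); enh <- list()

  tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  ## promoter ATAC peaks for a fraction of genes, centred on the TSS (the
  ## accessible promoter straddles the TSS; promoter-window overlap takes
  ## classification precedence over the gene-body overlap)
  n_prom <- round(config$promoter_acr_fraction * nrow(genes))
  prom_idx <- if (nrow(genes)) sort(sample(nrow(genes), n_prom)) else integer(0)
  for (g in prom_idx) {
    ctr <- tss[g]
    atac[[length(atac) + 1L]] <- data.frame(
      chrom = genes$chrom[g], start = ctr - aw / 2, end = ctr + aw / 2,
      kind = "promoter", gene = genes$gene_id[g])
  }
  ## genic ATAC peaks for 10% of genes (peak centred in the body); the
  ## designated differential gene is excluded so nothing stacks on its
  ## planted body peak and dilutes the constructed 4:1 contrast
  genic_pool <- setdiff(seq_len(nrow(genes)), prom_idx[1])
  genic_idx <- if (length(genic_pool))
    sample(genic_pool, round(0.1 * nrow(genes))) else integer(0)
  for (g in genic_idx) {
    ctr <- (genes$start[g] + genes$end[g]) / 2
    atac[[length(atac) + 1L]] <- data.frame(
      chrom = genes$chrom[g], start = ctr - aw / 2, end = ctr + aw / 2,
      kind = "genic", gene = genes$gene_id[g])
  }
  ## enhancers: H3K27ac distal peaks, placed mid-bin in the designated
  ## enhancer-anchor bins first, the rest in random gene-free bins
  n_enh_per_chrom <- ceiling(config$n_enhancers / length(chroms))
  for (ch in chroms) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    gene_bins <- unique(floor((g$start + g$end) / 2 / bs))
    anchor_bins <- genome$enhancer_anchor_bins[[ch]]
    free <- setdiff(setdiff(seq_len(bins_per_chrom(config)) - 1L, gene_bins),
                    anchor_bins)
    extra <- sample(free, max(0L, n_enh_per_chrom - length(anchor_bins)))
    ebins <- c(anchor_bins, extra)
    ctr <- ebins * bs + bs / 2
    enh[[ch]] <- data.frame(chrom = ch, start = ctr - hw / 2,
                            end = ctr + hw / 2,
                            anchor = c(rep(TRUE, length(anchor_bins)),
                                       rep(FALSE, length(extra))))
  }
  enh_df <- do.call(rbind, enh); rownames(enh_df) <- NULL
  ## active enhancers: first quarter (incl. anchors) get a coinciding ATAC peak
  n_active <- round(config$active_enhancer_fraction * nrow(enh_df))
  active_idx <- seq_len(n_active)
  for (e in active_idx) {
    ctr <- (enh_df$start[e] + enh_df$end[e]) / 2
    atac[[length(atac) + 1L]] <- data.frame(
      chrom = enh_df$chrom[e], start = ctr - aw / 2, end = ctr + aw / 2,
      kind = "distal", gene = NA_character_)
  }
  ## standalone distal ATAC peaks (inaccessible to enhancers)
  for (ch in chroms) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    used <- unique(c(floor((g$start + g$end) / 2 / bs),
                     floor((enh_df$start[enh_df$chrom == ch] +
                              enh_df$end[enh_df$chrom == ch]) / 2 / bs),
                     genome$enhancer_anchor_bins[[ch]]))
    free <- setdiff(seq_len(bins_per_chrom(config)) - 1L, used)
    db <- sample(free, min(10L, length(free)))
    for (b in db) {
      ctr <- b * bs + bs * 0.25
      atac[[length(atac) + 1L]] <- data.frame(
        chrom = ch, start = ctr - aw / 2, end = ctr + aw / 2,
        kind = "distal", gene = NA_character_)
    }
  }
  ## H3K27ac promoter peaks for 30% of genes (not enhancers by definition)
  hp_idx <- if (nrow(genes)) sample(nrow(genes), round(0.3 * nrow(genes)))
            else integer(0)
  h3k_rows <- list()
  for (g in hp_idx) {
    ctr <- if (genes$strand[g] == "+") tss[g] - 1000 else tss[g] + 1000
    h3k_rows[[length(h3k_rows) + 1L]] <- data.frame(
      chrom = genes$chrom[g], start = ctr - hw / 2, end = ctr + hw / 2,
      kind = "promoter")
  }
  h3k_df <- rbind(
    data.frame(chrom = enh_df$chrom, start = enh_df$start, end = enh_df$end,
               kind = "enhancer"),
    if (length(h3k_rows)) do.call(rbind, h3k_rows))
  atac_df <- do.call(rbind, atac); rownames(atac_df) <- NULL
  atac_df$start <- pmax(0, atac_df$start)
  atac_df$end <- pmin(L, atac_df$end)
  h3k_df$start <- pmax(0, h3k_df$start)
  h3k_df$end <- pmin(L, h3k_df$end)

  ## differential gene: a promoter-peaked gene gets a second, genic peak;
  ## both are attenuated 4-fold in sample 2
  if (length(prom_idx)) {
    diff_gene <- genes$gene_id[prom_idx[1]]
    dg <- genes[genes$gene_id == diff_gene, ]
    diff_body <- data.frame(chrom = dg$chrom,
                            start = (dg$start + dg$end) / 2 - aw / 2,
                            end = (dg$start + dg$end) / 2 + aw / 2,
                            kind = "diff_body", gene = diff_gene)
    atac_df <- rbind(atac_df, diff_body)
    diff_peaks <- rbind(
      atac_df[atac_df$kind == "promoter" & !is.na(atac_df$gene) &
                atac_df$gene == diff_gene, c("chrom", "start", "end")],
      diff_body[, c("chrom", "start", "end")])
  } else {
    diff_gene <- NA_character_
    diff_peaks <- data.frame(chrom = character(0), start = numeric(0),
                             end = numeric(0))
  }

  ## peak ids
  atac_df$peak_id <- sprintf("atac%04d", seq_len(nrow(atac_df)))
  h3k_df$peak_id <- sprintf("h3k%04d", seq_len(nrow(h3k_df)))

  ## ---- methylation (layer 4) ----
  set.seed(layer_seed(config, 4L))
  meth <- list()
  ctx_means <- list(CG = c(A = 0.45, B = 0.75),
                    CHG = c(A = 0.25, B = 0.55),
                    CHH = c(A = 0.18, B = 0.08))
  all_peaks <- rbind(atac_df[, c("chrom", "start", "end")],
                     h3k_df[, c("chrom", "start", "end")])
  for (ctx in names(ctx_means)) {
    rows <- list()
    for (ch in chroms) {
      nwin <- as.integer(L / step)
      starts <- (seq_len(nwin) - 1L) * step
      lab <- truth$compartment_labels[[ch]][
        pmin(floor(starts / bs), bins_per_chrom(config) - 1L) + 1L]
      m <- ctx_means[[ctx]][lab]
      ## dip inside peak bodies
      pk <- all_peaks[all_peaks$chrom == ch, , drop = FALSE]
      in_peak <- rep(FALSE, nwin)
      for (r in seq_len(nrow(pk))) {
        w0 <- max(0L, floor(pk$start[r] / step))
        w1 <- min(nwin - 1L, floor((pk$end[r] - 1) / step))
        if (w1 >= w0) in_peak[(w0:w1) + 1L] <- TRUE
      }
      m[in_peak] <- m[in_peak] * 0.25
      conc <- 30
      v <- rbeta(nwin, m * conc, (1 - m) * conc)
      rows[[ch]] <- data.frame(chrom = ch, start = starts,
                               end = starts + step, value = round(v, 4))
    }
    meth[[ctx]] <- do.call(rbind, rows)
  }

  ## ---- read-depth tracks (layer 5) ----
  set.seed(layer_seed(config, 5L))
  depth_track <- function(peaks, heights, tss_bump = TRUE) {
    rows <- list()
    for (ch in chroms) {
      nwin <- as.integer(L / step)
      starts <- (seq_len(nwin) - 1L) * step
      lam <- rep(2, nwin)
      if (tss_bump && nrow(genes)) {
        g <- genes[genes$chrom == ch, , drop = FALSE]
        ts <- ifelse(g$strand == "+", g$start, g$end)
        for (t in ts) {
          w <- floor(t / step)
          idx <- (w - 6):(w + 6)
          keep <- idx >= 0 & idx < nwin
          off <- (idx[keep] * step + step / 2 - t) / 300
          lam[idx[keep] + 1L] <- lam[idx[keep] + 1L] + 10 * exp(-off^2 / 2)
        }
      }
      pk <- peaks[peaks$chrom == ch, , drop = FALSE]
      hh <- heights[peaks$chrom == ch]
      for (r in seq_len(nrow(pk))) {
        w0 <- max(0L, floor(pk$start[r] / step))
        w1 <- min(nwin - 1L, floor((pk$end[r] - 1) / step))
        if (w1 >= w0) lam[(w0:w1) + 1L] <- lam[(w0:w1) + 1L] + hh[r]
      }
      rows[[ch]] <- data.frame(chrom = ch, start = starts,
                               end = starts + step,
                               value = rpois(nwin, lam))
    }
    do.call(rbind, rows)
  }
  is_diff <- atac_df$kind == "diff_body" |
    (!is.na(atac_df$gene) & atac_df$gene == diff_gene &
       atac_df$kind == "promoter")
  h1 <- ifelse(is_diff, 100, 30)
  h2 <- ifelse(is_diff, 25, 30)
  atac_depth1 <- depth_track(atac_df, h1)
  atac_depth2 <- depth_track(atac_df, h2)
  h3k_depth <- depth_track(h3k_df, rep(30, nrow(h3k_df)))

  ## ---- expression (layer 6) ----
  set.seed(layer_seed(config, 6L))
  lpg <- planted_loops_per_gene(truth, genes, config)
  has_prom <- genes$gene_id %in% atac_df$gene[atac_df$kind == "promoter"]
  mu <- 8 * (1 + lpg)^1.2 *
    ifelse(has_prom, config$promoter_expression_fold, 1)
  expression <- data.frame(gene_id = genes$gene_id,
                           value = round(mu * rlnorm(nrow(genes), 0, 0.4), 3))

  ## ---- SNPs (layer 7) ----
  set.seed(layer_seed(config, 7L))
  prom_windows <- promoter_windows(
    genes, upstream = 3000,
    chrom_sizes = data.frame(chrom = chroms, length = L))
  snp_elements <- merge_intervals(rbind(
    prom_windows[, c("chrom", "start", "end")],
    enh_df[, c("chrom", "start", "end")]))
  snps <- simulate_snps(snp_elements,
                        chrom_sizes = data.frame(chrom = chroms, length = L),
                        n_snps = config$n_snps,
                        enrichment_factor = config$snp_enrichment_factor)

  list(atac_peaks = atac_df, atac_peaks_sample2 = atac_df,
       h3k27ac_peaks = h3k_df,
       methylation = meth,
       atac_depth_sample1 = atac_depth1, atac_depth_sample2 = atac_depth2,
       h3k27ac_depth = h3k_depth,
       expression = expression,
       snps = snps,
       enhancers = enh_df,
       active_enhancer_idx = active_idx,
       differential_gene = diff_gene,
       differential_peaks = diff_peaks,
       loops_per_gene = data.frame(gene_id = genes$gene_id, n_loops = lpg),
       snp_elements = snp_elements)
}

## planted loop count per gene: loops whose anchor bin contains the gene body
planted_loops_per_gene <- function(truth, genes, config) {
  if (!nrow(genes)) return(integer(0))
  bs <- config$bin_size_bp
  n <- integer(nrow(genes))
  for (g in seq_len(nrow(genes))) {
    lp <- truth$loops[truth$loops$chrom == genes$chrom[g], , drop = FALSE]
    if (!nrow(lp)) next
    b0 <- floor(genes$start[g] / bs)
    b1 <- floor((genes$end[g] - 1) / bs)
    n[g] <- sum(lp$i %in% b0:b1 | lp$j %in% b0:b1)
  }
  n
}

#' Simulate SNPs enriched inside a set of elements
#'
#' Each SNP falls inside the (merged) element space with probability
#' `f*r / (f*r + 1 - r)` where `f` is the enrichment factor and `r` the
#' element fraction of the genome, which makes the in-element versus
#' background density ratio equal `f` in expectation; positions are
#' uniform within the chosen stratum.
#'
#' @param elements merged element intervals (chrom, start, end; 0-based
#'   half-open)
#' @param chrom_sizes data.frame (chrom, length)
#' @param n_snps number of SNPs
#' @param enrichment_factor in/out density ratio `f`
#' @return data.frame (chrom, pos_1based, id, in_element)
#' @export
simulate_snps <- function(elements, chrom_sizes, n_snps, enrichment_factor) {
  total <- sum(chrom_sizes$length)
  elements <- merge_intervals(elements)
  elen <- sum(elements$end - elements$start)
  r <- elen / total
  p_in <- enrichment_factor * r / (enrichment_factor * r + 1 - r)
  inside <- runif(n_snps) < p_in
  chrom <- character(n_snps); pos <- numeric(n_snps)
  ## element space sampler: pick an element weighted by length
  if (nrow(elements)) {
    ew <- elements$end - elements$start
    eidx <- sample(nrow(elements), sum(inside), replace = TRUE, prob = ew)
    chrom[inside] <- elements$chrom[eidx]
    pos[inside] <- floor(elements$start[eidx] +
                           runif(sum(inside)) * ew[eidx]) + 1  # 1-based
  } else inside[] <- FALSE
  n_out <- sum(!inside)
  if (n_out) {
    cw <- chrom_sizes$length
    ## uniform over the element complement: resample draws landing inside
    todo <- which(!inside)
    for (tries in 1:100) {
      if (!length(todo)) break
      cidx <- sample(nrow(chrom_sizes), length(todo), replace = TRUE,
                     prob = cw)
      chrom[todo] <- chrom_sizes$chrom[cidx]
      pos[todo] <- floor(runif(length(todo)) * chrom_sizes$length[cidx]) + 1
      if (!nrow(elements)) break
      bad <- overlaps_any(data.frame(chrom = chrom[todo],
                                     start = pos[todo] - 1,
                                     end = pos[todo]), elements)
      todo <- todo[bad]
    }
  }
  data.frame(chrom = chrom, pos_1based = as.numeric(pos),
             id = sprintf("snp%05d", seq_len(n_snps)),
             in_element = inside)
}

#' Simulate a full synthetic dataset with planted truth
#'
#' Runs [make_truth()], [make_genome()], [simulate_contacts()] and
#' [simulate_functional_layers()] under one configuration and bundles the
#' results. Identical configurations (including the seed) give identical
#' output, byte-for-byte once written with [write_dataset()].
#'
#' @param config a [synthetic_config()]
#' @return an object of class `synthetic_dataset`
#' @export
simulate_dataset <- function(config = synthetic_config()) {
  truth <- make_truth(config)
  genome <- make_genome(config, truth)
  contacts <- simulate_contacts(truth, config)
  layers <- simulate_functional_layers(truth, genome, config)
  structure(list(config = config, truth = truth, genome = genome,
                 contacts = contacts, layers = layers),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(paste0("synthetic_dataset: %d chromosomes x %.1f Mb @ %d bp ",
                     "bins\n  %d genes, %d planted loops, %d ATAC peaks, ",
                     "%d H3K27ac peaks, %d SNPs\n"),
              x$config$n_chromosomes, x$config$chrom_length_bp / 1e6,
              x$config$bin_size_bp, nrow(x$genome$genes),
              nrow(x$truth$loops), nrow(x$layers$atac_peaks),
              nrow(x$layers$h3k27ac_peaks), nrow(x$layers$snps)))
  invisible(x)
}

#' Write a synthetic dataset to standard text formats
#'
#' Emits `chrom.sizes`, `contacts.<chrom>.coo`, `genes.gff3`,
#' `atac_sample1.bed` / `atac_sample2.bed` / `h3k27ac.bed`,
#' `meth_<ctx>.bedGraph`, `atac_depth_sample{1,2}.bedGraph`,
#' `h3k27ac_depth.bedGraph`, `expression.tsv`, `snps.tsv` and
#' `truth.json`.
#'
#' @param sim a [simulate_dataset()] result
#' @param outdir output directory (created if needed)
#' @return `outdir`, invisibly
#' @export
write_dataset <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg <- sim$config
  p <- function(...) file.path(outdir, ...)
  write.table(data.frame(chrom_names(cfg), format(cfg$chrom_length_bp,
                                                  scientific = FALSE)),
              p("chrom.sizes"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  for (ch in names(sim$contacts))
    write_contacts(sim$contacts[[ch]], p(sprintf("contacts.%s.coo", ch)))
  write_gff3(sim$genome$genes, p("genes.gff3"))
  write_bed(sim$layers$atac_peaks, p("atac_sample1.bed"))
  write_bed(sim$layers$atac_peaks_sample2, p("atac_sample2.bed"))
  write_bed(sim$layers$h3k27ac_peaks, p("h3k27ac.bed"))
  for (ctx in names(sim$layers$methylation))
    write_bedgraph(sim$layers$methylation[[ctx]],
                   p(sprintf("meth_%s.bedGraph", ctx)))
  bs <- cfg$bin_size_bp
  nb <- bins_per_chrom(cfg)
  bin_starts <- (seq_len(nb) - 1L) * bs
  for (nm in c("gc", "ltr")) {
    tr <- do.call(rbind, lapply(chrom_names(cfg), function(ch)
      data.frame(chrom = ch, start = bin_starts, end = bin_starts + bs,
                 value = round(sim$genome[[nm]][[ch]], 4))))
    write_bedgraph(tr, p(sprintf("%s.bedGraph", nm)))
  }
  write_bedgraph(sim$layers$atac_depth_sample1, p("atac_depth_sample1.bedGraph"))
  write_bedgraph(sim$layers$atac_depth_sample2, p("atac_depth_sample2.bedGraph"))
  write_bedgraph(sim$layers$h3k27ac_depth, p("h3k27ac_depth.bedGraph"))
  write.table(sim$layers$expression, p("expression.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$layers$snps[, c("chrom", "pos_1based", "id")],
              p("snps.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  truth_json <- list(
    compartment_labels = sim$truth$compartment_labels,
    tad_boundaries = sim$truth$tad_boundaries,
    loop_pixels = sim$truth$loops[, c("chrom", "i", "j")],
    differential_gene = sim$layers$differential_gene,
    snp_in_element = sim$layers$snps$in_element)
  jsonlite::write_json(truth_json, p("truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(outdir)
}
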