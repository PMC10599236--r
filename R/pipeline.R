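pipeline_defaults <- function() {
  list(seed = 1L,
       input_dir = NULL,
       compartment_rebin_factor = 1L,
       insulation_window = 5L,
       boundary_delta = 0.1,
       min_tad_bins = 3L,
       tad_resolution_factors = c(1L, 2L, 4L),
       loop_q = 0.05,
       loop_donut_enrichment = 1.75,
       loop_lowerleft_enrichment = 1.5,
       loop_min_dist_bins = 2L,
       loop_max_dist_bp = 2e6,
       promoter_upstream = 3000,
       da_lfc = 1,
       da_alpha = 0.05,
       synthetic = list())
}

#' Validate a pipeline configuration
#'
#' Reads a YAML key/value file (or takes a list), fills documented
#' defaults, rejects unknown keys by name and range-checks every
#' threshold. The optional `synthetic` block holds overrides for
#' [synthetic_config()] and is used when no `input_dir` is given.
#'
#' @param config path to a YAML file, or a named list
#' @return a validated `pipeline_config` list
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop2("config file not found: ", config)
    config <- yaml::read_yaml(config) %||% list()
  }
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop2("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  syn_unknown <- setdiff(names(cfg$synthetic),
                         names(formals(synthetic_config)))
  if (length(syn_unknown))
    stop2("unknown synthetic config key(s): ",
          paste(syn_unknown, collapse = ", "))
  chk <- function(cond, msg) if (!cond) stop2("config error: ", msg)
  chk(cfg$loop_q > 0 && cfg$loop_q <= 1, "loop_q must be in (0, 1]")
  chk(cfg$da_alpha > 0 && cfg$da_alpha < 1, "da_alpha must be in (0, 1)")
  chk(cfg$boundary_delta >= 0, "boundary_delta must be >= 0")
  chk(cfg$insulation_window >= 1, "insulation_window must be >= 1")
  chk(cfg$min_tad_bins >= 1, "min_tad_bins must be >= 1")
  chk(cfg$promoter_upstream > 0, "promoter_upstream must be positive")
  chk(cfg$loop_donut_enrichment >= 1, "loop_donut_enrichment must be >= 1")
  chk(cfg$loop_lowerleft_enrichment >= 1,
      "loop_lowerleft_enrichment must be >= 1")
  chk(cfg$loop_min_dist_bins >= 1, "loop_min_dist_bins must be >= 1")
  chk(cfg$loop_max_dist_bp > 0, "loop_max_dist_bp must be positive")
  chk(all(cfg$tad_resolution_factors >= 1),
      "tad_resolution_factors must be >= 1")
  if (!is.null(cfg$input_dir))
    chk(dir.exists(cfg$input_dir),
        paste0("input_dir does not exist: ", cfg$input_dir))
  class(cfg) <- "pipeline_config"
  cfg
}

log_stage <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

read_input_dir <- function(dir, config) {
  req <- function(f) {
    path <- file.path(dir, f)
    if (!file.exists(path)) stop2("missing input file: ", path)
    path
  }
  sizes <- read_chrom_sizes(req("chrom.sizes"))
  coo <- list.files(dir, pattern = "^contacts\\..*\\.coo$")
  if (!length(coo)) stop2("missing input file: contacts.<chrom>.coo in ", dir)
  ## infer bin size from the densest COO: max index vs chromosome length
  contacts <- list()
  for (f in coo) {
    ch <- sub("^contacts\\.(.*)\\.coo$", "\\1", f)
    len <- sizes$length[sizes$chrom == ch]
    tab <- read.table(file.path(dir, f))
    nb <- max(tab[[1]], tab[[2]]) + 1L
    bin_size <- as.integer(len / nb)
    contacts[[ch]] <- read_contacts(file.path(dir, f), req("chrom.sizes"),
                                    ch, bin_size)
  }
  list(chrom_sizes = sizes,
       contacts = contacts,
       genes = read_gff3(req("genes.gff3")),
       atac_peaks = read_bed(req("atac_sample1.bed")),
       h3k27ac_peaks = read_bed(req("h3k27ac.bed")),
       methylation = list(CG = read_bedgraph(req("meth_CG.bedGraph")),
                          CHG = read_bedgraph(req("meth_CHG.bedGraph")),
                          CHH = read_bedgraph(req("meth_CHH.bedGraph"))),
       gc = read_bedgraph(req("gc.bedGraph")),
       ltr = read_bedgraph(req("ltr.bedGraph")),
       atac_depth1 = read_bedgraph(req("atac_depth_sample1.bedGraph")),
       atac_depth2 = read_bedgraph(req("atac_depth_sample2.bedGraph")),
       h3k27ac_depth = read_bedgraph(req("h3k27ac_depth.bedGraph")),
       expression = read.table(req("expression.tsv"), header = TRUE,
                               col.names = c("gene_id", "value")),
       snps = read.table(req("snps.tsv"), header = TRUE))
}

inputs_from_dataset <- function(sim) {
  cfg <- sim$config
  bs <- cfg$bin_size_bp
  nb <- bins_per_chrom(cfg)
  bin_starts <- (seq_len(nb) - 1L) * bs
  bin_tr <- function(lst) do.call(rbind, lapply(chrom_names(cfg), function(ch)
    data.frame(chrom = ch, start = bin_starts, end = bin_starts + bs,
               value = lst[[ch]])))
  list(chrom_sizes = data.frame(chrom = chrom_names(cfg),
                                length = cfg$chrom_length_bp),
       contacts = sim$contacts,
       genes = sim$genome$genes,
       atac_peaks = sim$layers$atac_peaks,
       h3k27ac_peaks = sim$layers$h3k27ac_peaks,
       methylation = sim$layers$methylation,
       gc = bin_tr(sim$genome$gc),
       ltr = bin_tr(sim$genome$ltr),
       atac_depth1 = sim$layers$atac_depth_sample1,
       atac_depth2 = sim$layers$atac_depth_sample2,
       h3k27ac_depth = sim$layers$h3k27ac_depth,
       expression = sim$layers$expression,
       snps = sim$layers$snps)
}

#' Run the full 3D-chromatin pipeline
#'
#' Executes the stages in dependency order — contact balancing, A/B
#' compartments, multi-resolution TADs with epigenetic clustering, loop
#' calling with gene classification and expression association,
#' ACR/enhancer annotation with loop-mediated enhancer-gene links and
#' differential accessibility, and SNP density/enrichment — on the files
#' under `config$input_dir` or, when that is unset, on a synthetic dataset
#' generated from `config$synthetic` (seeded by `config$seed`). Each stage
#' logs its input/output sizes to stderr.
#'
#' @param config a [validate_config()] result (or anything it accepts)
#' @param outdir optional output directory; when given, the stage outputs
#'   and a JSON run report are written there
#' @return a `run_report` list of per-stage summary statistics
#' @export
run_all <- function(config = list(), outdir = NULL) {
  config <- validate_config(config)
  if (is.null(config$input_dir)) {
    syn <- do.call(synthetic_config,
                   utils::modifyList(config$synthetic,
                                     list(rng_seed = config$seed)))
    log_stage("simulate", "generating synthetic dataset (seed %d)",
              config$seed)
    inputs <- inputs_from_dataset(simulate_dataset(syn))
  } else {
    log_stage("input", "reading %s", config$input_dir)
    inputs <- read_input_dir(config$input_dir, config)
  }
  chroms <- names(inputs$contacts)
  genes <- inputs$genes
  chrom_sizes <- inputs$chrom_sizes
  genome_length <- sum(chrom_sizes$length)

  ## ---- contacts ----
  balanced <- lapply(inputs$contacts, ice_balance)
  log_stage("contacts", "%d chromosomes balanced", length(balanced))

  ## ---- per-chromosome bin tracks for compartments/domains ----
  tracks <- list()
  for (ch in chroms) {
    m <- balanced[[ch]]
    nb <- n_bins(m)
    tr <- list(
      gene_density = {
        g <- genes[genes$chrom == ch, , drop = FALSE]
        as.numeric(tabulate(pmin(floor((g$start + g$end) / 2 / m$bin_size),
                                 nb - 1) + 1L, nb))
      },
      gc = bin_track(inputs$gc, ch, m$bin_size, nb),
      ltr = bin_track(inputs$ltr, ch, m$bin_size, nb),
      cg = bin_track(inputs$methylation$CG, ch, m$bin_size, nb),
      chg = bin_track(inputs$methylation$CHG, ch, m$bin_size, nb),
      chh = bin_track(inputs$methylation$CHH, ch, m$bin_size, nb),
      atac = bin_track(inputs$atac_depth1, ch, m$bin_size, nb),
      h3k27ac = bin_track(inputs$h3k27ac_depth, ch, m$bin_size, nb),
      ## expression enters the marker matrix on the log scale so a handful
      ## of very highly expressed genes cannot dominate the z-scores
      expression = gene_expression_track(
        genes, transform(inputs$expression, value = log2(1 + value)), ch,
        m$bin_size, nb))
    tracks[[ch]] <- tr
  }

  ## ---- compartments ----
  comp <- lapply(chroms, function(ch)
    call_compartments(balanced[[ch]], tracks[[ch]]$gene_density,
                      genes = genes[genes$chrom == ch, , drop = FALSE],
                      tracks = tracks[[ch]]))
  names(comp) <- chroms
  pct_A <- 100 * sum(sapply(comp, function(x)
    sum(x$label == "A", na.rm = TRUE))) /
    sum(sapply(comp, function(x) sum(!is.na(x$label))))
  comp_stats <- list(
    n_A_segments = sum(sapply(comp, function(x) x$stats$n_A_segments)),
    n_B_segments = sum(sapply(comp, function(x) x$stats$n_B_segments)),
    pct_A = pct_A, pct_B = 100 - pct_A,
    genes_in_A = sum(sapply(comp, function(x) x$stats$genes_in_A)),
    genes_in_B = sum(sapply(comp, function(x) x$stats$genes_in_B)))
  log_stage("compartments", "%.1f%% A / %.1f%% B, %d+%d segments",
            comp_stats$pct_A, comp_stats$pct_B,
            comp_stats$n_A_segments, comp_stats$n_B_segments)

  ## ---- domains ----
  tads_by_res <- list()
  for (ch in chroms) {
    res <- multi_resolution_tads(inputs$contacts[[ch]],
                                 factors = config$tad_resolution_factors,
                                 window_bins = config$insulation_window,
                                 delta_threshold = config$boundary_delta,
                                 min_tad_bins = config$min_tad_bins)
    for (nm in names(res))
      tads_by_res[[nm]] <- rbind(tads_by_res[[nm]], res[[nm]])
  }
  tad_counts <- sapply(tads_by_res, nrow)
  native <- names(tads_by_res)[1]
  tads <- tads_by_res[[native]]
  ## marker matrix across chromosomes at native resolution
  marker_rows <- list()
  for (ch in chroms) {
    tch <- tads[tads$chrom == ch, , drop = FALSE]
    if (nrow(tch) < 2) next
    marker_rows[[ch]] <- sapply(names(tracks[[ch]]), function(nm)
      apply(tch, 1, function(td)
        mean(tracks[[ch]][[nm]][(as.numeric(td["start_bin"]) + 1):
                                  as.numeric(td["end_bin"])], na.rm = TRUE)))
  }
  raw_markers <- do.call(rbind, marker_rows)
  zmat <- scale(raw_markers)
  clust <- cluster_tads(zmat, k = min(3L, nrow(zmat)))
  log_stage("domains", "TADs per resolution: %s",
            paste(sprintf("%s=%d", names(tad_counts), tad_counts),
                  collapse = ", "))

  ## ---- loops ----
  loop_list <- lapply(chroms, function(ch)
    call_loops(balanced[[ch]],
               min_dist_bins = config$loop_min_dist_bins,
               max_dist_bp = config$loop_max_dist_bp,
               q_threshold = config$loop_q,
               donut_enrichment = config$loop_donut_enrichment,
               lowerleft_enrichment = config$loop_lowerleft_enrichment))
  loops <- do.call(rbind, loop_list)
  loops <- classify_loops(loops, genes)
  cat_counts <- table(factor(loops$category,
                             levels = c("gene-gene", "gene-intergenic",
                                        "intergenic-intergenic")))
  profiles <- loops_per_gene(loops, genes)
  expr_trend <- expression_by_loopcount(profiles, inputs$expression)
  dist_stats <- loop_distance_stats(loops)
  log_stage("loops", "%d loops (%s)", nrow(loops),
            paste(sprintf("%s=%d", names(cat_counts), as.integer(cat_counts)),
                  collapse = ", "))

  ## ---- elements ----
  acrs <- classify_acrs(inputs$atac_peaks, genes, chrom_sizes,
                        upstream = config$promoter_upstream)
  acr_counts <- table(factor(acrs$element_class,
                             levels = c("promoter_ACR", "other_ACR",
                                        "distal_ACR")))
  enhancers <- define_enhancers(inputs$h3k27ac_peaks, genes, chrom_sizes,
                                upstream = config$promoter_upstream)
  enhancers <- mark_active(enhancers, inputs$atac_peaks)
  links <- link_enhancer_genes(enhancers, loops, genes, chrom_sizes,
                               upstream = config$promoter_upstream)
  prom_expr <- promoter_acr_expression(
    genes, acrs[acrs$element_class == "promoter_ACR", , drop = FALSE],
    inputs$expression, chrom_sizes, upstream = config$promoter_upstream)
  da <- differential_accessibility(inputs$atac_depth1, inputs$atac_depth2,
                                   inputs$atac_peaks,
                                   lfc_threshold = config$da_lfc,
                                   alpha = config$da_alpha)
  log_stage("elements", "%d ACRs (%s); %d enhancers (%.0f%% active)",
            nrow(acrs),
            paste(sprintf("%s=%d", names(acr_counts), as.integer(acr_counts)),
                  collapse = ", "),
            nrow(enhancers), 100 * attr(enhancers, "active_fraction"))

  ## ---- variants ----
  elements <- rbind(
    data.frame(chrom = acrs$chrom, start = acrs$start, end = acrs$end,
               element_class = acrs$element_class)[
                 acrs$element_class == "promoter_ACR", ],
    data.frame(chrom = enhancers$chrom, start = enhancers$start,
               end = enhancers$end, element_class = "enhancer"))
  dens <- snp_density(inputs$snps, elements, genome_length, chrom_sizes)
  log_stage("variants", "%s",
            paste(sprintf("%s: %.2f SNPs/kb (%.1fx)", dens$class_name,
                          dens$density_snps_per_kb, dens$enrichment),
                  collapse = "; "))

  report <- list(
    version = as.character(utils::packageVersion("chroma3d")),
    config = unclass(config)[setdiff(names(config), "synthetic")],
    compartments = comp_stats,
    tad_counts = as.list(tad_counts),
    tad_cluster_sizes = as.list(table(clust$role)),
    loops = list(total = nrow(loops),
                 by_category = as.list(cat_counts),
                 fraction_within_400kb = dist_stats$fraction_within,
                 expression_spearman_rho = expr_trend$rho),
    elements = list(atac_peaks = nrow(acrs),
                    acr_classes = as.list(acr_counts),
                    n_enhancers = nrow(enhancers),
                    n_active_enhancers = sum(enhancers$active),
                    active_fraction = attr(enhancers, "active_fraction"),
                    n_enhancer_anchors = links$n_enhancer_anchors,
                    n_linked_genes = links$n_genes,
                    promoter_acr_expression_p = prom_expr$p_value,
                    n_differential_peaks = sum(da$differential)),
    snp_density = dens)
  class(report) <- "run_report"

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_run_outputs(outdir, comp, tads_by_res, loops, acrs, enhancers,
                      dens, profiles, report)
  }
  report
}

write_run_outputs <- function(outdir, comp, tads_by_res, loops, acrs,
                              enhancers, dens, profiles, report) {
  p <- function(...) file.path(outdir, ...)
  seg <- do.call(rbind, lapply(comp, function(x) {
    s <- x$segments
    data.frame(chrom = x$chrom, start = s$start_bin * x$bin_size,
               end = s$end_bin * x$bin_size, peak_id = s$label)
  }))
  write_bed(seg, p("compartments.bed"))
  pc1 <- do.call(rbind, lapply(comp, function(x) {
    nb <- length(x$pc1)
    data.frame(chrom = x$chrom, start = (seq_len(nb) - 1) * x$bin_size,
               end = seq_len(nb) * x$bin_size,
               value = round(ifelse(is.na(x$pc1), 0, x$pc1), 6))
  }))
  write_bedgraph(pc1, p("pc1.bedGraph"))
  for (nm in names(tads_by_res)) {
    td <- tads_by_res[[nm]]
    write_bed(data.frame(chrom = td$chrom, start = td$start, end = td$end,
                         peak_id = sprintf("tad%04d", seq_len(nrow(td)))),
              p(sprintf("tads_%s.bed", nm)))
  }
  bedpe <- data.frame(loops$chrom, loops$anchor1_start, loops$anchor1_end,
                      loops$chrom, loops$anchor2_start, loops$anchor2_end,
                      sprintf("loop%05d", seq_len(nrow(loops))),
                      round(-log10(pmax(loops$q, 1e-300)), 3), ".", ".",
                      loops$observed, round(loops$expected_local, 3),
                      signif(loops$q, 4), loops$category)
  write.table(bedpe, p("loops.bedpe"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(profiles, p("gene_loops.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_bed(data.frame(chrom = acrs$chrom, start = acrs$start,
                       end = acrs$end, peak_id = acrs$element_class),
            p("acrs.bed"))
  write_bed(data.frame(chrom = enhancers$chrom, start = enhancers$start,
                       end = enhancers$end,
                       peak_id = ifelse(enhancers$active, "active_enhancer",
                                        "enhancer")),
            p("enhancers.bed"))
  write.table(dens, p("snp_density.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(unclass(report), p("report.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
}

#' @export
print.run_report <- function(x, ...) {
  cat("chroma3d run report\n")
  cat(sprintf("  compartments: %.1f%% A / %.1f%% B (%d A + %d B segments)\n",
              x$compartments$pct_A, x$compartments$pct_B,
              x$compartments$n_A_segments, x$compartments$n_B_segments))
  cat(sprintf("  TADs: %s\n",
              paste(sprintf("%s=%s", names(x$tad_counts), x$tad_counts),
                    collapse = ", ")))
  cat(sprintf("  loops: %d (%s); %.1f%% within 400 kb\n", x$loops$total,
              paste(sprintf("%s=%s", names(x$loops$by_category),
                            x$loops$by_category), collapse = ", "),
              100 * x$loops$fraction_within_400kb))
  cat(sprintf("  elements: %d ACRs; %d enhancers, %d active (%.0f%%)\n",
              x$elements$atac_peaks, x$elements$n_enhancers,
              x$elements$n_active_enhancers,
              100 * x$elements$active_fraction))
  cat(sprintf("  enhancer-gene links: %d anchors, %d genes\n",
              x$elements$n_enhancer_anchors, x$elements$n_linked_genes))
  for (i in seq_len(nrow(x$snp_density)))
    cat(sprintf("  SNPs in %s: %.2f /kb (%.1fx genome-wide)\n",
                x$snp_density$class_name[i],
                x$snp_density$density_snps_per_kb[i],
                x$snp_density$enrichment[i]))
  invisible(x)
}
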