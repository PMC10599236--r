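#' First principal component of the O/E correlation map
#'
#' Computes the Pearson correlation matrix of the O/E columns over valid
#' bins, double-centres it, and extracts the leading eigenvector (unit
#' norm) by power iteration. The sign is arbitrary until
#' [orient_and_label()].
#'
#' @param oe an O/E matrix from [oe_transform()] (masked bins `NA`)
#' @return numeric vector of length `nrow(oe)` with `NA` at masked bins
#' @export
correlation_pc1 <- function(oe) {
  valid <- which(colSums(is.finite(oe)) > 0)
  if (length(valid) < 3) stop2("need >= 3 valid bins for compartment PCA")
  sub <- oe[valid, valid, drop = FALSE]
  C <- suppressWarnings(cor(sub))
  if (any(!is.finite(C))) {
    zv <- apply(sub, 2, sd) == 0
    if (all(zv)) stop2("O/E matrix has no variance; cannot compute PC1")
    C[!is.finite(C)] <- 0
  }
  ## double-centre (preserves symmetry), then dominant eigenvector
  M <- C - matrix(rowMeans(C), nrow(C), ncol(C)) -
    matrix(colMeans(C), nrow(C), ncol(C), byrow = TRUE) + mean(C)
  v <- power_iteration(M)
  out <- rep(NA_real_, nrow(oe))
  out[valid] <- v
  out
}

## dominant eigenvector by |eigenvalue|, unit norm; deterministic start
power_iteration <- function(M, tol = 1e-12, max_iter = 10000L) {
  n <- nrow(M)
  v <- seq_len(n) / sqrt(sum(seq_len(n)^2))
  for (it in seq_len(max_iter)) {
    u <- M %*% v
    nu <- sqrt(sum(u^2))
    if (nu == 0) return(as.numeric(v))
    u <- as.numeric(u / nu)
    if (sum((u - v)^2) < tol^2 || sum((u + v)^2) < tol^2) return(u)
    v <- u
  }
  v
}

#' Orient PC1 by gene density and assign A/B labels
#'
#' The eigenvector sign is flipped iff its Pearson correlation with gene
#' density is negative, so that positive PC1 marks the gene-rich (A)
#' compartment. Bins with PC1 exactly 0 inherit the label of the previous
#' bin (or the next labelled bin at the chromosome start).
#'
#' @param pc1 vector from [correlation_pc1()]
#' @param gene_density per-bin gene counts, same length
#' @return list with `pc1` (oriented) and `label` ("A"/"B", `NA` at masked
#'   bins)
#' @export
orient_and_label <- function(pc1, gene_density) {
  if (length(pc1) != length(gene_density))
    stop2("pc1 and gene_density lengths differ")
  ok <- is.finite(pc1) & is.finite(gene_density)
  if (sd(gene_density[ok]) == 0) {
    warning("gene density has zero variance; PC1 orientation undetermined",
            call. = FALSE)
  } else if (cor(pc1[ok], gene_density[ok]) < 0) {
    pc1 <- -pc1
  }
  label <- ifelse(is.na(pc1), NA_character_,
                  ifelse(pc1 > 0, "A", ifelse(pc1 < 0, "B", "")))
  ## tie rule: zero bins inherit the previous label
  idx <- which(!is.na(label) & label == "")
  for (i in idx) {
    prev <- which(!is.na(label) & label != "" & seq_along(label) < i)
    if (length(prev)) label[i] <- label[max(prev)]
  }
  ## leading zeros: inherit the next labelled bin
  idx <- which(!is.na(label) & label == "")
  for (i in rev(idx)) {
    nxt <- which(!is.na(label) & label != "" & seq_along(label) > i)
    if (length(nxt)) label[i] <- label[min(nxt)] else label[i] <- "A"
  }
  list(pc1 = pc1, label = label)
}

#' Segment compartment labels and summarise per-class features
#'
#' Maximal same-label runs of valid bins become segments; per-class genome
#' percentages are over valid bins; genes are assigned to the compartment
#' containing their midpoint bin (half-open: a midpoint on a bin edge
#' belongs to the right bin); each supplied per-bin track is averaged per
#' class.
#'
#' @param label per-bin "A"/"B" vector (`NA` allowed)
#' @param bin_size bin width in bp
#' @param genes optional gene frame (chrom/start/end/gene_id) restricted to
#'   this chromosome
#' @param tracks optional named list of per-bin numeric tracks
#' @return list with `segments` (start_bin, end_bin half-open, label),
#'   `stats` (n_A_segments, n_B_segments, pct_A, pct_B, genes_in_A,
#'   genes_in_B) and `track_means` (data.frame track x class)
#' @export
segment_and_summarize <- function(label, bin_size, genes = NULL,
                                  tracks = list()) {
  if (length(label) == 0) stop2("empty label vector")
  valid <- !is.na(label)
  if (!any(valid)) stop2("no labelled bins")
  r <- rle(label[valid])
  vidx <- which(valid)
  ends <- cumsum(r$lengths)
  starts <- c(1, head(ends, -1) + 1)
  segments <- data.frame(start_bin = vidx[starts] - 1L,
                         end_bin = vidx[ends],    # half-open in bin units
                         label = r$values)
  nA <- sum(r$values == "A"); nB <- sum(r$values == "B")
  pctA <- 100 * sum(label[valid] == "A") / sum(valid)
  stats <- list(n_A_segments = nA, n_B_segments = nB,
                pct_A = pctA, pct_B = 100 - pctA)
  if (!is.null(genes) && nrow(genes)) {
    mid_bin <- floor(floor((genes$start + genes$end) / 2) / bin_size) + 1L
    mid_bin <- pmin(mid_bin, length(label))
    gl <- label[mid_bin]
    stats$genes_in_A <- sum(gl == "A", na.rm = TRUE)
    stats$genes_in_B <- sum(gl == "B", na.rm = TRUE)
  } else {
    stats$genes_in_A <- 0L; stats$genes_in_B <- 0L
  }
  track_means <- NULL
  if (length(tracks)) {
    track_means <- do.call(rbind, lapply(names(tracks), function(nm) {
      tr <- tracks[[nm]]
      data.frame(track = nm,
                 mean_A = mean(tr[valid & label == "A"], na.rm = TRUE),
                 mean_B = mean(tr[valid & label == "B"], na.rm = TRUE))
    }))
  }
  list(segments = segments, stats = stats, track_means = track_means)
}

#' Call A/B compartments on one chromosome
#'
#' Convenience wrapper: ICE-balanced matrix -> decay expectation -> O/E ->
#' correlation PC1 -> gene-density orientation -> segmentation.
#'
#' @param m a raw or balanced [contact_matrix()]
#' @param gene_density per-bin gene counts
#' @param genes,tracks passed to [segment_and_summarize()]
#' @return an object of class `compartment_call`
#' @export
call_compartments <- function(m, gene_density, genes = NULL, tracks = list()) {
  if (!m$balanced) m <- ice_balance(m)
  prof <- expected_by_distance(m)
  oe <- oe_transform(m, prof)
  pc1 <- correlation_pc1(oe)
  ol <- orient_and_label(pc1, gene_density)
  seg <- segment_and_summarize(ol$label, m$bin_size, genes = genes,
                               tracks = tracks)
  structure(list(chrom = m$chrom, bin_size = m$bin_size, pc1 = ol$pc1,
                 label = ol$label, segments = seg$segments,
                 stats = seg$stats, track_means = seg$track_means),
            class = "compartment_call")
}

#' @export
print.compartment_call <- function(x, ...) {
  cat(sprintf(
    "compartment_call: %s — %d A / %d B segments; %.1f%% A, %.1f%% B\n",
    x$chrom, x$stats$n_A_segments, x$stats$n_B_segments,
    x$stats$pct_A, x$stats$pct_B))
  invisible(x)
}
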