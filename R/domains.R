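#' Insulation score along a chromosome
#'
#' For each interior bin `i`, the diamond mean is the average balanced
#' contact value over `balanced[(i-w)..(i-1), (i+1)..(i+w)]` (valid pixels
#' only); the score is `log2(diamond / chromosome-wide mean diamond)`.
#' Scores are undefined (`NA`) within `window_bins` of the chromosome ends
#' and where the diamond is fully masked.
#'
#' @param m a balanced [contact_matrix()]
#' @param window_bins diamond half-width in bins (default 5)
#' @return an object of class `insulation_profile`: list with `chrom`,
#'   `window_bins`, `score` (per bin)
#' @export
insulation_score <- function(m, window_bins = 5L) {
  b <- balanced_counts(m)
  nb <- n_bins(m)
  w <- as.integer(window_bins)
  if (w < 1L) stop2("window_bins must be >= 1")
  if (w > nb / 2) stop2("window larger than half the chromosome")
  dm <- rep(NA_real_, nb)
  for (i in (w + 1):(nb - w)) {
    block <- b[(i - w):(i - 1), (i + 1):(i + w), drop = FALSE]
    v <- block[!is.na(block)]
    if (length(v)) dm[i] <- mean(v)
  }
  mu <- mean(dm, na.rm = TRUE)
  score <- log2(dm / mu)
  score[!is.finite(score)] <- NA_real_
  structure(list(chrom = m$chrom, window_bins = w, bin_size = m$bin_size,
                 score = score),
            class = "insulation_profile")
}

#' Call TAD boundaries from an insulation profile
#'
#' Boundaries are local minima of the insulation score whose prominence —
#' the smaller of the rises to the intervening maxima towards the
#' neighbouring minima (or the ends of the scored region) — is at least
#' `delta_threshold`. A plateau of equal minima keeps its leftmost bin.
#'
#' @param profile an [insulation_score()] result
#' @param delta_threshold minimum prominence (default 0.1)
#' @return data.frame (bin — 0-based, strength)
#' @export
call_boundaries <- function(profile, delta_threshold = 0.1) {
  s <- profile$score
  ok <- which(!is.na(s))
  if (length(ok) < 3)
    return(data.frame(bin = integer(0), strength = numeric(0)))
  x <- s[ok]
  n <- length(x)
  ## local minima; a plateau of equal values keeps its leftmost bin
  is_min <- logical(n)
  for (i in 2:(n - 1)) {
    if (x[i] < x[i - 1] && x[i] <= x[i + 1]) is_min[i] <- TRUE
  }
  mins <- which(is_min)
  if (!length(mins))
    return(data.frame(bin = integer(0), strength = numeric(0)))
  ## prominence: max of x between consecutive minima (and to region ends)
  bounds <- c(0, mins, n + 1)
  strength <- numeric(length(mins))
  for (k in seq_along(mins)) {
    i <- mins[k]
    lseg <- x[max(1, bounds[k] + 1):i]
    rseg <- x[i:min(n, bounds[k + 2] - 1)]
    strength[k] <- min(max(lseg) - x[i], max(rseg) - x[i])
  }
  keep <- strength >= delta_threshold
  data.frame(bin = ok[mins[keep]] - 1L, strength = strength[keep])
}

#' Assemble TADs from boundaries
#'
#' Chromosome ends count as boundaries; consecutive boundary pairs become
#' TAD intervals (half-open, in bins); intervals shorter than
#' `min_tad_bins` are discarded.
#'
#' @param boundaries sorted 0-based boundary bins (vector or the frame from
#'   [call_boundaries()])
#' @param chrom_bins number of bins on the chromosome
#' @param min_tad_bins minimum TAD length in bins (default 3)
#' @return data.frame (start_bin, end_bin)
#' @export
assemble_tads <- function(boundaries, chrom_bins, min_tad_bins = 3L) {
  if (is.data.frame(boundaries)) boundaries <- boundaries$bin
  cut <- unique(c(0L, sort(as.integer(boundaries)), as.integer(chrom_bins)))
  tads <- data.frame(start_bin = cut[-length(cut)], end_bin = cut[-1])
  tads <- tads[tads$end_bin - tads$start_bin >= min_tad_bins, , drop = FALSE]
  rownames(tads) <- NULL
  tads
}

#' Call TADs on one chromosome, optionally at multiple resolutions
#'
#' `call_tads()` runs balancing, insulation scoring, boundary calling and
#' assembly at the matrix's native resolution. `multi_resolution_tads()`
#' repeats this after coarsening the raw matrix by each factor; finer
#' resolutions resolve at least as many domains as coarser ones on
#' structured maps.
#'
#' @param m a [contact_matrix()] (raw; balanced internally)
#' @param window_bins,delta_threshold,min_tad_bins caller parameters
#' @return data.frame of TADs with bp coordinates (`start`, `end`) added
#' @export
call_tads <- function(m, window_bins = 5L, delta_threshold = 0.1,
                      min_tad_bins = 3L) {
  mb <- if (m$balanced) m else ice_balance(m)
  prof <- insulation_score(mb, window_bins)
  b <- call_boundaries(prof, delta_threshold)
  tads <- assemble_tads(b, n_bins(mb), min_tad_bins)
  tads$chrom <- mb$chrom
  tads$resolution_bp <- mb$bin_size
  tads$start <- tads$start_bin * mb$bin_size
  tads$end <- pmin(tads$end_bin * mb$bin_size, mb$chrom_length)
  tads
}

#' @rdname call_tads
#' @param factors integer coarsening factors (1 = native resolution)
#' @export
multi_resolution_tads <- function(m, factors = c(1L, 2L, 4L),
                                  window_bins = 5L, delta_threshold = 0.1,
                                  min_tad_bins = 3L) {
  setNames(lapply(factors, function(f)
    call_tads(rebin(m, f), window_bins, delta_threshold, min_tad_bins)),
    paste0(sapply(factors, function(f) m$bin_size * f), "bp"))
}

#' Per-TAD marker matrix (z-scored)
#'
#' Averages each per-bin track over the bins of each TAD, then z-scores
#' each column. Zero-variance tracks become `NA` columns and are flagged.
#'
#' @param tads TAD frame (start_bin, end_bin)
#' @param tracks named list of per-bin numeric tracks
#' @return numeric matrix (TADs x tracks) with attribute `flagged` naming
#'   zero-variance tracks
#' @export
tad_marker_matrix <- function(tads, tracks) {
  if (nrow(tads) < 2) stop2("need >= 2 TADs to z-score markers")
  if (length(tracks) < 2) stop2("need >= 2 tracks")
  raw <- sapply(tracks, function(tr)
    apply(tads, 1, function(td)
      mean(tr[(td["start_bin"] + 1):td["end_bin"]], na.rm = TRUE)))
  raw <- matrix(raw, nrow = nrow(tads),
                dimnames = list(NULL, names(tracks)))
  sds <- apply(raw, 2, sd, na.rm = TRUE)
  flagged <- names(tracks)[!is.finite(sds) | sds == 0]
  z <- scale(raw)
  z[, colnames(z) %in% flagged] <- NA_real_
  attr(z, "flagged") <- flagged
  z
}

#' Pearson correlation between TAD markers
#'
#' @param marker_matrix a [tad_marker_matrix()] result
#' @return correlation matrix (pairwise-complete)
#' @export
marker_correlation <- function(marker_matrix) {
  suppressWarnings(cor(marker_matrix, use = "pairwise.complete.obs"))
}

#' Cluster TADs by epigenetic markers and assign roles
#'
#' Agglomerative hierarchical clustering (Euclidean distance, Ward
#' linkage) cut at `k`. The cluster with the highest mean active score
#' (mean of the z-scored active marker columns) is "active"; among the
#' remaining clusters the one with the highest mean repressive score is
#' "repressive"; the rest are "intermediate". Role assignment depends only
#' on cluster contents, never on cluster ids.
#'
#' @param marker_matrix a [tad_marker_matrix()] result
#' @param k number of clusters (default 3)
#' @param active_markers,repressive_markers column names used for the role
#'   scores (missing columns are ignored)
#' @return list with `cluster` (integer per TAD), `role` (character per
#'   TAD) and `cluster_roles` (role per cluster id)
#' @export
cluster_tads <- function(marker_matrix, k = 3L,
                         active_markers = c("h3k27ac", "atac", "expression",
                                            "gene_density"),
                         repressive_markers = c("cg", "chg", "chh")) {
  M <- marker_matrix[, colSums(is.na(marker_matrix)) < nrow(marker_matrix),
                     drop = FALSE]
  if (k > nrow(M)) stop2("k exceeds the number of TADs")
  if (all(dist(M) == 0)) stop2("all TADs identical; clustering undefined")
  M0 <- M; M0[is.na(M0)] <- 0
  hc <- hclust(dist(M0), method = "ward.D2")
  cl <- cutree(hc, k = k)
  score <- function(markers, cluster) {
    cols <- intersect(markers, colnames(M))
    if (!length(cols)) return(NA_real_)
    mean(M[cl == cluster, cols], na.rm = TRUE)
  }
  ids <- sort(unique(cl))
  act <- sapply(ids, function(cid) score(active_markers, cid))
  rep_ <- sapply(ids, function(cid) score(repressive_markers, cid))
  roles <- rep("intermediate", length(ids))
  active_id <- ids[which.max(act)]
  roles[ids == active_id] <- "active"
  rest <- ids[ids != active_id]
  if (length(rest)) {
    repress_id <- rest[which.max(rep_[ids %in% rest])]
    roles[ids == repress_id] <- "repressive"
  }
  names(roles) <- ids
  list(cluster = cl, role = unname(roles[as.character(cl)]),
       cluster_roles = roles)
}

#' Locate the TAD completely containing a gene
#'
#' @param gene one-row frame or list with `start`, `end` (bp, half-open)
#' @param tads TAD frame with bp `start`/`end` columns (one chromosome)
#' @return the containing TAD row, or `NULL` if none contains the gene
#'   entirely
#' @export
locate_gene_tad <- function(gene, tads) {
  hit <- which(tads$start <= gene$start & gene$end <= tads$end)
  if (!length(hit)) return(NULL)
  tads[hit[1], , drop = FALSE]
}
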