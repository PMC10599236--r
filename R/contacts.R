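#' Contact matrix container
#'
#' A per-chromosome symmetric matrix of binned intra-chromosomal Hi-C
#' contact counts, with a valid-bin mask and (after [ice_balance()])
#' per-bin balancing weights. Bins are 0-based half-open
#' `[k*bin_size, (k+1)*bin_size)`; the last bin is truncated at the
#' chromosome end.
#'
#' @param counts symmetric non-negative numeric matrix (n_bins x n_bins)
#' @param chrom chromosome name
#' @param bin_size bin width in bp
#' @param chrom_length chromosome length in bp (defaults to
#'   `nrow(counts) * bin_size`)
#' @return an object of class `contact_matrix`: a list with elements
#'   `chrom`, `bin_size`, `chrom_length`, `counts`, `valid` (logical per
#'   bin), `weights` (numeric per bin, `NA` until balanced), `balanced`.
#' @export
contact_matrix <- function(counts, chrom, bin_size,
                           chrom_length = nrow(counts) * bin_size) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop2("contact matrix must be square")
  if (any(counts < 0)) stop2("contact counts must be non-negative")
  if (!isTRUE(all.equal(counts, t(counts), tolerance = 1e-12)))
    stop2("contact matrix must be symmetric")
  n <- nrow(counts)
  if (!(n * bin_size >= chrom_length && chrom_length > (n - 1) * bin_size))
    stop2("bin count inconsistent with chromosome length")
  structure(list(chrom = as.character(chrom), bin_size = as.integer(bin_size),
                 chrom_length = as.numeric(chrom_length), counts = counts,
                 valid = rep(TRUE, n), weights = rep(NA_real_, n),
                 balanced = FALSE),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("contact_matrix: %s, %d bins @ %d bp (%s; %d valid bins)\n",
              x$chrom, nrow(x$counts), x$bin_size,
              if (x$balanced) "balanced" else "raw", sum(x$valid)))
  invisible(x)
}

n_bins <- function(m) nrow(m$counts)

#' Balanced contact values
#'
#' Returns the ICE-balanced matrix `counts[i,j] * w[i] * w[j]` with masked
#' rows/columns set to `NA`.
#'
#' @param m a balanced [contact_matrix()]
#' @return numeric matrix
#' @export
balanced_counts <- function(m) {
  if (!m$balanced) stop2("matrix is not balanced; run ice_balance() first")
  w <- ifelse(m$valid, m$weights, NA_real_)
  m$counts * outer(w, w)
}

#' Read a binned contact matrix from COO text
#'
#' The file has three whitespace-separated columns `bin_i bin_j count`
#' (0-based bins, upper triangle `i <= j` only). Duplicate pixels are
#' summed; absent pixels are zero.
#'
#' @param coo_path path to the COO text file
#' @param chrom_sizes_path path to a `chrom.sizes` file (name TAB length)
#' @param chrom chromosome name (must be present in chrom.sizes)
#' @param bin_size bin width in bp
#' @return a [contact_matrix()]
#' @export
read_contacts <- function(coo_path, chrom_sizes_path, chrom, bin_size) {
  sizes <- read_chrom_sizes(chrom_sizes_path)
  if (!chrom %in% sizes$chrom) stop2("chromosome '", chrom, "' not in chrom.sizes")
  len <- sizes$length[sizes$chrom == chrom]
  nb <- as.integer(ceiling(len / bin_size))
  coo <- read.table(coo_path, header = FALSE,
                    col.names = c("i", "j", "count"))
  bad <- which(coo$i < 0 | coo$j < 0 | coo$i >= nb | coo$j >= nb)
  if (length(bad))
    stop2("bin index out of range [0, ", nb - 1, "] at line ", bad[1],
          " of ", coo_path)
  neg <- which(coo$count < 0)
  if (length(neg)) stop2("negative count at line ", neg[1], " of ", coo_path)
  swap <- coo$i > coo$j
  if (any(swap)) stop2("lower-triangle entry (i > j) at line ", which(swap)[1])
  counts <- matrix(0, nb, nb)
  for (k in seq_len(nrow(coo))) {
    i <- coo$i[k] + 1L; j <- coo$j[k] + 1L
    counts[i, j] <- counts[i, j] + coo$count[k]
  }
  counts[lower.tri(counts)] <- t(counts)[lower.tri(counts)]
  contact_matrix(counts, chrom, bin_size, chrom_length = len)
}

#' Write a contact matrix as COO text (upper triangle, nonzero pixels)
#'
#' @param m a [contact_matrix()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_contacts <- function(m, path) {
  idx <- which(upper.tri(m$counts, diag = TRUE) & m$counts != 0,
               arr.ind = TRUE)
  df <- data.frame(i = idx[, 1] - 1L, j = idx[, 2] - 1L,
                   count = m$counts[idx])
  df <- df[order(df$i, df$j), ]
  write.table(format(df, scientific = FALSE, trim = TRUE), path,
              quote = FALSE, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' ICE iterative-correction balancing
#'
#' Equalises per-bin coverage by iterative correction: low-coverage bins
#' (marginal sum below `mask_quantile` of the nonzero marginals) are
#' masked, then weights are updated as `w <- w / (marginal / mean marginal)`
#' until the coefficient of variation of the balanced marginals drops
#' below `tol` or `max_iter` is reached. Balanced values are
#' `counts[i,j] * w[i] * w[j]`.
#'
#' @param m a [contact_matrix()]
#' @param max_iter maximum iterations (default 200)
#' @param tol CV convergence tolerance on balanced marginals (default 1e-5)
#' @param mask_quantile marginal-sum quantile below which bins are masked
#'   (default 0.02)
#' @return `m` with `weights` filled, `valid` updated and `balanced = TRUE`
#' @export
ice_balance <- function(m, max_iter = 200L, tol = 1e-5, mask_quantile = 0.02) {
  counts <- m$counts
  marg <- rowSums(counts)
  nz <- marg[marg > 0]
  if (length(nz) == 0L) stop2("all bins empty; cannot balance")
  ## type-1 quantile is an order statistic of the data; the 0.1% slack
  ## keeps bins that sit at the cut up to numerical noise, so re-balancing
  ## an already-balanced (near-uniform-marginal) matrix masks nothing new
  cut <- quantile(nz, mask_quantile, names = FALSE, type = 1)
  valid <- marg > 0 & marg >= cut * (1 - 1e-3)
  if (!any(valid)) stop2("all bins masked; cannot balance")
  sub <- counts[valid, valid, drop = FALSE]
  w <- rep(1, nrow(sub))
  for (it in seq_len(max_iter)) {
    b <- sub * outer(w, w)
    s <- rowSums(b)
    mu <- mean(s)
    cv <- sd(s) / mu
    if (is.na(cv)) cv <- 0   # single valid bin
    if (cv < tol) break
    w <- w / (s / mu)
  }
  ## normalise so the mean balanced value equals the mean raw value
  b <- sub * outer(w, w)
  scale <- sqrt(mean(sub) / mean(b))
  if (is.finite(scale) && scale > 0) w <- w * scale
  weights <- rep(NA_real_, n_bins(m))
  weights[valid] <- w
  m$valid <- valid
  m$weights <- weights
  m$balanced <- TRUE
  m
}

#' Distance-decay expectation
#'
#' Mean balanced contact value over valid pixel pairs at each bin
#' separation `d = 0 .. n_bins - 1`. Distances with no valid pair are `NA`
#' and are excluded from downstream division.
#'
#' @param m a balanced [contact_matrix()]
#' @return an object of class `decay_profile`: numeric vector indexed by
#'   distance + 1
#' @export
expected_by_distance <- function(m) {
  b <- balanced_counts(m)
  nb <- n_bins(m)
  out <- rep(NA_real_, nb)
  for (d in 0:(nb - 1)) {
    i <- seq_len(nb - d)
    v <- b[cbind(i, i + d)]
    v <- v[!is.na(v)]
    if (length(v)) out[d + 1] <- mean(v)
  }
  structure(out, class = "decay_profile")
}

#' Observed/expected transformation
#'
#' Divides each balanced pixel by the decay expectation at its distance,
#' floored at `floor` to avoid division blow-ups. Masked bins propagate
#' as `NA`.
#'
#' @param m a balanced [contact_matrix()]
#' @param profile the [expected_by_distance()] profile of `m`
#' @param floor lower bound on the expectation (default 1e-10); pixels
#'   whose expectation hit the floor are flagged in the `"floored"`
#'   attribute
#' @return numeric O/E matrix with attribute `floored` (logical matrix)
#' @export
oe_transform <- function(m, profile, floor = 1e-10) {
  b <- balanced_counts(m)
  nb <- n_bins(m)
  if (length(profile) != nb) stop2("profile length does not match matrix")
  d <- abs(outer(seq_len(nb), seq_len(nb), "-"))
  e <- matrix(unclass(profile)[d + 1], nb, nb)
  floored <- !is.na(e) & e < floor
  oe <- b / pmax(e, floor)
  oe[is.na(e)] <- NA_real_
  attr(oe, "floored") <- floored
  oe
}

#' Coarsen a contact matrix by an integer factor
#'
#' Sums counts within `factor x factor` blocks, producing the same map at
#' `factor * bin_size` resolution. Used to call TADs at multiple
#' resolutions from one base-resolution matrix.
#'
#' @param m a (raw) [contact_matrix()]
#' @param factor integer coarsening factor >= 1
#' @return a raw [contact_matrix()] at the coarser resolution
#' @export
rebin <- function(m, factor) {
  factor <- as.integer(factor)
  if (factor < 1L) stop2("factor must be >= 1")
  if (factor == 1L) {
    m$balanced <- FALSE
    m$weights <- rep(NA_real_, n_bins(m))
    m$valid <- rep(TRUE, n_bins(m))
    return(m)
  }
  nb <- n_bins(m)
  nb2 <- as.integer(ceiling(nb / factor))
  grp <- (seq_len(nb) - 1L) %/% factor + 1L
  agg <- rowsum(m$counts, grp)
  agg <- t(rowsum(t(agg), grp))
  contact_matrix(agg, m$chrom, m$bin_size * factor,
                 chrom_length = m$chrom_length)
}

read_chrom_sizes <- function(path) {
  df <- read.table(path, header = FALSE, col.names = c("chrom", "length"),
                   colClasses = c("character", "numeric"))
  df
}
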