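## Shared fixtures, generated once per test run and cached by seed.

.fixture_cache <- new.env(parent = emptyenv())

## full default synthetic dataset under the study conditions
fixture_dataset <- function(seed = 1L) {
  key <- paste0("sim", seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- simulate_dataset(synthetic_config(rng_seed = seed))
  .fixture_cache[[key]]
}

## balanced contact matrices of a fixture
fixture_balanced <- function(seed = 1L) {
  key <- paste0("bal", seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- lapply(fixture_dataset(seed)$contacts, ice_balance)
  .fixture_cache[[key]]
}

## per-bin gene-density track for one chromosome of a fixture
fixture_gene_density <- function(sim, chrom) {
  cfg <- sim$config
  nb <- as.integer(cfg$chrom_length_bp / cfg$bin_size_bp)
  g <- sim$genome$genes[sim$genome$genes$chrom == chrom, , drop = FALSE]
  as.numeric(tabulate(
    pmin(floor((g$start + g$end) / 2 / cfg$bin_size_bp), nb - 1) + 1L, nb))
}

## greedy one-to-one matching of called loops to planted pixels (+/-1 bin)
match_loops <- function(calls, truth_loops, tol = 1L) {
  used <- rep(FALSE, nrow(calls))
  hit <- rep(FALSE, nrow(truth_loops))
  for (k in seq_len(nrow(truth_loops))) {
    cand <- which(!used & calls$chrom == truth_loops$chrom[k] &
                    abs(calls$bin_i - truth_loops$i[k]) <= tol &
                    abs(calls$bin_j - truth_loops$j[k]) <= tol)
    if (length(cand)) {
      used[cand[1]] <- TRUE
      hit[k] <- TRUE
    }
  }
  list(recall = mean(hit),
       precision = if (nrow(calls)) mean(used) else NA_real_)
}

## simple symmetric Poisson-decay matrix with no planted structure
null_contact_matrix <- function(seed, n = 200L, scale = 50, alpha = 1) {
  cfg <- synthetic_config(n_chromosomes = 1L, plaid_amplitude = 0,
                          tad_contrast = 1, coverage_scale = scale,
                          decay_exponent = alpha, rng_seed = seed)
  truth <- make_truth(cfg)
  truth$loops <- truth$loops[0, , drop = FALSE]
  truth$tad_boundaries[[1]] <- integer(0)
  simulate_contacts(truth, cfg)[[1]]
}

## brute-force interval overlap (>= 1 bp) between a point set of intervals
brute_overlaps_any <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    any(b$chrom == a$chrom[i] & b$start < a$end[i] & a$start[i] < b$end)
  }, logical(1))
}

chrom_names_of <- function(sim) names(sim$contacts)
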