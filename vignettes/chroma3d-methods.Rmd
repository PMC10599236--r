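---
title: "Methods: models and design choices in chroma3d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models and design choices in chroma3d}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

chroma3d reconstructs the three layers of plant 3D-genome organisation —
A/B compartments, topologically associating domains (TADs) and chromatin
loops — from binned intra-chromosomal Hi-C contact maps, and ties them to
regulatory annotation: accessible chromatin regions (ACRs) from ATAC-seq
peaks, enhancers from H3K27ac peaks, loop-mediated enhancer–gene links,
and SNP enrichment inside regulatory elements. This vignette documents
the statistical models, the tunable parameters, and the design decisions
behind each stage, and states precisely what the bundled synthetic-genome
generator does and does not emulate.

## Contact-map model and normalisation

A contact map is a symmetric `n × n` matrix of non-negative counts at a
fixed bin size; bins are 0-based half-open intervals, and the last bin is
truncated at the chromosome end. All analyses are cis (intra-chromosomal):
compartments, domains and loops are all defined on single-chromosome maps,
so inter-chromosomal contacts are never modelled.

`ice_balance()` performs iterative correction: bins whose marginal count
falls below the `mask_quantile` (default 0.02) order statistic of the
nonzero marginals are masked, then weights are updated as
`w <- w / (marginal / mean marginal)` until the coefficient of variation
of the balanced marginals drops below `tol` (default 1e-5, `max_iter`
200). Two numerical details matter:

* the quantile is computed as a type-1 (order-statistic) quantile with a
  0.1% relative slack below the cut. Without the slack, re-balancing an
  already balanced matrix — whose marginals are equal up to numerical
  noise — would re-trim its bottom bins every round; with it, balancing
  is idempotent while genuinely low-coverage bins are still masked;
* weights are rescaled once at convergence so the mean balanced value
  equals the mean raw value, which keeps balanced matrices on an
  interpretable count scale.

The distance-decay expectation is the mean balanced value over valid
pixel pairs at each separation; distances with no valid pair carry `NA`
and are excluded from any later division. The observed/expected (O/E)
transform divides by this expectation floored at 1e-10; floored pixels
are flagged and excluded from loop statistics.

## Compartments

Following standard practice, the A/B signal is the first principal
component of the Pearson correlation matrix of the O/E columns (whether
to correlate O/E or decompose it directly is a genuinely open choice; the
correlation map sharpens the plaid and is what the field's tools default
to). The correlation matrix is double-centred — which preserves symmetry
— and its dominant eigenvector is extracted by power iteration from a
deterministic start (tolerance 1e-12). The dense eigendecomposition is
deliberately *not* used in the implementation so that tests can hold it
up as an independent oracle.

The eigenvector sign is arbitrary, so `orient_and_label()` flips it iff
its correlation with per-bin gene density is negative: gene density is
the discriminating covariate of the A class in this dataset, and GC
content is intentionally not used for orientation. Bins with PC1
exactly 0 inherit the previous bin's label; leading zeros take the next
labelled bin. Compartments are counted as maximal same-label runs of
valid bins — the only reading under which compartment counts in the
hundreds coexist with 100-kb bins — and genes are assigned to the
compartment of their midpoint bin (a midpoint on a bin edge belongs to
the right bin, by the half-open convention).

## TADs

`insulation_score()` computes, for each interior bin, the mean balanced
value in a `window_bins × window_bins` diamond (default 5 bins) touching
the diagonal at that bin, and reports `log2(diamond / chromosome-mean
diamond)`. Boundaries are local minima with prominence — the smaller of
the rises to the intervening maxima towards the neighbouring minima or
the scored-region ends — of at least `delta_threshold` (default 0.1); a
plateau of equal minima keeps its leftmost bin. Chromosome ends count as
boundaries; intervals shorter than `min_tad_bins` (default 3) are
dropped. The window and delta defaults are declared choices: the
upstream tools this replaces take them from configuration files that are
not part of any publication, and the defaults here were fixed from the
geometry of the fixture (TADs of 15–35 bins at contrast 1.5) before any
recovery test was run. Multi-resolution calling coarsens the raw matrix
by integer factors and repeats the procedure; finer resolutions resolve
at least as many domains as coarser ones on structured maps.

Per-TAD marker vectors are the means of each per-bin track (gene
density, GC, LTR density, CG/CHG/CHH methylation, ATAC and H3K27ac
depth, expression) over the TAD's bins, z-scored per track. Expression
enters on the `log2(1 + x)` scale — the field's standard — because a
handful of very highly expressed genes would otherwise dominate the
z-scores and the clustering. TADs are clustered by Ward-linkage
hierarchical clustering on Euclidean distances cut at `k = 3` (three
groups is the biological structure being modelled; the linkage is a
declared choice). Roles are assigned from cluster means: highest mean
active score (z-means of H3K27ac, ATAC, expression, gene density) →
active; among the rest, highest mean repressive score (CG, CHG, CHH) →
repressive; remainder intermediate. Role assignment depends only on
cluster contents, so relabelling cluster ids can never change it.

## Loops

`call_loops()` is a single-resolution donut test in the spirit of the
standard GPU/CPU callers, deliberately simplified: no lambda-chunking,
no Knight–Ruiz specifics, one resolution. For each candidate pixel
(separation between 2 bins and 2 Mb by default, both bins valid), the
local expectation is the global decay expectation at that distance
rescaled by the donut-neighbourhood O/E ratio (annulus of Chebyshev
radius 3–5). The p-value is the upper-tail Poisson probability of the
observed **raw** count given this expectation mapped back through the
balancing weights; Benjamini–Hochberg FDR is applied per chromosome
(`bh_fdr()` is implemented in the package and cross-checked against the
reference implementation in tests). Significant pixels must additionally
be ≥ 1.75-fold enriched over the donut expectation and ≥ 1.5-fold over
the lower-left-neighbourhood expectation — both on the decay-normalised
scale, otherwise near-diagonal pixels would be compared against a
background dominated by much closer contacts. Eight-connected
significant pixels merge into one loop; clusters below
`min_cluster_pixels` (default 2) are discarded, the singleton filter
customary in donut-based callers — a genuine loop enriches a
neighbourhood of pixels, and with hundreds of truly enriched pixels in a
map, pixel-level BH alone does not control the *cluster*-level error of
isolated single-pixel Poisson flukes. The representative pixel is the
cluster member nearest the cluster centroid (ties broken by enrichment):
centroids track the focus centre, whereas the maximally enriched pixel
drifts by a bin and, with 1-bin anchors, a 1-bin drift reassigns genes.
Anchors are the representative pixel's bins as bp intervals.

Downstream statistics follow simple conventions: an anchor is genic iff
it overlaps ≥ 1 bp of a gene body (strand ignored); a loop with both
anchors on the same gene counts once for that gene; "multi-loop" genes
are those with strictly more than `min_loops` (default 10) loops; the
expression trend is summarised by group medians over loop-count bins
(1, 2–5, 6–10, >10) and a Spearman rank correlation.

## Regulatory elements and variants

The promoter window is the 3000 bp immediately upstream of the TSS,
strand-aware and clipped at chromosome bounds. ATAC peaks are classified
with promoter precedence — promoter window overlap first, then gene
body, else distal — so the three ACR classes partition the peak set.
Enhancers are H3K27ac peaks classified distal by the same geometry, and
are active iff they overlap ≥ 1 bp of an ATAC peak. The promoter window
doubles as the proximal zone because no separate distal cutoff is
defined for this dataset. Enhancer–gene links are loop-mediated only: an
anchor carrying an enhancer links the genes whose body *or promoter
window* overlaps the partner anchor (both gene-anchor readings are
accepted); an enhancer and gene sharing one anchor with an empty partner
yield no link. Reported counts de-duplicate anchors by coordinates and
genes by id.

Differential accessibility between two samples without replicates uses
per-peak counts scaled to counts per million, a pseudocount of 0.5, and
an exact two-sided binomial rate test conditional on the summed count
(success probability = library-size share), chosen for exactness at low
counts; a peak is differential iff `|log2 ratio| ≥ 1` and `p < 0.05`.

SNP positions are 1-based, elements 0-based half-open, so position `p`
lies in `[s, e)` iff `s ≤ p − 1 < e`. Same-class elements are merged
before length summation so overlapping elements never double-count
kilobases; class density is SNPs per merged kb and enrichment is that
density over the genome-wide density. Whether published per-class
densities were computed over merged or raw summed lengths is unstated
anywhere; merged length is the definition here.

## The synthetic genome and what passing tests mean

The generator is an assumption-faithful stand-in for the real assays
(whose processing details live in unavailable supplements), not a
reconstruction of them. Defaults: 2 chromosomes × 5 Mb at 25-kb bins
(200 bins per chromosome), decay exponent 1, plaid amplitude 0.3, TAD
contrast 1.5, loop strength 3, coverage scale 50, 400 genes, 40
enhancers (25% active), 3000 SNPs at in/out enrichment factor 20. These
sizes keep every stage's recovery measurable in seconds while leaving
each planted structure enough signal to be found by the declared
defaults, and they are the fixed study conditions of the acceptance
checks — they are not tuned per test.

Contact counts are independent Poisson draws per upper-triangle pixel
with mean `coverage_scale · (1+d)^-α · c · t · l` (compartment plaid
`c = 1 ± amplitude`, within-TAD factor `t`, loop factor `l` on the
1-pixel neighbourhood of each planted pixel), then symmetrised.
Compartment layout is deterministic — A over the telomeric quarters, B
over the pericentromeric half — so positional assertions are exact.
The two loop "hubs" (7 and 4 loops sharing an anchor) are pinned inside
telomeric A domains, since loop-dense anchors belong in gene-rich active
chromatin; all planted pixels keep pairwise Chebyshev distance ≥ 5 so
two planted loops can never merge into one 8-connected cluster through a
single noise pixel. Methylation is beta-distributed per 100-bp window
with context- and compartment-specific means (CG/CHG higher in B, CHH
higher in A) and a 4-fold dip inside peak bodies; depth tracks are
Poisson with a Gaussian bump at every TSS and plateaus over peaks; the
designated differential gene carries two peaks at a constructed 4:1
depth contrast (and is excluded from the generic genic-peak draw so
nothing stacks on top of that construction). Expression is lognormal
around `8 · (1 + loops)^1.2`, times 2.5 for genes with a promoter ACR.
SNPs fall inside the merged element space with probability
`f·r / (f·r + 1 − r)` (`f` the enrichment factor, `r` the element
fraction), which makes the in/out *density ratio* equal `f`; note the
density-over-genome-wide enrichment that `snp_density()` reports then
has expectation `f / (f·r + 1 − r)`, slightly below `f`, which is why
recovery is asserted on a small (~0.5%) element footprint.

Each output layer draws from its own seeded RNG stream (`seed +
layer-index`), so adding a layer never perturbs existing fixtures, and
identical configurations produce byte-identical files.

What the generator does **not** emulate: read-level data (FASTQ,
alignment, duplicates), bisulfite conversion, inter-chromosomal
contacts, diploid genotypes, replicate structure/IDR, peak calling
itself, genuine sequence (GC and LTR tracks are numeric surrogates), or
the long-tailed coverage heterogeneity of real Hi-C libraries. Passing
recovery tests therefore shows that each algorithm inverts its own
generative assumptions at realistic signal-to-noise — it does not show
robustness to artefacts these simplifications exclude.

## Problem sizes and numerical conventions

Recovery checks run on the default fixture: compartment and TAD-boundary
recovery aggregate 5 seeds (≈ 2000 labelled bins, ≈ 90 planted
boundaries), the loop caller is scored against 50 planted loops at ±1
pixel with one-to-one greedy matching, and the null false-discovery rate
is the mean per-seed false-discovery proportion (0/0 := 0) over 20
pure-decay matrices. Degenerate inputs are flagged rather than guessed
at: fewer than 3 valid bins or a zero-variance O/E map abort compartment
PCA, a single TAD cannot be z-scored, fewer than two distinct loop
counts make the expression trend undefined, and an empty group voids the
promoter-ACR rank test. Ties are resolved by fixed rules stated in the
function documentation (left plateau minima, previous-bin label
inheritance, right-bin midpoint assignment).
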