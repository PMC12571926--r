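---
title: "Methods: spatial co-profiling of DNA methylation and transcriptome"
author: "sdmt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial co-profiling of DNA methylation and transcriptome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The assay this package models

A tissue section is addressed by a two-dimensional grid of *pixels*, each
defined by a pair of combinatorial ligation barcodes (A~i~, B~j~), i, j =
1..50 in the standard device, giving n = 2,500 pixels. Two libraries are
made from every pixel: an RNA library (UMI-tagged cDNA) and a DNA library
that is enzymatically deaminated — TET2 protects modified cytosines while
APOBEC deaminates unmodified C to U, read as T. Consequently:

* In the DNA library **every sequence, including the barcodes, is
  deaminated**. Demultiplexing must therefore compare reads to whitelists in
  the C→T *collapsed* alphabet {A, G, T}, and whitelists must be validated
  for collisions after collapse ("crosstalk").
* At a cytosine with true methylation level $m$ and per-cytosine conversion
  probability $c$, the probability of reading C (a *retained* cytosine) is
  $$\Pr(\text{C}) \;=\; m + (1 - m)(1 - c),$$
  the **retention rate**. Retention pools methylation with incomplete
  conversion; on methylation-free linker sequence ($m = 0$) the converted
  fraction estimates $c$ directly — the **conversion efficiency**.
* 5mC and 5hmC are not distinguished by the chemistry, and neither are they
  in the simulator.

The pipeline implemented here takes demultiplexed, position-annotated reads
(alignment itself is out of scope) to per-pixel methylome and transcriptome
matrices, their joint clustering and downstream statistics.

# The synthetic-data generator

`sim_config()` / `make_truth()` / `emit_reads()` generate complete synthetic
datasets with ground truth, so every stage is testable offline. The
generator's defaults encode the study conditions the package is designed
around:

| parameter           | default | meaning                                        |
|---------------------|---------|------------------------------------------------|
| `grid_rows/cols`    | 50 × 50 | 2,500 barcoded pixels                          |
| `baseline_mcg`      | 0.75    | CG methylation baseline (retention band 70–80%)|
| `mch_level`         | 0       | embryo-like CH methylation (mCA < 1%)          |
| `conversion_prob`   | 0.995   | per-cytosine deamination (linker QC > 99%)     |
| `vmr_delta`         | −0.5    | methylation offset inside region VMRs          |
| `cpg_density`       | 10/kb   | planted CpG sites per kb                       |
| `dup_fraction`      | 0.3     | verbatim PCR duplicates (printed 20–53% band)  |
| `seq_error`         | 0.001   | per-base substitutions (linkers + inserts)     |
| `barcode_error`     | 0.005   | per-barcode substitution probability           |
| `nb_mean`, `nb_dispersion` | 2, 2 | negative-binomial RNA molecule counts      |

Design choices where the assay description leaves the details open:

* **Read layout.** Read 2 = barcode B (8 nt) + linker 1 (15 nt) + barcode A
  (8 nt) + linker 2 (15 nt) + [UMI (10 nt), RNA only] + insert. The real
  barcode/linker oligos are not published at sequence level; the layout is
  configurable (`read_layout()`), and each default linker carries exactly 5
  cytosines so linker-based conversion QC has a known denominator.
* **Region geometry.** Regions are a Voronoi partition of the grid seeded by
  uniform centroids — the simplest generator of contiguous, irregular
  regions; centroids are redrawn until every region is non-empty.
* **Methylation state is sampled per read**, not per molecule lineage; PCR
  duplicates are modelled by re-emitting a `dup_fraction` share of reads
  verbatim (the total DNA read count stays `pixels × reads_per_pixel_dna`).
* **Reference sequence.** Background bases are uniform with CG dinucleotides
  removed, then CpGs are planted at `cpg_density`; background cytosines
  supply CH contexts. Mitochondrial truth methylation is 0 at all sites.
* Sequencing errors are applied to linker and insert bases; barcode errors
  are governed by the single `barcode_error` knob so that barcode-matching
  behaviour has one interpretable rate.

What the generator does **not** emulate: realistic sequence composition,
fragment-length distributions, alignment artefacts, M-bias, chimeric reads,
or molecule-lineage duplicate structure. Passing tests therefore demonstrate
the *estimators and algorithms* are correct under the stated statistical
model, not that real libraries are free of these artefacts.

# Demultiplexing

Barcodes are matched by nearest Hamming neighbour with a budget of
`max_hamming` (default 1) mismatches per barcode — in the collapsed alphabet
for the DNA library, raw for RNA. Ties at the minimal distance are left
*ambiguous* rather than arbitrarily resolved, protecting spatial purity; `N`
counts as a mismatch. `validate_whitelist()` fails a whitelist whose
same-role pairs fall below a minimum pairwise distance in the working
alphabet; for DNA-mode demultiplexing a collapsed distance of at least
`2·max_hamming + 1` is required so that tolerant matching stays unambiguous.
Linker bases of DNA reads are retained by `demux_reads()` for conversion QC.

# Methylation calling and QC

`aggregate_calls()` deduplicates on (pixel, contig, leftmost read position,
strand) — the DNA library carries no UMI — keeping the first record, and
accumulates retained/converted counts per (pixel, site, strand, context).
Strands are kept separate in the call table; CG metrics, VMR aggregation and
coverage export merge the two strands of a palindromic CpG at the
plus-strand C position, matching standard extractor conventions while
preserving the raw data. Positions are 1-based in call tables; all BED
interchange is 0-based half-open.

Retention is reported per context as `100 · Σretained / Σ(retained +
converted)`; contexts with zero coverage are *missing*, never 0. mCH pools
CA/CC/CT.

**Knee filter.** Low-signal pixels are removed at the knee of the rank–count
curve: on (log10 rank, log10(count + 1)) the knee is the point of maximum
perpendicular distance to the chord joining the first and last points. The
assay description names only a "knee-plot cut-off"; the distance-to-chord
construction is this package's explicit, deterministic choice. A curve that
is a straight line (maximum distance < 1e-8) keeps all pixels with a
warning, and the threshold always equals an observed count.

# The methylome feature space

Sparse per-CpG data cannot feed a feature matrix directly, so the genome is
tiled into sliding windows (defaults 2,000/1,000 bp; window a multiple of
step). A window is *eligible* with ≥ `min_sites` CpGs (guided by the read
coverage knee plot) and ≥ `min_pixels` covered pixels (default 10). Each
eligible window is scored by the across-pixel variance of
**coverage-shrunken residuals**
$$r_{pw} = \frac{\mathrm{cov}_{pw}}{\mathrm{cov}_{pw} + k}\,
          (m_{pw} - \bar m_w), \qquad k = 1,$$
where $\bar m_w$ is the window's pooled mean. Exactly
`ceiling(top_fraction · n_eligible)` windows are selected (default top 2%),
with score ties broken by genomic order, and overlapping or book-ended
(gap 0) selected windows are fused into VMR intervals. The window/step/`k`
defaults and the shrinkage form are this package's documented
reimplementation choices; bit-compatibility with any external VMR scanner is
a non-goal.

**Iterative-PCA imputation.** Missing residuals start at 0 and missing
levels at the per-feature observed mean; a rank-r truncated SVD
reconstruction (no centring, so exact low-rank completion is a fixed point)
repeatedly replaces only the missing entries until the largest update falls
below `tol` (default 1e-4) or `max_iter`. Observed entries are never
altered; imputed levels are clamped to [0, 1]; all-missing features are
dropped with a report.

# Integration and clustering

RNA counts are UMI-collapsed (distinct (pixel, gene, UMI) triples,
exact-match collapse) and normalised by **median-ratio log-normalisation**
(scale each pixel to the median total, then log(1 + x)). This deliberately
replaces a regularised negative-binomial variance-stabilisation: the
contract is variance-stabilised input to PCA, not numerical identity with
any particular transform. PCA uses 30 components for RNA and 10 for
methylation residuals by default; component signs are fixed (largest
loading positive) so embeddings are bit-reproducible.

**WNN fusion** is a documented simplified variant of weighted-nearest-
neighbour integration. For pixel $i$ and modality $m$, the mean of its k
nearest neighbours' profiles predicts $x_{m,i}$ twice — once with the
modality's own neighbours (error $e^{\text{within}}_m$), once with the other
modality's neighbours ($e^{\text{cross}}_m$). With $\sigma_{i,m}$ the mean
distance to the k within-modality neighbours,
$$\beta_m = \frac{e^{\text{cross}}_m - e^{\text{within}}_m}{\sigma_{i,m}},
\qquad w_{\text{rna}} = \frac{e^{\beta_{\text{rna}}}}
      {e^{\beta_{\text{rna}}} + e^{\beta_{\text{meth}}}},$$
so the weights sum to one and are exactly ½/½ for identical embeddings.
Fused similarity is $w_{\text{rna}} e^{-d_{\text{rna}}/\sigma_{\text{rna}}} +
w_{\text{meth}} e^{-d_{\text{meth}}/\sigma_{\text{meth}}}$; a
shared-nearest-neighbour graph (Jaccard over fused k-NN sets, pruned below
1/15) feeds Leiden (default, modularity objective) or Louvain clustering,
seeded for determinism. Graph `k = 20` and resolution 0.8 are conventional
defaults. UMAP is a visualisation concern only and is never an acceptance
surface.

# Downstream statistics

* `diff_features()` — two-sided Wilcoxon rank-sum per feature (exact for
  small untied samples, normal approximation with tie correction
  otherwise), BH or Bonferroni across features. Log2 fold changes use a
  pseudo-count of 0.01 on methylation levels and 1 on normalised expression.
  Where the source protocol is internally inconsistent between a rank-sum
  and a signed-rank test, the rank-sum is implemented.
* `pair_vmr_gene()` / `corr_meth_expr()` — VMR–gene pairs by interval
  overlap with optional strand-aware upstream flank; Pearson correlation
  over jointly observed pixels (≥ 3), BH across pairs. Negative r is the
  repressive direction.
* `fold_enrichment()` — for a query CpG set against an annotation feature in
  a universe of N CpGs, $E = |q||f|/N$, $\mathrm{FE} = O/E$, one-sided
  (greater) Fisher exact p, BH across features. The O/E normalisation keeps
  high-coverage data from inflating odds ratios.

# Spatial utilities

Grid convention: barcode A index = row, barcode B index = column, 1-based;
(A1, B1) is pixel (1, 1); the image frame is x-right/y-down. Registration to
a bright-field image is a least-squares affine fit from ≥ 3 non-collinear
correspondences. `nn_smooth()` replaces each pixel by the uniform mean of
its k nearest pixels (Euclidean grid distance, ties broken lexicographically
by (row, col)); the original assay's smoothing kernel is not specified at
this level of detail, so the uniform k-NN mean is documented as this
package's choice. Missing neighbours are excluded; all-missing
neighbourhoods stay missing.

# Numerical choices and degenerate inputs

* Knee detection tolerance 1e-8 (degenerate straight-line curves keep all).
* Imputation: convergence on the max-norm of updates; tolerance 1e-4;
  observed entries bit-identical before/after.
* PCA signs fixed by the largest-magnitude loading; zero-variance columns
  are left unscaled when `scale. = TRUE`.
* WNN bandwidths floored at 1e-12; k ≥ 2 and k < n enforced.
* Zero-coverage retention contexts are `NA`; zero-total RNA pixels are
  dropped with a report; empty VMR scans warn and return an empty set.
* Wilcoxon features with < 2 observed values per group are flagged
  `tested = FALSE`, not silently dropped.

# Problem sizes used in the shipped checks

The package's own test suite and the acceptance script run entirely on
synthetic data at desk scale, chosen so the whole suite completes in a few
minutes on one CPU: full 50 × 50 grids with one read per pixel for the
demultiplexing completeness check; 100,000 linker-bearing DNA reads for
conversion-efficiency estimation; 200 pixels with > 10^4 CG and CH
observations for the retention-band checks; 1,000 eligible windows for the
top-2% selection check; and a 196-pixel, four-region joint simulation
(methylation delta 0.4, marker fold change 4, deep per-pixel coverage,
reflecting the >10^5-CpG-per-pixel depth of the real assay) for cluster
recovery, on which the WNN-Leiden pipeline is required to reach ARI ≥ 0.8
against the true regions across seeds.

# Known limitations

* The simulator's truth is piecewise-constant methylation over planted
  intervals; real VMR structure is softer and autocorrelated.
* Deduplication by genomic position slightly overestimates duplication at
  extreme depth (coincidental identical fragments are collapsed).
* The WNN variant targets contract-level behaviour (weight normalisation,
  symmetry, informativeness ordering), not numerical identity with any
  published implementation.
* Alignment, M-bias trimming, base-quality recalibration, label transfer,
  pseudotime, motif databases and GO databases are out of scope; annotation
  inputs (genes, chromatin states, PMDs, TSS) are consumed as user-supplied
  BED-style tables.
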