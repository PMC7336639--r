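---
title: "Methods: muscle atlas processing and ligand-receptor scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: muscle atlas processing and ligand-receptor scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind each stage of
`musclecomm`, the parameters that matter, the design choices made where
several defensible options existed, and what the synthetic validation
does and does not demonstrate about real data.

## Quality control

Cells are retained when they have strictly more than `min_umi` (default
1000) UMIs and strictly less than `max_mito_frac` (default 0.20) of their
UMIs on genes whose symbol starts with `mito_prefix` (`"MT-"`). Both cell
rules are strict inequalities, taken literally from the protocol they
implement; the gene rule ("expressed in at least `min_cells_per_gene`
cells", default 3) is non-strict. Cell filtering precedes gene filtering:
gene detection is counted over surviving cells only, which matches common
practice and is the order in which the rules are stated. The mitochondrial
fraction of an all-zero cell is defined as 0, so empty cells fail only the
UMI rule.

One consequence worth knowing: QC is a fixed point of itself only when
surviving cells clear `min_umi` on the surviving genes alone. Removing
genes lowers cell totals, so a cell sitting exactly at the threshold can
drop on a second application. The per-cell statistics are therefore meant
to be computed once, on the raw matrix.

## Normalization and covariate scaling

Expression is library-size normalized to `scale_factor` (default 10,000,
the droplet-workflow convention) and transformed with natural-log
`log1p`. For any non-empty cell the delogged values sum back to the scale
factor exactly, which the tests assert.

Technical covariates are then removed by per-gene ordinary least squares:
each gene's normalized values are regressed on an intercept, the 10x
chemistry (treatment-coded factor) and the number of genes detected per
cell; the residuals replace the values and are standardized to unit
sample variance, clipped at `clip` (default 10) standard deviations.
Chemistry is the dominant technical axis in mixed v2/v3 designs — v3
captures systematically more molecules per cell — and genes-detected is
its cell-level proxy. Constant covariates are dropped with a warning; a
rank-deficient design degrades gracefully by dropping the pivoted-out
columns rather than failing. The package treats externally integrated
matrices as an interface point: if a batch-corrected matrix is available
it can be passed straight to `regress_covariates()` or `embed_pca()`;
the regression path is the self-contained correction.

## Clustering

Cells are embedded with exact PCA (`n_pcs` = 30 components; signs fixed
by making the largest-magnitude loading positive so embeddings are
platform-reproducible). The shared-nearest-neighbor graph uses each
cell's `k_neighbors` = 20 Euclidean nearest neighbors, counting the cell
itself — the convention of the standard single-cell workflow, and the
reason a pair of mutually nearest cells gets Jaccard weight 1 at k = 2.
Edge weights are Jaccard overlaps of neighbor sets; edges at or below
`snn_prune` = 1/15 are removed. Neighbor ties are broken by cell index,
which keeps the graph deterministic.

Communities are found by Leiden optimization of modularity with a
resolution parameter (default 0.4, the analysis value this pipeline is
built around) and a mandatory seed. Leiden is preferred over plain
Louvain for its refinement guarantees and reproducibility. Labels are
renumbered consecutively by decreasing cluster size.

Annotation is marker-driven: each cell type's score in a cluster is the
mean over its marker genes of the per-gene mean *normalized* (not scaled)
expression, so scores stay non-negative and interpretable; the argmax
wins, ties break alphabetically with a warning. A 12-term human muscle
nomenclature with canonical markers (*PAX7* for MuSC, *RGS5*/*MYH11* for
mural cells, *PECAM1* for endothelium, ...) ships in
`inst/extdata/human_muscle_markers.tsv`. The mapping from shared terms to
finer subpopulations (e.g. the two MuSC pools) is deliberately left to
the marker table supplied by the user.

## Differential expression

`wilcoxon_rank_sum()` computes the Mann-Whitney U from midranks. With
combined sample size at most 12 and no ties the p-value is exact from the
Wilcoxon distribution; otherwise the normal approximation with tie
correction and continuity correction is used — the same formulation as
`stats::wilcox.test`, against which the approximate branch is
cross-checked, with one deliberate difference: when every value is
identical the tie-corrected variance vanishes and the p-value is defined
as 1 rather than NaN.

`find_markers()` gates genes before testing: the expressing fraction of
at least one group must reach `min_pct` (default 0.25) and |log2FC| must
exceed `lfc_threshold` (default 0.25). The fold-change is computed on
delogged means with a pseudocount:
`log2((mean(expm1(x)) + 1) / (mean(expm1(y)) + 1))`. The printed form of
the fold-change gate in the protocol this follows ("> log2(0.25)") is
internally inconsistent — log2(0.25) = −2 would gate nothing — so the
package uses 0.25 log2 units, the threshold of the workflow the protocol
names. The `pct_side` switch selects whether the fraction gate uses the
larger of the two groups (default, symmetric) or the focal group only.

Multiple-testing correction is Benjamini-Hochberg. The default universe
is **all genes of the matrix** (`bh_universe = "all"`), mirroring the
adjusted p-values of the standard workflow, which corrects over the full
dataset. The alternative of correcting only over the genes surviving the
fold-change gate (`bh_universe = "gated"`) is available but
anti-conservative: gating selects genes extreme by chance, and in planted
-truth simulations at atlas-like scale the observed false discovery rate
under the gated universe exceeded 0.5 at q < 0.05, versus ~0.02-0.06
under the full universe with unchanged sensitivity. That measurement
drove the default.

## The ligand-receptor communication model

For a focal (receptor-bearing) population, receptors from the pair table
are first gated by one-vs-rest differential expression: q < `alpha`
(default 0.05) **and positive fold-change** — an under-expressed
"differential" receptor would contradict the model's intent. The phrase
"compared individually to all other cell types" is read as a single
one-vs-rest test; a `pairwise_all` mode requiring a win against every
other population individually is provided because the phrase admits both
readings.

Each gated pair is scored against every sender as the product of the mean
receptor expression in the focal population and the mean ligand
expression in the sender. Means are arithmetic means of log1p-normalized
values: deterministic, monotone, and robust to single deep cells; a
sensitivity analysis on delogged means is possible by transforming the
matrix beforehand. Senders exclude the focal population itself (the model
targets signals *to* the stem cells from their niche); `include_autocrine
= TRUE` lifts that. Raw scores are bilinear in the two mean expressions,
which the tests exploit as an invariant.

Row z-scores standardize each (pair, focal) row across senders with the
sample SD (divisor n − 1); constant or singleton rows are defined as
z = 0 everywhere rather than NaN. Ligand specificity is flagged when the
sender expresses the ligand differentially (one-vs-rest, q < alpha,
positive fold-change) — interactions so flagged are likely cell-type
specific rather than ubiquitous. Exports cover the three standard views:
the per-focal score/z table, a receptor panel ranked by fold-change
between two focal subpopulations with an FDR significance flag, and a
flat chord-edge list in which `significant` marks edges whose receptor
passed the gate (edges scored with `all_pairs = TRUE` supply the gray
background of a chord diagram).

## The synthetic-atlas generator

`synth_spec()` defaults emulate the atlas design this pipeline targets:
10 donors at 2206 ± 1961 cells each (log-normal, truncated), v2/v3
chemistries alternating across donors (v3 at 1.6× depth), 16 populations
including MuSC1/MuSC2 with geometrically decaying frequencies, 2000 genes
of which 13 are "MT-" mitochondrial genes carrying 10% of baseline
expression (so mitochondrial QC is exercised on both sides of the
threshold), baseline 1 UMI per gene per cell, negative-binomial size 2 —
the accepted overdispersion model for UMI counts — and log-normal donor
depth factors (σ = 0.3) mimicking donor-to-donor depth heterogeneity.
Donor-level sex/age/site metadata is drawn to mirror the atlas metadata
schema. Markers multiply the baseline mean by `2^marker_log2fc` in their
own population; LR circuits multiply the ligand mean in the sender and
the receptor mean in the receiver by `fold`, independently per
(gene, population) cell of the mean matrix. Every donor has its own RNG
stream derived from the master seed, so donor D01's cells are identical
whether 2 or 10 donors are generated.

What the generator does **not** emulate: gene-gene correlation structure,
doublets, ambient RNA, skewed per-gene abundance profiles, or
cluster-specific library sizes. Passing recovery tests on this generator
therefore demonstrates the correctness of the algorithms under the
assumed noise model, not robustness to every artifact of real droplet
data. The covariate-regression path also does not reproduce a full
integration algorithm; it is the self-contained technical correction.

## Validation scale and determinism

The test suite and `scripts/acceptance.R` use desk-scale problem sizes
chosen so the whole validation runs in about a minute on one CPU while
keeping sampling error far from the asserted margins: exhaustive Wilcoxon
enumeration over all splits with group sizes ≤ 6 (3418 splits); a null
type-I simulation of 2000 genes at 100 + 100 cells; marker recovery on 10
populations × 200 cells with 5 markers each at log2FC 1.5; LR circuit
recovery (fold 8) over 20 seeded runs of 10 populations × 200 cells;
clustering recovery on 5 populations × 200 cells with 20 markers each at
log2FC 2 — the configuration this package treats as "well separated".
All randomness flows from explicit seeds; pipeline reruns with the same
config and seed are byte-identical, which the manifest checksums assert.

## Known limitations

- Exact kNN is O(n²) in cells (blocked to bound memory); beyond ~10⁵
  cells an approximate neighbor search would be needed.
- Wilcoxon p-values for heavily tied, small groups rely on the
  tie-corrected normal approximation; no permutation fallback is
  implemented.
- Annotation assumes marker genes are informative in normalized space; it
  does not model marker absence (negative markers).
- The LR score is a mean-product heuristic: it has expression² units, is
  comparable only within a row after z-standardization, and carries no
  per-pair significance test beyond the two DE gates.
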