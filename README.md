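# musclecomm

Single-cell RNA-seq processing for human skeletal-muscle atlases, with a
ligand-receptor (LR) cell-communication scoring model centered on muscle
stem cells (MuSCs).

Droplet scRNA-seq of whole muscle captures a mixture of myogenic, stromal,
vascular, and immune populations, including two MuSC subpopulations — a
quiescent pool (high *PAX7*, *CDKN1C*, *DLK1*) and an early-activated,
inflammation-associated pool (*TNFRSF12A*/FN14, *CD44*). A central question
is which signals other cell types send to these stem cells. `musclecomm`
implements the full path from raw UMI count matrices to a scored
communication network, plus a synthetic-atlas generator with planted ground
truth so every stage can be validated quantitatively.

## What the package computes

1. **QC filtering** — retain cells with more than 1000 UMIs and less than
   20% mitochondrial UMIs, then genes expressed in at least 3 surviving
   cells (all thresholds configurable).
2. **Normalization and scaling** — per-cell library-size normalization to
   10,000 counts with `log1p`; then per-gene OLS regression removing
   technical covariates (10x chemistry v2/v3, genes detected per cell) and
   standardization to unit variance.
3. **Clustering** — PCA (30 PCs), shared-nearest-neighbor graph (k = 20,
   Jaccard edge weights pruned at 1/15), Leiden modularity communities at
   resolution 0.4, and marker-based cell-type annotation against a bundled
   12-term human muscle nomenclature.
4. **Marker detection** — Wilcoxon rank-sum tests with expressing-fraction
   (≥ 0.25) and |log2FC| (> 0.25) gates, Benjamini-Hochberg q-values.
   Fold-changes are ratios of pseudocounted delogged mean normalized
   expression.
5. **LR communication model** — for a focal population *F* (e.g. MuSC1)
   and a curated ligand-receptor pair table (Ramilowski-style), receptors
   are gated by differential expression in *F* (one-vs-rest, q < 0.05,
   positive fold-change); each surviving pair (L, R) is scored against
   every other cell type *S* as

   ```
   score(L_R, S) = mean expr(R | cells of F) x mean expr(L | cells of S)
   ```

   Scores are row-standardized (z-score across senders) for heatmap-style
   comparison, and a sender is flagged when it expresses the ligand
   differentially (the interaction is then likely cell-type specific).
   Ranked receptor panels (e.g. MuSC1 vs MuSC2) and chord-diagram edge
   tables are exported as TSV.

A negative-binomial generator (`synth_spec()` / `generate_dataset()`)
emulates the atlas design — 10 donors, two 10x chemistries, 16 populations
including MuSC1/MuSC2, mitochondrial genes, donor depth variability — and
plants marker genes and LR circuits whose recovery the test suite and
acceptance script measure.

## Worked example

Simulate a small five-population atlas with one planted communication
circuit (ligand `GENE00300` from Fibroblast1 to receptor `GENE00301` on
MuSC1, fold 8), cluster it, and score the circuit:

```r
library(musclecomm)

spec <- synth_spec(
  n_donors = 4, cells_per_donor = list(mean = 500, sd = 0),
  n_populations = 5, population_proportions = rep(0.2, 5),
  n_genes = 600, marker_genes_per_population = 20, marker_log2fc = 2,
  lr_circuits = list(list(ligand = "GENE00300", receptor = "GENE00301",
                          sender = "Fibroblast1", receiver = "MuSC1",
                          fold = 8)),
  seed = 1)
ds <- generate_dataset(spec)

qcp    <- qc_params(min_umi = 300)        # 600-gene toy; scale threshold down
qc     <- compute_cell_qc(ds$counts, qcp)
counts <- apply_qc_filters(ds$counts, qc, qcp)
nm     <- log_normalize(counts)
keep   <- match(colnames(counts), qc$barcode)
sm     <- regress_covariates(nm, data.frame(
  chemistry = ds$meta$chemistry[keep],
  n_genes_detected = qc$n_genes_detected[keep]))
cl     <- cluster_cells(sm, cluster_params(resolution = 0.4, seed = 1))
table(cl, ds$truth$cells$population[keep])
```

```
cl  Fibroblast1 Fibroblast2 MuSC1 MuSC2 Myonuclei
  1           0           1     0   433         1
  2         429           0     0     0         0
  3           1           1     0     0       391
  4           0           2   390     1         0
  5           0         350     0     0         0
```

The five planted populations are recovered almost perfectly at the default
resolution. Scoring the planted circuit with MuSC1 as the receptor-bearing
focal population:

```r
pairs <- data.frame(ligand = "GENE00300", receptor = "GENE00301",
                    pair_name = "GENE00300_GENE00301")
res <- lr_analysis(nm, ds$truth$cells$population[keep], "MuSC1", pairs)
res$scores[, c("pair_name", "sender", "raw_score", "z_score", "ligand_de")]
```

```
            pair_name      sender raw_score z_score ligand_de
1 GENE00300_GENE00301 Fibroblast1     18.21   1.498      TRUE
2 GENE00300_GENE00301 Fibroblast2      7.28  -0.493     FALSE
3 GENE00300_GENE00301       MuSC2      6.88  -0.564     FALSE
4 GENE00300_GENE00301   Myonuclei      7.56  -0.441     FALSE
```

The receptor passes the differential-expression gate in MuSC1, the planted
sender attains the largest row z-score, and only that sender is flagged as
expressing the ligand differentially — the behavior the model is designed
to exhibit on a genuine communication circuit.

`run_pipeline()` chains all stages (simulate/load → QC → normalize/scale →
cluster → markers → LR scoring) from a YAML config, writing stage TSVs and
a `manifest.json` with parameters, seed, and output checksums;
`inst/scripts/run_pipeline.R` wraps it for shell use.

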