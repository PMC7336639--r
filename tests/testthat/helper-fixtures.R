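# Shared fixtures and independent oracles for the test suite.

# Exhaustive permutation oracle for the two-sided Wilcoxon rank-sum
# p-value: enumerate every assignment of the pooled values to the two
# groups and compare the observed U against the full distribution.
enum_wilcox_p <- function(x, y) {
  nx <- length(x)
  z <- c(x, y)
  n <- length(z)
  r <- rank(z)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  sets <- utils::combn(n, nx)
  us <- apply(sets, 2, function(ix) sum(r[ix]) - nx * (nx + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# hand-enumerated QC fixture: 4 genes x 5 cells, min_umi 10 (strict),
# max mito fraction 0.2 (strict), min 3 expressing cells per gene.
# Surviving cells: C1 (14 UMI), C4 (15 UMI, 13.3% mito), C5 (11 UMI);
# C2 fails at exactly 10 UMIs, C3 at 25% mito. Among survivors MT-X is
# expressed in 1 cell and G2 in 2, so only G1 and G3 survive; the
# surviving cells keep > 10 UMIs on G1 + G3 alone, so the filter is a
# fixed point of itself on this fixture.
qc_toy <- function() {
  m <- Matrix::Matrix(c(
    0, 0, 5, 2, 0,    # MT-X
    8, 10, 10, 8, 6,  # G1
    3, 0, 0, 2, 0,    # G2
    3, 0, 5, 3, 5),   # G3
    nrow = 4, byrow = TRUE, sparse = TRUE,
    dimnames = list(c("MT-X", "G1", "G2", "G3"), paste0("C", 1:5)))
  list(counts = m,
       params = qc_params(min_umi = 10, max_mito_frac = 0.2,
                          min_cells_per_gene = 3),
       surviving_cells = c("C1", "C4", "C5"),
       surviving_genes = c("G1", "G3"))
}

# small balanced synthetic atlas without depth confounders, for recovery
# tests where the planted structure should dominate
flat_spec <- function(n_populations, cells_per_pop, n_genes, seed,
                      markers_per_pop = 5, marker_log2fc = 1.5,
                      lr_circuits = list(), n_donors = 2) {
  synth_spec(
    n_donors = n_donors,
    cells_per_donor = list(mean = n_populations * cells_per_pop / n_donors,
                           sd = 0),
    n_populations = n_populations,
    population_proportions = rep(1 / n_populations, n_populations),
    n_genes = n_genes, n_mito_genes = 10,
    baseline_mean = 1, nb_dispersion = 2,
    marker_genes_per_population = markers_per_pop,
    marker_log2fc = marker_log2fc,
    chemistry_effect = c(v2 = 1, v3 = 1.4),
    donor_depth_sd = 0.2, mito_share = 0.05,
    lr_circuits = lr_circuits, seed = seed)
}

# normalized matrix with exact constant values per (gene, group); handy
# for arithmetic checks of DE and LR scoring
block_nm <- function(gene_means, labels) {
  # gene_means: genes x groups matrix of delogged means
  vals <- log1p(gene_means[, labels, drop = FALSE])
  colnames(vals) <- sprintf("cell%03d", seq_along(labels))
  as.matrix(vals)
}

true_labels <- function(ds) {
  ds$truth$cells$population[match(colnames(ds$counts),
                                  ds$truth$cells$barcode)]
}
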